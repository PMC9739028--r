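#' Event list for one effector
#'
#' An ordered sequence of ground-contact events for one effector (pole,
#' left ski or right ski).  Kinds strictly alternate `ON`, `OFF`, `ON`, ...
#' starting with `ON`; times are strictly increasing and given in seconds.
#' A final unpaired `ON` (contact still ongoing at the end of the recording)
#' is legal.
#'
#' @param time numeric vector of event times in seconds, strictly increasing.
#' @param kind character vector of `"ON"`/`"OFF"`, same length as `time`,
#'   strictly alternating and starting with `"ON"`.
#' @param effector one of `"pole"`, `"left_ski"`, `"right_ski"`.
#' @return An object of class `event_list`: a list with elements `time`,
#'   `kind` and `effector`.
#' @examples
#' ev <- event_list(c(0.10, 0.60), c("ON", "OFF"), "pole")
#' ev
#' @export
event_list <- function(time = numeric(), kind = character(),
                       effector = c("pole", "left_ski", "right_ski")) {
  effector <- match.arg(effector)
  time <- as.numeric(time)
  kind <- as.character(kind)
  if (length(time) != length(kind))
    stop("`time` and `kind` must have the same length")
  if (length(time)) {
    if (anyNA(time) || any(!is.finite(time)))
      stop("event times must be finite")
    if (any(diff(time) <= 0))
      stop("event times must be strictly increasing")
    if (!all(kind %in% c("ON", "OFF")))
      stop("event kinds must be \"ON\" or \"OFF\"")
    expected <- rep_len(c("ON", "OFF"), length(kind))
    if (!identical(kind, expected))
      stop("event kinds must strictly alternate ON, OFF, ... starting with ON")
  }
  structure(list(time = time, kind = kind, effector = effector),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list: %s, %d events>\n", x$effector, length(x$time)))
  if (length(x$time)) {
    show <- utils::head(data.frame(kind = x$kind, time_s = x$time), 10L)
    print(show, row.names = FALSE)
    if (length(x$time) > 10L) cat(sprintf("... %d more\n", length(x$time) - 10L))
  }
  invisible(x)
}

#' @export
length.event_list <- function(x) length(x$time)

#' Binary phase sequence
#'
#' Per-timestep 0/1 encoding of swing (0) versus ground contact (1) for one
#' effector at a fixed sampling rate.
#'
#' @param values integer vector over \{0, 1\}.
#' @param sample_rate sampling rate in Hz, positive.
#' @param effector one of `"pole"`, `"left_ski"`, `"right_ski"`.
#' @return An object of class `binary_phase`.
#' @export
binary_phase <- function(values, sample_rate,
                         effector = c("pole", "left_ski", "right_ski")) {
  effector <- match.arg(effector)
  values <- as.integer(values)
  if (anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("`values` must contain only 0 and 1")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a positive scalar")
  structure(list(values = values, sample_rate = as.numeric(sample_rate),
                 effector = effector),
            class = "binary_phase")
}

#' @export
print.binary_phase <- function(x, ...) {
  cat(sprintf("<binary_phase: %s, %d samples @ %g Hz, %.1f%% contact>\n",
              x$effector, length(x$values), x$sample_rate,
              if (length(x$values)) 100 * mean(x$values) else 0))
  invisible(x)
}

#' @export
length.binary_phase <- function(x) length(x$values)

#' Encode an event list as a binary phase sequence
#'
#' Contact is 1 on the half-open sample interval
#' `[round(t_ON * rate), round(t_OFF * rate))` for every ON/OFF pair, 1 from a
#' final unpaired ON to the end of the sequence, and 0 elsewhere.
#'
#' @param events an [event_list].
#' @param n_samples length of the output sequence.
#' @param sample_rate output sampling rate in Hz.
#' @return A [binary_phase] of length `n_samples`.
#' @examples
#' ev <- event_list(c(0.10, 0.60), c("ON", "OFF"), "pole")
#' sum(events_to_binary(ev, 100, 100)$values)  # 50 contact samples
#' @export
events_to_binary <- function(events, n_samples, sample_rate) {
  stopifnot(inherits(events, "event_list"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 0) stop("`n_samples` must be non-negative")
  v <- integer(n_samples)
  if (length(events$time)) {
    bad <- events$time >= n_samples / sample_rate
    if (any(bad))
      stop(sprintf("event at %.6f s lies beyond the sequence end (%.6f s)",
                   events$time[which(bad)[1]], n_samples / sample_rate))
    idx <- as.integer(round(events$time * sample_rate))
    idx <- pmin(pmax(idx, 0L), n_samples)
    ons <- idx[events$kind == "ON"]
    offs <- idx[events$kind == "OFF"]
    if (length(offs) < length(ons)) offs <- c(offs, n_samples)
    for (k in seq_along(ons)) {
      if (offs[k] > ons[k]) v[(ons[k] + 1L):offs[k]] <- 1L
    }
  }
  binary_phase(v, sample_rate, events$effector)
}

#' Read events out of a binary phase sequence
#'
#' Emits ON at every 0-to-1 transition (and at sample 0 if the sequence starts
#' in contact) and OFF at every 1-to-0 transition; the time of sample `k` is
#' `k / sample_rate` seconds.  Inverse of [events_to_binary()] for event lists
#' whose OFF precedes the sequence end.
#'
#' @param seq a [binary_phase].
#' @return An [event_list].
#' @export
binary_to_events <- function(seq) {
  stopifnot(inherits(seq, "binary_phase"))
  v <- seq$values
  n <- length(v)
  if (n == 0L) return(event_list(effector = seq$effector))
  prev <- c(0L, v[-n])
  on_idx <- which(v == 1L & prev == 0L) - 1L
  off_idx <- which(v == 0L & prev == 1L) - 1L
  idx <- sort(c(on_idx, off_idx))
  kind <- ifelse(idx %in% on_idx, "ON", "OFF")
  event_list(idx / seq$sample_rate, kind, seq$effector)
}
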