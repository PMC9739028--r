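#' Extract reference contact events from a force channel
#'
#' Thresholds a force signal at a fraction of bodyweight (5% for force poles,
#' 7% for force insoles) and emits contact events: ON at the first sample at
#' or above the threshold after being below it (or at time 0 when the trace
#' starts in contact), OFF at the first sample strictly below the threshold
#' after an ON.  A contact still ongoing at the end of the trace emits no
#' trailing OFF.  No smoothing, hysteresis or debouncing is applied; the raw
#' force trace is thresholded as-is.
#'
#' @param force numeric vector of force samples in newtons.
#' @param sample_rate sampling rate of `force` in Hz.
#' @param bodyweight subject bodyweight in newtons, positive.
#' @param threshold_fraction threshold as a fraction of bodyweight in (0, 1);
#'   0.05 for poles, 0.07 for skis.
#' @param effector effector label carried by the returned [event_list].
#' @return An [event_list]; empty when the force never reaches the threshold.
#' @examples
#' f <- c(rep(0, 10), rep(100, 50), rep(0, 40))
#' extract_events(f, 100, 800, 0.05)  # ON at 0.10 s, OFF at 0.60 s
#' @export
extract_events <- function(force, sample_rate, bodyweight, threshold_fraction,
                           effector = c("pole", "left_ski", "right_ski")) {
  effector <- match.arg(effector)
  if (!is.numeric(bodyweight) || length(bodyweight) != 1L || bodyweight <= 0)
    stop("`bodyweight` must be a positive scalar")
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("`threshold_fraction` must lie in (0, 1)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a positive scalar")
  force <- as.numeric(force)
  if (length(force) == 0L) return(event_list(effector = effector))
  if (anyNA(force) || any(!is.finite(force)))
    stop("`force` contains non-finite samples")

  above <- force >= bodyweight * threshold_fraction
  n <- length(above)
  prev <- c(FALSE, above[-n])
  on_idx <- which(above & !prev) - 1L    # 0-based sample indices
  off_idx <- which(!above & prev) - 1L
  idx <- sort(c(on_idx, off_idx))
  if (length(idx) == 0L) return(event_list(effector = effector))
  kind <- ifelse(idx %in% on_idx, "ON", "OFF")
  event_list(idx / sample_rate, kind, effector)
}

#' Extract the reference events for every effector of a trial
#'
#' Applies [extract_events()] to the left pole force (5% bodyweight threshold)
#' and to the two insole forces (7% bodyweight).  Only the left pole drives
#' the pole event stream: the cycle is anchored at the left-pole plant and one
#' network is trained per pole/ski stream.
#'
#' @param trial a `trial_recording` from [generate_trial()] or [read_trial()].
#' @param pole_fraction,ski_fraction bodyweight fractions for the thresholds.
#' @return Named list of [event_list]: `pole`, `left_ski`, `right_ski`.
#' @export
extract_reference <- function(trial, pole_fraction = 0.05,
                              ski_fraction = 0.07) {
  stopifnot(inherits(trial, "trial_recording"))
  list(
    pole = extract_events(trial$pole_force_left, trial$force_sample_rate,
                          trial$bodyweight, pole_fraction, "pole"),
    left_ski = extract_events(trial$insole_force_left, trial$force_sample_rate,
                              trial$bodyweight, ski_fraction, "left_ski"),
    right_ski = extract_events(trial$insole_force_right,
                               trial$force_sample_rate, trial$bodyweight,
                               ski_fraction, "right_ski")
  )
}
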