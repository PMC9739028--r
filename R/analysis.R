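# Event attribution and error statistics: each detected (ML) event is
# attributed to the closest reference event of the same kind; reference
# events with no attribution are missed, surplus attributions beyond the
# first are extra.  Timing errors are signed ml - ref in milliseconds.

#' Match detected events against reference events
#'
#' Each ML event of the given kind is attributed to the reference event of
#' that kind with the minimal absolute time difference (a tie goes to the
#' earlier reference event).  A reference event with no attributed ML event
#' counts as missed; for a reference event with `k > 1` attributions the
#' closest ML event forms the timing pair (a tie goes to the earlier ML
#' event) and the other `k - 1` count as extra.  No maximum-distance gate is
#' applied unless `max_distance` is set.  With an empty reference list
#' nothing can be attributed, so `n_missed = n_extra = 0` while `n_ml` still
#' reports the detections.
#'
#' @param ml [event_list] of detected events.
#' @param ref [event_list] of reference events (same effector).
#' @param kind `"ON"` or `"OFF"`.
#' @param max_distance optional gate in seconds: ML events farther than this
#'   from every reference event are dropped from attribution (counted
#'   neither as pairs nor extra).  Default `Inf` (off).
#' @return An object of class `match_report`: list with `effector`, `kind`,
#'   `pairs` (data frame `ref_time`, `ml_time`, `error_ms`), `n_ref`,
#'   `n_ml`, `n_missed`, `n_extra`.
#' @examples
#' ref <- event_list(c(1, 2, 3), c("ON", "OFF", "ON"), "pole")
#' ml <- event_list(c(1.05, 2.0, 2.98), c("ON", "OFF", "ON"), "pole")
#' match_events(ml, ref, "ON")
#' @export
match_events <- function(ml, ref, kind = c("ON", "OFF"),
                         max_distance = Inf) {
  kind <- match.arg(kind)
  stopifnot(inherits(ml, "event_list"), inherits(ref, "event_list"))
  if (ml$effector != ref$effector)
    stop(sprintf("effector mismatch: ml is %s, ref is %s", ml$effector,
                 ref$effector))
  mt <- ml$time[ml$kind == kind]
  rt <- ref$time[ref$kind == kind]
  n_ml <- length(mt)
  n_ref <- length(rt)
  pairs <- data.frame(ref_time = numeric(0), ml_time = numeric(0),
                      error_ms = numeric(0))
  if (n_ref == 0L || n_ml == 0L) {
    return(structure(list(effector = ml$effector, kind = kind, pairs = pairs,
                          n_ref = n_ref, n_ml = n_ml, n_missed = n_ref,
                          n_extra = 0L),
                     class = "match_report"))
  }
  # attribution: nearest reference per ML event, tie -> earlier reference
  attr_of <- integer(n_ml)
  for (j in seq_len(n_ml)) {
    d <- abs(mt[j] - rt)
    i <- which(d <= min(d) + 1e-12)[1L]
    attr_of[j] <- if (d[i] <= max_distance) i else NA_integer_
  }
  n_missed <- 0L
  n_extra <- 0L
  for (i in seq_len(n_ref)) {
    js <- which(!is.na(attr_of) & attr_of == i)
    if (length(js) == 0L) {
      n_missed <- n_missed + 1L
      next
    }
    d <- abs(mt[js] - rt[i])
    jbest <- js[which(d <= min(d) + 1e-12)[1L]]  # tie -> earlier ML event
    pairs <- rbind(pairs, data.frame(ref_time = rt[i], ml_time = mt[jbest],
                                     error_ms = 1000 * (mt[jbest] - rt[i])))
    n_extra <- n_extra + length(js) - 1L
  }
  structure(list(effector = ml$effector, kind = kind, pairs = pairs,
                 n_ref = n_ref, n_ml = n_ml, n_missed = n_missed,
                 n_extra = n_extra),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report: %s %s, %d ref / %d ml, %d pairs, %d missed, %d extra>\n",
              x$effector, x$kind, x$n_ref, x$n_ml, nrow(x$pairs), x$n_missed,
              x$n_extra))
  if (nrow(x$pairs))
    cat(sprintf("  error: mean %.1f ms, SD %.1f ms\n", mean(x$pairs$error_ms),
                stats::sd(x$pairs$error_ms)))
  invisible(x)
}

#' Inner-cycle phases of an event list
#'
#' One (contact time, flight time) pair per complete ON -> OFF -> next-ON
#' triple: `CT = OFF - ON`, `FT = next ON - OFF`, both in milliseconds, so
#' `CT + FT` telescopes exactly to the inter-ON interval.  Trailing
#' incomplete cycles are omitted.
#'
#' @param events an [event_list].
#' @return An object of class `phase_series`: data frame with columns
#'   `on_time` (cycle anchor, s), `ct_ms`, `ft_ms`.
#' @examples
#' ev <- event_list(c(1.00, 1.42, 1.65, 2.10), c("ON", "OFF", "ON", "OFF"),
#'                  "pole")
#' compute_phases(ev)  # one cycle: CT 420 ms, FT 230 ms
#' @export
compute_phases <- function(events) {
  stopifnot(inherits(events, "event_list"))
  on <- events$time[events$kind == "ON"]
  off <- events$time[events$kind == "OFF"]
  n <- min(length(off), length(on) - 1L)
  if (n < 1L) {
    out <- data.frame(on_time = numeric(0), ct_ms = numeric(0),
                      ft_ms = numeric(0))
  } else {
    out <- data.frame(on_time = on[seq_len(n)],
                      ct_ms = 1000 * (off[seq_len(n)] - on[seq_len(n)]),
                      ft_ms = 1000 * (on[seq_len(n) + 1L] - off[seq_len(n)]))
  }
  class(out) <- c("phase_series", "data.frame")
  attr(out, "effector") <- events$effector
  out
}

#' Per-cycle contact- and flight-time errors
#'
#' Pairs cycles through matched ON events: a cycle is comparable only when
#' its ON event formed a timing pair and both the reference and the ML cycle
#' anchored there are complete.  Absolute errors are `ml - ref` in ms; the
#' relative error of a cycle is `100 * (ml - ref) / ref` with that cycle's
#' own reference phase as denominator (`mode = "per_cycle"`), or with the
#' mean reference phase as a common denominator (`mode = "pooled_mean"`).
#'
#' @param ml_events,ref_events [event_list]s for the same effector.
#' @param match_on a `match_report` of kind `"ON"` for the same two lists;
#'   computed when `NULL`.
#' @param mode relative-error normalization, `"per_cycle"` (default) or
#'   `"pooled_mean"`.
#' @return Data frame with one row per comparable cycle: `ct_error_ms`,
#'   `ft_error_ms`, `ct_rel_pct`, `ft_rel_pct`.
#' @export
phase_errors <- function(ml_events, ref_events, match_on = NULL,
                         mode = c("per_cycle", "pooled_mean")) {
  mode <- match.arg(mode)
  if (is.null(match_on)) match_on <- match_events(ml_events, ref_events, "ON")
  ml_ph <- compute_phases(ml_events)
  ref_ph <- compute_phases(ref_events)
  empty <- data.frame(ct_error_ms = numeric(0), ft_error_ms = numeric(0),
                      ct_rel_pct = numeric(0), ft_rel_pct = numeric(0))
  if (nrow(match_on$pairs) == 0L || nrow(ml_ph) == 0L || nrow(ref_ph) == 0L)
    return(empty)
  ri <- match(round(match_on$pairs$ref_time, 9), round(ref_ph$on_time, 9))
  mi <- match(round(match_on$pairs$ml_time, 9), round(ml_ph$on_time, 9))
  ok <- !is.na(ri) & !is.na(mi)
  if (!any(ok)) return(empty)
  ref_ct <- ref_ph$ct_ms[ri[ok]]; ref_ft <- ref_ph$ft_ms[ri[ok]]
  ml_ct <- ml_ph$ct_ms[mi[ok]]; ml_ft <- ml_ph$ft_ms[mi[ok]]
  den_ct <- if (mode == "per_cycle") ref_ct else mean(ref_ph$ct_ms)
  den_ft <- if (mode == "per_cycle") ref_ft else mean(ref_ph$ft_ms)
  data.frame(ct_error_ms = ml_ct - ref_ct,
             ft_error_ms = ml_ft - ref_ft,
             ct_rel_pct = 100 * (ml_ct - ref_ct) / den_ct,
             ft_rel_pct = 100 * (ml_ft - ref_ft) / den_ft)
}

#' Evaluate held-out predictions against the reference
#'
#' Runs [match_events()] (ON and OFF) and [phase_errors()] for every
#' prediction record of a [run_loso()] result — or any list of records with
#' `events_ml`, `events_ref`, `subject_id`, `sensor`, `effector` — and
#' collects per-event and per-cycle error tables.
#'
#' @param predictions a `loso_result` or its `predictions` list.
#' @param reference use `"reference"` events (force-threshold labels) or
#'   ground `"truth"` events as the comparison standard.
#' @param mode relative-error normalization, see [phase_errors()].
#' @param max_distance optional attribution gate in seconds.
#' @return An object of class `evaluation`: list of data frames `events`
#'   (one row per timing pair), `counts` (one row per trial x kind) and
#'   `phases` (one row per comparable cycle).
#' @export
evaluate_predictions <- function(predictions,
                                 reference = c("reference", "truth"),
                                 mode = c("per_cycle", "pooled_mean"),
                                 max_distance = Inf) {
  reference <- match.arg(reference)
  mode <- match.arg(mode)
  if (inherits(predictions, "loso_result"))
    predictions <- predictions$predictions
  events <- list(); counts <- list(); phases <- list()
  for (p in predictions) {
    ref <- if (reference == "reference") p$events_ref else p$truth
    mon <- match_events(p$events_ml, ref, "ON", max_distance)
    moff <- match_events(p$events_ml, ref, "OFF", max_distance)
    for (m in list(mon, moff)) {
      counts[[length(counts) + 1L]] <- data.frame(
        subject_id = p$subject_id, sensor = p$sensor, effector = p$effector,
        lap = p$lap, kind = m$kind, n_ref = m$n_ref, n_ml = m$n_ml,
        n_pairs = nrow(m$pairs), n_missed = m$n_missed, n_extra = m$n_extra)
      if (nrow(m$pairs))
        events[[length(events) + 1L]] <- data.frame(
          subject_id = p$subject_id, sensor = p$sensor,
          effector = p$effector, lap = p$lap, kind = m$kind, m$pairs)
    }
    ph <- phase_errors(p$events_ml, ref, mon, mode)
    if (nrow(ph))
      phases[[length(phases) + 1L]] <- data.frame(
        subject_id = p$subject_id, sensor = p$sensor, effector = p$effector,
        lap = p$lap, ph)
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  structure(list(
    events = bind(events, data.frame(subject_id = character(0),
                                     sensor = character(0),
                                     effector = character(0),
                                     lap = integer(0), kind = character(0),
                                     ref_time = numeric(0),
                                     ml_time = numeric(0),
                                     error_ms = numeric(0))),
    counts = bind(counts, data.frame()),
    phases = bind(phases, data.frame())),
    class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("<evaluation: %d timing pairs, %d trial-kind count rows, %d cycles>\n",
              nrow(x$events), nrow(x$counts), nrow(x$phases)))
  invisible(x)
}

#' Per-subject and pooled error summary
#'
#' Builds one row per subject plus an `"All"` row per (sensor, effector),
#' mirroring the field-report layout: reference and detected event counts,
#' ON and OFF timing error mean and SD (ms), missed and extra percentages,
#' and CT/FT error mean and SD (ms).  Percentages are
#' `100 * n_missed / n_ref` and `100 * n_extra / n_ref`.  The pooled `"All"`
#' row aggregates the union of all per-event errors (not the mean of the
#' subject means); SDs use the `n - 1` denominator.
#'
#' @param evaluation an `evaluation` from [evaluate_predictions()].
#' @return A data frame of class `error_summary`.
#' @export
summarize_errors <- function(evaluation) {
  stopifnot(inherits(evaluation, "evaluation"))
  ev <- evaluation$events
  ct <- evaluation$counts
  ph <- evaluation$phases
  groups <- unique(ct[, c("sensor", "effector")])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sen <- groups$sensor[g]; eff <- groups$effector[g]
    subs <- unique(ct$subject_id[ct$sensor == sen & ct$effector == eff])
    for (scope in c(subs, "All")) {
      pick <- function(d) {
        sel <- d$sensor == sen & d$effector == eff
        if (scope != "All") sel <- sel & d$subject_id == scope
        d[sel, , drop = FALSE]
      }
      e <- pick(ev); cc <- pick(ct); p <- if (nrow(ph)) pick(ph) else ph
      stat <- function(x) if (length(x)) c(mean(x), stats::sd(x)) else c(NA, NA)
      kindstat <- function(kind) stat(e$error_ms[e$kind == kind])
      kindpct <- function(kind, col) {
        k <- cc[cc$kind == kind, , drop = FALSE]
        if (!nrow(k) || sum(k$n_ref) == 0) return(NA_real_)
        100 * sum(k[[col]]) / sum(k$n_ref)
      }
      on <- kindstat("ON"); off <- kindstat("OFF")
      cts <- stat(p$ct_error_ms); fts <- stat(p$ft_error_ms)
      ctr <- stat(p$ct_rel_pct); ftr <- stat(p$ft_rel_pct)
      kon <- cc[cc$kind == "ON", , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        sensor = sen, effector = eff, subject = scope,
        n_ref = sum(kon$n_ref), n_ml = sum(kon$n_ml),
        on_mean_ms = on[1], on_sd_ms = on[2],
        on_missed_pct = kindpct("ON", "n_missed"),
        on_extra_pct = kindpct("ON", "n_extra"),
        off_mean_ms = off[1], off_sd_ms = off[2],
        off_missed_pct = kindpct("OFF", "n_missed"),
        off_extra_pct = kindpct("OFF", "n_extra"),
        ct_mean_ms = cts[1], ct_sd_ms = cts[2],
        ft_mean_ms = fts[1], ft_sd_ms = fts[2],
        ct_rel_mean_pct = ctr[1], ct_rel_sd_pct = ctr[2],
        ft_rel_mean_pct = ftr[1], ft_rel_sd_pct = ftr[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("error_summary", "data.frame")
  out
}
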