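#' Leave-one-subject-out run plan
#'
#' Enumerates the folds of the leave-one-subject-out protocol: every subject
#' is held out exactly once, and one network is trained per (held-out
#' subject, sensor, effector), so the plan counts
#' `length(subjects) * length(sensors) * length(effectors)` trained networks
#' (9 subjects x 3 sensors x 3 effectors = 81).
#'
#' @param subjects character vector of subject ids, or a `cohort`.
#' @param sensors sensor locations included.
#' @param effectors effectors included.
#' @return An object of class `loso_plan` with elements `subjects`,
#'   `sensors`, `effectors`, `folds` (list of `(test_subject,
#'   training_subjects)` pairs) and `n_models`.
#' @examples
#' plan <- loso_plan(sprintf("SJ%d", 1:9),
#'                   sensors = c("upper_back", "sternum", "sacrum"),
#'                   effectors = c("pole", "left_ski", "right_ski"))
#' plan$n_models  # 81
#' @export
loso_plan <- function(subjects,
                      sensors = "upper_back",
                      effectors = c("pole", "left_ski", "right_ski")) {
  if (inherits(subjects, "cohort")) subjects <- cohort_subjects(subjects)
  subjects <- as.character(subjects)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  if (anyDuplicated(subjects)) stop("duplicated subject ids")
  stopifnot(all(sensors %in% SENSOR_LOCATIONS),
            all(effectors %in% c("pole", "left_ski", "right_ski")))
  folds <- lapply(subjects, function(s)
    list(test_subject = s, training_subjects = setdiff(subjects, s)))
  structure(list(subjects = subjects, sensors = sensors,
                 effectors = effectors, folds = folds,
                 n_models = length(subjects) * length(sensors) *
                   length(effectors)),
            class = "loso_plan")
}

#' @export
print.loso_plan <- function(x, ...) {
  cat(sprintf("<loso_plan: %d subjects x %d sensors x %d effectors = %d trained networks>\n",
              length(x$subjects), length(x$sensors), length(x$effectors),
              x$n_models))
  invisible(x)
}

# Pooled per-channel moments over a list of raw 6 x T matrices.
pooled_norm <- function(raws) {
  pooled <- do.call(cbind, raws)
  mu <- rowMeans(pooled)
  sdv <- apply(pooled, 1, stats::sd)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad))
    stop(sprintf("zero-variance channel during normalization fitting: %s",
                 paste(FEATURE_CHANNELS[bad], collapse = ", ")))
  list(mean = setNames(mu, FEATURE_CHANNELS),
       sd = setNames(sdv, FEATURE_CHANNELS))
}

#' Run the leave-one-subject-out training and prediction protocol
#'
#' For every fold (held-out subject) and every requested sensor and
#' effector: reference labels are extracted from the force channels of the
#' training trials, normalization constants are fitted on the training
#' subjects only, one LSTM is trained, and predictions are produced for the
#' held-out subject's trials (optionally block-filtered).  Models that
#' predict a subject have never seen that subject's data.
#'
#' @param cohort a `cohort` from [generate_cohort()] (or an equivalent list
#'   of `trial`/`truth`/metadata entries).
#' @param plan a [loso_plan]; defaults to all subjects and sensors present
#'   in the cohort and the requested `effectors`.
#' @param config an [lstm_config]; `config$seed` is the master seed fanned
#'   out into one seed per trained network.
#' @param effectors effectors to train when `plan` is `NULL`.
#' @param postfilter apply [filter_blocks()] to the raw predictions.
#' @param max_gap,min_block block-filter parameters.
#' @param verbose print per-fold progress.
#' @return An object of class `loso_result`: list with `models` (named list
#'   of `lstm_labeler`), `predictions` (list of per-trial records with raw
#'   and filtered sequences, predicted events, reference events and ground
#'   truth) and `plan`.
#' @export
run_loso <- function(cohort, plan = NULL, config = lstm_config(),
                     effectors = "pole", postfilter = TRUE,
                     max_gap = 20L, min_block = 30L, verbose = FALSE) {
  stopifnot(length(cohort) >= 1L)
  sensors_present <- unique(vapply(cohort, `[[`, "", "sensor"))
  if (is.null(plan))
    plan <- loso_plan(cohort_subjects(cohort), sensors = sensors_present,
                      effectors = effectors)
  missing_sensor <- setdiff(plan$sensors, sensors_present)
  if (length(missing_sensor))
    stop(sprintf("plan requests sensor(s) absent from the cohort: %s",
                 paste(missing_sensor, collapse = ", ")))
  subj_of <- vapply(cohort, `[[`, "", "subject_id")
  for (s in plan$subjects)
    if (!any(subj_of == s)) stop(sprintf("subject %s has no trials", s))

  # raw (unstandardised) 100 Hz features and reference labels, once per trial
  raws <- lapply(cohort, function(e) raw_features(e$trial))
  refs <- lapply(cohort, function(e) extract_reference(e$trial))

  n_nets <- length(plan$folds) * length(plan$sensors) * length(plan$effectors)
  net_seeds <- seed_stream(config$seed, n_nets)
  net_i <- 0L
  models <- list()
  predictions <- list()

  for (fold in plan$folds) {
    for (sensor in plan$sensors) {
      tr_idx <- which(subj_of %in% fold$training_subjects &
                        vapply(cohort, `[[`, "", "sensor") == sensor)
      te_idx <- which(subj_of == fold$test_subject &
                        vapply(cohort, `[[`, "", "sensor") == sensor)
      if (!length(tr_idx))
        stop(sprintf("no training trials for fold %s / sensor %s",
                     fold$test_subject, sensor))
      norm <- pooled_norm(raws[tr_idx])
      std <- function(i) (raws[[i]] - norm$mean) / norm$sd
      tr_feats <- lapply(tr_idx, std)
      te_feats <- lapply(te_idx, std)
      for (eff in plan$effectors) {
        net_i <- net_i + 1L
        cfg <- config
        cfg$seed <- net_seeds[net_i]
        labels <- lapply(seq_along(tr_idx), function(j) {
          i <- tr_idx[j]
          ev <- refs[[i]][[eff]]
          n_force <- length(cohort[[i]]$trial$pole_force_left)
          lab <- events_to_binary(ev, n_force, ANALYSIS_RATE)
          align_labels(lab, ncol(tr_feats[[j]]))$values
        })
        if (verbose)
          message(sprintf("fold %s / %s / %s: training on %d trials",
                          fold$test_subject, sensor, eff, length(tr_idx)))
        model <- lstm_labeler(tr_feats, labels, cfg, effector = eff,
                              norm = norm,
                              training_subjects = fold$training_subjects)
        key <- paste(fold$test_subject, sensor, eff, sep = "/")
        models[[key]] <- model
        for (j in seq_along(te_idx)) {
          i <- te_idx[j]
          raw_pred <- predict(model, te_feats[[j]])
          filt <- if (postfilter)
            filter_blocks(raw_pred, max_gap, min_block) else raw_pred
          predictions[[length(predictions) + 1L]] <- list(
            subject_id = fold$test_subject, sensor = sensor, effector = eff,
            lap = cohort[[i]]$lap,
            raw = raw_pred, filtered = filt,
            events_ml = binary_to_events(filt),
            events_ref = refs[[i]][[eff]],
            truth = cohort[[i]]$truth[[eff]])
        }
      }
    }
  }
  structure(list(models = models, predictions = predictions, plan = plan),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result: %d trained networks, %d held-out trial predictions>\n",
              length(x$models), length(x$predictions)))
  print(x$plan)
  invisible(x)
}
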