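# On-disk dialects: tab-separated signal files (one per sampling rate, header
# row naming channels), a JSON event sidecar shared by ground truth,
# reference and predictions, and a JSON cohort manifest.

event_to_json_list <- function(events) {
  list(effector = events$effector,
       events = if (length(events$time))
         data.frame(kind = events$kind, time_s = round(events$time, 6))
       else data.frame(kind = character(0), time_s = numeric(0)))
}

json_list_to_event <- function(x) {
  ev <- x$events
  if (is.null(ev) || length(ev) == 0L)
    return(event_list(effector = x$effector))
  event_list(vapply(ev, function(e) as.numeric(e$time_s), 0),
             vapply(ev, function(e) as.character(e$kind), ""),
             x$effector)
}

#' Write event lists to a JSON sidecar
#'
#' One canonical on-disk event dialect is shared by ground truth, reference
#' extraction and predictions: a JSON array of
#' `{effector, events: [{kind, time_s}, ...]}` objects, times in seconds to
#' six decimals.
#'
#' @param events a single [event_list] or a (possibly named) list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (inherits(events, "event_list")) events <- list(events)
  payload <- lapply(unname(events), event_to_json_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read event lists from a JSON sidecar
#' @param path file written by [write_events()].
#' @return Named list of [event_list] (names are effectors).
#' @export
read_events <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(raw$effector)) raw <- list(raw)  # single object form
  out <- lapply(raw, json_list_to_event)
  names(out) <- vapply(out, `[[`, "", "effector")
  out
}

#' Write one trial to disk
#'
#' Emits `<id>_imu.tsv` (6 IMU channels at the IMU rate), `<id>_force.tsv`
#' (4 force channels at the force rate), `<id>_meta.json` (metadata and
#' sampling rates) and, when ground truth is supplied, `<id>_events.json`.
#'
#' @param trial a `trial_recording`.
#' @param dir output directory (created if needed).
#' @param id file-name stem.
#' @param truth optional named list of ground-truth [event_list]s.
#' @return The file-name stem `id`, invisibly.
#' @export
write_trial <- function(trial, dir, id, truth = NULL) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imu <- as.data.frame(t(rbind(trial$accel, trial$gyro)))
  names(imu) <- FEATURE_CHANNELS
  write.table(format(imu, digits = 8, trim = TRUE, scientific = FALSE),
              file.path(dir, paste0(id, "_imu.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  force <- data.frame(pole_force_left = trial$pole_force_left,
                      pole_force_right = trial$pole_force_right,
                      insole_force_left = trial$insole_force_left,
                      insole_force_right = trial$insole_force_right)
  write.table(format(force, digits = 8, trim = TRUE, scientific = FALSE),
              file.path(dir, paste0(id, "_force.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(subject_id = trial$subject_id,
               sensor_location = trial$sensor_location,
               sample_rate = trial$sample_rate,
               force_sample_rate = trial$force_sample_rate,
               bodyweight = trial$bodyweight,
               intensity = trial$intensity, friction = trial$friction)
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth))
    write_events(truth, file.path(dir, paste0(id, "_events.json")))
  invisible(id)
}

#' Read a trial written by [write_trial()]
#' @param dir directory holding the files.
#' @param id file-name stem.
#' @return List with `trial` (a `trial_recording`) and `truth` (named list
#'   of [event_list]s, or `NULL` when no event sidecar exists).
#' @export
read_trial <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  imu <- read.delim(file.path(dir, paste0(id, "_imu.tsv")))
  force <- read.delim(file.path(dir, paste0(id, "_force.tsv")))
  trial <- trial_recording(
    subject_id = meta$subject_id, sensor_location = meta$sensor_location,
    accel = t(as.matrix(imu[, 1:3])), gyro = t(as.matrix(imu[, 4:6])),
    sample_rate = meta$sample_rate,
    pole_force_left = force$pole_force_left,
    pole_force_right = force$pole_force_right,
    insole_force_left = force$insole_force_left,
    insole_force_right = force$insole_force_right,
    force_sample_rate = meta$force_sample_rate,
    bodyweight = meta$bodyweight,
    intensity = meta$intensity, friction = meta$friction)
  ev_path <- file.path(dir, paste0(id, "_events.json"))
  truth <- if (file.exists(ev_path)) read_events(ev_path) else NULL
  list(trial = trial, truth = truth)
}

#' File-name stem of a cohort entry
#' @param entry one element of a `cohort`.
#' @return `"<subject>_lap<k>_<sensor>"`.
#' @export
cohort_trial_id <- function(entry) {
  sprintf("%s_lap%d_%s", entry$subject_id, entry$lap, entry$sensor)
}

#' Write a cohort and its manifest
#'
#' Writes every trial with [write_trial()] and a `manifest.json` listing
#' trial ids and metadata.
#'
#' @param cohort a `cohort`.
#' @param dir output directory.
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(e) {
    id <- cohort_trial_id(e)
    write_trial(e$trial, dir, id, truth = e$truth)
    list(id = id, subject_id = e$subject_id, lap = e$lap, sensor = e$sensor,
         intensity = e$intensity, friction = e$friction)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from a manifest directory
#' @param dir directory holding `manifest.json` and the trial files.
#' @return A `cohort` (ground truth populated from the event sidecars).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  out <- lapply(manifest, function(m) {
    tr <- read_trial(dir, m$id)
    list(trial = tr$trial, truth = tr$truth, subject_id = m$subject_id,
         lap = m$lap, sensor = m$sensor, intensity = m$intensity,
         friction = m$friction)
  })
  structure(out, class = "cohort")
}
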