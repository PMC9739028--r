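# Synthetic skating-trial generator.
#
# A lap is a sequence of quasi-periodic movement cycles (one left-pole plant
# per cycle), optionally interrupted by a non-cyclic downhill segment in the
# middle of the lap.  Ground-truth contact events are laid out first; force
# channels (pole grips, insoles) and the six IMU channels are then rendered
# as deterministic functions of the cycle phase plus additive noise, so that
# the reference thresholds recover the truth and the IMU carries enough
# information for the events to be learnable.

SENSOR_LOCATIONS <- c("upper_back", "sternum", "sacrum")

# Fixed waveform constants: 3 harmonics per channel.  Rows: accel x,y,z then
# gyro x,y,z.  Amplitudes in m/s^2 (accel) and deg/s (gyro).
IMU_AMP <- matrix(c(3.0, 1.2, 0.5,
                    2.0, 1.0, 0.4,
                    3.5, 1.5, 0.6,
                    50,  20,  8,
                    35,  15,  6,
                    60,  25, 10), nrow = 6, byrow = TRUE)
IMU_PHASE <- matrix(c(0.0, 0.8, 1.9,
                      1.2, 2.5, 0.3,
                      2.1, 0.4, 1.1,
                      0.6, 1.7, 2.9,
                      1.9, 0.2, 1.5,
                      2.8, 1.1, 0.7), nrow = 6, byrow = TRUE)
SENSOR_AMP_FACTOR <- c(upper_back = 1.0, sternum = 0.9, sacrum = 0.8)
SENSOR_PHASE_SHIFT <- c(upper_back = 0.0, sternum = 0.3, sacrum = 0.6)

# Per-subject style: multiplicative amplitude perturbation, additive phase
# perturbation, and duty/cycle-duration multipliers.  Drawn once per subject.
draw_subject_style <- function(config, subject_seed) {
  sdv <- config$subject_style_sd
  with_seed(subject_seed, {
    list(
      amp = matrix(pmax(0.3, 1 + sdv * rnorm(18)), nrow = 6),
      phase = matrix(sdv * rnorm(18), nrow = 6),
      cycle_mult = max(0.7, 1 + (sdv / 2) * rnorm(1)),
      pole_duty_mult = min(2, max(0.5, 1 + (sdv / 4) * rnorm(1))),
      ski_duty_mult = min(1.25, max(0.5, 1 + (sdv / 8) * rnorm(1))),
      bodyweight = 9.81 * min(95, max(55, rnorm(1, 74.2, 5.5)))
    )
  })
}

neutral_style <- function(bodyweight = 9.81 * 74.2) {
  list(amp = matrix(1, 6, 3), phase = matrix(0, 6, 3), cycle_mult = 1,
       pole_duty_mult = 1, ski_duty_mult = 1, bodyweight = bodyweight)
}

# Truncated-normal cycle durations filling [seg_start, seg_end); returns
# matrix-free list(start, duration) of cycles that fit entirely.
draw_cycles <- function(seg_start, seg_end, mean_dur, sd_dur) {
  starts <- numeric(0)
  durs <- numeric(0)
  pos <- seg_start
  repeat {
    d <- if (sd_dur > 0) {
      z <- rnorm(1)
      while (abs(z) > 3) z <- rnorm(1)
      max(0.4, mean_dur + sd_dur * z)
    } else mean_dur
    if (pos + d > seg_end + 1e-12) break
    starts <- c(starts, pos)
    durs <- c(durs, d)
    pos <- pos + d
  }
  list(start = starts, duration = durs)
}

# Merge overlapping contact intervals and those separated by sub-resolution
# gaps (< min_len), clip to [0, t_max] and drop contacts shorter than
# `min_len`: gaps or contacts shorter than a few force samples would be
# invisible to the force channels and unrecoverable by thresholding.
sanitize_contacts <- function(on, off, t_max, min_len = 0.03) {
  if (length(on) == 0L) return(list(on = numeric(0), off = numeric(0)))
  o <- order(on)
  on <- on[o]; off <- pmin(off[o], t_max)
  keep_on <- on[1]; keep_off <- off[1]
  res_on <- numeric(0); res_off <- numeric(0)
  if (length(on) > 1L) {
    for (k in 2:length(on)) {
      if (on[k] <= keep_off + min_len) {
        keep_off <- max(keep_off, off[k])
      } else {
        res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
        keep_on <- on[k]; keep_off <- off[k]
      }
    }
  }
  res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
  ok <- res_off >= res_on + min_len
  list(on = res_on[ok], off = res_off[ok])
}

contacts_to_events <- function(contacts, effector) {
  n <- length(contacts$on)
  if (n == 0L) return(event_list(effector = effector))
  time <- as.vector(rbind(contacts$on, contacts$off))
  kind <- rep(c("ON", "OFF"), n)
  event_list(time, kind, effector)
}

events_to_contacts <- function(events) {
  on <- events$time[events$kind == "ON"]
  off <- events$time[events$kind == "OFF"]
  if (length(off) < length(on)) on <- on[seq_along(off)]
  list(on = on, off = off)
}

# Render a force channel from contact intervals.  `shape` is a function of
# the normalised within-contact position u in [0, 1) returning force as a
# fraction of bodyweight; outside contact the force is near zero.  The
# rendered trace is clamped so that it sits above `floor_frac` of bodyweight
# at every in-contact sample and below 1% of bodyweight outside contact,
# making threshold recovery of the truth exact to one sample.
render_force <- function(contacts, n, rate, bodyweight, shape, floor_frac,
                         noise_sd_frac = 0.0015) {
  t <- (seq_len(n) - 1) / rate
  f <- numeric(n)
  inside <- logical(n)
  for (k in seq_along(contacts$on)) {
    m <- t >= contacts$on[k] - 1e-12 & t < contacts$off[k] - 1e-12
    u <- (t[m] - contacts$on[k]) / (contacts$off[k] - contacts$on[k])
    f[m] <- bodyweight * shape(u)
    inside[m] <- TRUE
  }
  f <- f + rnorm(n, 0, noise_sd_frac * bodyweight)
  f[inside] <- pmax(f[inside], floor_frac * bodyweight)
  f[!inside] <- pmin(pmax(f[!inside], 0), 0.0099 * bodyweight)
  f
}

pole_shape <- function(peak) {
  function(u) 0.08 + (peak - 0.08) * sin(pi * u)
}
insole_shape <- function(peak) {
  function(u) 0.10 + (peak - 0.10) * pmin(1, u / 0.1, (1 - u) / 0.1)
}

#' Generate one synthetic skating trial
#'
#' Produces one lap of aligned multi-channel signals (6 IMU channels at the
#' sensor's native rate, pole-grip and insole forces at the force rate) plus
#' the ground-truth contact events for the pole, left ski and right ski.
#' Signals are deterministic functions of the per-cycle phase plus additive
#' Gaussian noise; force channels exceed the reference thresholds exactly
#' during ground-truth contact.  The upper-back sensor records natively at
#' 100 Hz; sternum and sacrum sensors at `config$sample_rate_imu`.
#'
#' @param config a [sim_config].
#' @param subject_id subject label, e.g. `"SJ1"`.
#' @param seed integer seed for this trial's random draws (defaults to a
#'   deterministic function of the config seed and the subject id).
#' @param sensor sensor location, one of `"upper_back"`, `"sternum"`,
#'   `"sacrum"`.
#' @param intensity `"low"` or `"high"` (high scales waveform amplitude and
#'   pole peak force).
#' @param friction roller-ski wheel type, `"type1"` (low) or `"type3"`
#'   (high rolling resistance); mild amplitude effect.
#' @param style per-subject style parameters (as drawn by the cohort
#'   generator); `NULL` draws them from the config seed and subject id.
#' @return A list with elements `trial` (a `trial_recording`) and `truth`
#'   (named list of ground-truth [event_list]s: `pole`, `left_ski`,
#'   `right_ski`).
#' @examples
#' cfg <- sim_config(lap_duration = 20, seed = 7)
#' tr <- generate_trial(cfg, "SJ1")
#' tr$truth$pole
#' @export
generate_trial <- function(config, subject_id, seed = NULL,
                           sensor = c("upper_back", "sternum", "sacrum"),
                           intensity = c("low", "high"),
                           friction = c("type1", "type3"),
                           style = NULL) {
  validate_sim_config(config)
  sensor <- match.arg(sensor)
  intensity <- match.arg(intensity)
  friction <- match.arg(friction)
  if (is.null(seed))
    seed <- (config$seed * 7919L +
             sum(utf8ToInt(as.character(subject_id)))) %% .Machine$integer.max
  if (is.null(style)) {
    style <- if (config$subject_style_sd > 0)
      draw_subject_style(config, seed + 1L) else neutral_style()
  }
  with_seed(seed, generate_trial_impl(config, subject_id, sensor, intensity,
                                      friction, style))
}

generate_trial_impl <- function(config, subject_id, sensor, intensity,
                                friction, style) {
  L <- config$lap_duration
  f_rate <- config$sample_rate_force
  imu_rate <- if (sensor == "upper_back") 100 else config$sample_rate_imu
  n_f <- round(L * f_rate)
  n_i <- round(L * imu_rate)
  bw <- style$bodyweight
  t_max <- L - 2 / f_rate  # all contacts end before the trace does

  # --- segment layout: cyclic / downhill / cyclic ---
  d <- config$downhill_fraction * L
  segs <- if (d > 0) {
    c1 <- (L - d) / 2
    list(cyclic = list(c(0, c1), c(c1 + d, L)), downhill = c(c1, c1 + d))
  } else list(cyclic = list(c(0, L)), downhill = NULL)

  mean_dur <- config$cycle_duration_mean * style$cycle_mult
  p_duty <- min(0.95, max(0.05, config$pole_duty * style$pole_duty_mult))
  s_duty <- min(0.95, max(0.05, config$ski_duty * style$ski_duty_mult))

  cyc_start <- numeric(0); cyc_dur <- numeric(0)
  for (sg in segs$cyclic) {
    cy <- draw_cycles(sg[1], sg[2], mean_dur, config$cycle_duration_sd)
    cyc_start <- c(cyc_start, cy$start)
    cyc_dur <- c(cyc_dur, cy$duration)
  }

  # --- ground-truth contacts ---
  pole_on <- cyc_start
  pole_off <- cyc_start + p_duty * cyc_dur
  ls_on <- cyc_start + 0.05 * cyc_dur
  ls_off <- ls_on + s_duty * cyc_dur
  rs_on <- cyc_start + 0.55 * cyc_dur
  rs_off <- rs_on + s_duty * cyc_dur
  if (!is.null(segs$downhill)) {
    ls_on <- c(ls_on, segs$downhill[1]); ls_off <- c(ls_off, segs$downhill[2])
    rs_on <- c(rs_on, segs$downhill[1]); rs_off <- c(rs_off, segs$downhill[2])
  }
  pole_c <- sanitize_contacts(pole_on, pole_off, t_max)
  ls_c <- sanitize_contacts(ls_on, ls_off, t_max)
  rs_c <- sanitize_contacts(rs_on, rs_off, t_max)
  truth <- list(pole = contacts_to_events(pole_c, "pole"),
                left_ski = contacts_to_events(ls_c, "left_ski"),
                right_ski = contacts_to_events(rs_c, "right_ski"))

  # --- force channels ---
  pole_peak <- if (intensity == "high") 1.2 else 1.0
  insole_peak <- if (intensity == "high") 1.15 else 1.0
  noise_frac <- if (config$noise_sd_accel > 0 || config$noise_sd_gyro > 0)
    0.0015 else 0
  pole_force_left <- render_force(pole_c, n_f, f_rate, bw,
                                  pole_shape(pole_peak), 0.06, noise_frac)
  pole_force_right <- render_force(pole_c, n_f, f_rate, bw,
                                   pole_shape(0.95 * pole_peak), 0.06,
                                   noise_frac)
  insole_force_left <- render_force(ls_c, n_f, f_rate, bw,
                                    insole_shape(insole_peak), 0.08,
                                    noise_frac)
  insole_force_right <- render_force(rs_c, n_f, f_rate, bw,
                                     insole_shape(insole_peak), 0.08,
                                     noise_frac)

  # --- IMU channels ---
  t_i <- (seq_len(n_i) - 1) / imu_rate
  phase <- rep(NA_real_, n_i)
  if (length(cyc_start)) {
    idx <- findInterval(t_i, cyc_start)
    ok <- idx > 0
    ok[ok] <- t_i[ok] < cyc_start[idx[ok]] + cyc_dur[idx[ok]]
    phase[ok] <- (t_i[ok] - cyc_start[idx[ok]]) / cyc_dur[idx[ok]]
  }
  amp_fac <- SENSOR_AMP_FACTOR[[sensor]] *
    (if (intensity == "high") 1.25 else 1) *
    (if (friction == "type3") 1.05 else 1)
  ph_shift <- SENSOR_PHASE_SHIFT[[sensor]]
  sig <- matrix(0, nrow = 6, ncol = n_i)
  cyc <- !is.na(phase)
  for (ch in 1:6) {
    s <- numeric(n_i)
    for (k in 1:3) {
      a <- IMU_AMP[ch, k] * style$amp[ch, k] * amp_fac
      p <- IMU_PHASE[ch, k] + style$phase[ch, k] + ph_shift
      s[cyc] <- s[cyc] + a * sin(2 * pi * k * phase[cyc] + p)
    }
    # low-amplitude rolling vibration where there is no cyclic motion
    s[!cyc] <- 0.1 * IMU_AMP[ch, 1] * amp_fac *
      sin(2 * pi * 8 * t_i[!cyc] + ch)
    sig[ch, ] <- s
  }
  sig[3, ] <- sig[3, ] + 9.81  # gravity on the longitudinal accelerometer axis
  if (config$noise_sd_accel > 0)
    sig[1:3, ] <- sig[1:3, ] + rnorm(3 * n_i, 0, config$noise_sd_accel)
  if (config$noise_sd_gyro > 0)
    sig[4:6, ] <- sig[4:6, ] + rnorm(3 * n_i, 0, config$noise_sd_gyro)

  trial <- trial_recording(subject_id = subject_id, sensor_location = sensor,
                           accel = sig[1:3, , drop = FALSE],
                           gyro = sig[4:6, , drop = FALSE],
                           sample_rate = imu_rate,
                           pole_force_left = pole_force_left,
                           pole_force_right = pole_force_right,
                           insole_force_left = insole_force_left,
                           insole_force_right = insole_force_right,
                           force_sample_rate = f_rate, bodyweight = bw,
                           intensity = intensity, friction = friction)
  list(trial = trial, truth = truth)
}

#' Trial recording container
#'
#' One lap's aligned multi-channel signals plus metadata: 3-axis
#' accelerometer and gyroscope from one trunk-mounted IMU, pole-grip and
#' insole force channels (reference only), subject bodyweight and lap
#' conditions.
#'
#' @param subject_id subject label.
#' @param sensor_location `"upper_back"`, `"sternum"` or `"sacrum"`.
#' @param accel,gyro 3 x T numeric matrices (m/s^2, deg/s).
#' @param sample_rate IMU sampling rate in Hz.
#' @param pole_force_left,pole_force_right,insole_force_left,insole_force_right
#'   force channels in newtons, all the same length.
#' @param force_sample_rate force sampling rate in Hz.
#' @param bodyweight subject bodyweight in newtons.
#' @param intensity `"low"` or `"high"`.
#' @param friction `"type1"` or `"type3"`.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, sensor_location, accel, gyro,
                            sample_rate, pole_force_left, pole_force_right,
                            insole_force_left, insole_force_right,
                            force_sample_rate, bodyweight,
                            intensity = "low", friction = "type1") {
  if (!is.matrix(accel) || nrow(accel) != 3L)
    stop("`accel` must be a 3 x T matrix")
  if (!is.matrix(gyro) || nrow(gyro) != 3L)
    stop("`gyro` must be a 3 x T matrix")
  if (ncol(accel) != ncol(gyro))
    stop("`accel` and `gyro` must have the same number of samples")
  nf <- length(pole_force_left)
  if (length(pole_force_right) != nf || length(insole_force_left) != nf ||
      length(insole_force_right) != nf)
    stop("force channels must all have the same length")
  if (!is.numeric(bodyweight) || bodyweight <= 0)
    stop("`bodyweight` must be positive")
  if (!sensor_location %in% SENSOR_LOCATIONS)
    stop("unknown `sensor_location`")
  structure(list(subject_id = as.character(subject_id),
                 sensor_location = sensor_location,
                 accel = accel, gyro = gyro,
                 sample_rate = as.numeric(sample_rate),
                 pole_force_left = as.numeric(pole_force_left),
                 pole_force_right = as.numeric(pole_force_right),
                 insole_force_left = as.numeric(insole_force_left),
                 insole_force_right = as.numeric(insole_force_right),
                 force_sample_rate = as.numeric(force_sample_rate),
                 bodyweight = as.numeric(bodyweight),
                 intensity = intensity, friction = friction),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording: %s @ %s, %d IMU samples @ %g Hz, %d force samples @ %g Hz>\n",
              x$subject_id, x$sensor_location, ncol(x$accel), x$sample_rate,
              length(x$pole_force_left), x$force_sample_rate))
  cat(sprintf("  bodyweight %.0f N, intensity %s, friction %s\n",
              x$bodyweight, x$intensity, x$friction))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects * laps_per_subject` trials per requested sensor.
#' Per-subject style parameters (waveform perturbations, duty and cycle
#' multipliers, bodyweight) are drawn once per subject and reused across that
#' subject's laps.  Lap intensity is low for the first half of each subject's
#' laps and high for the second half; ski friction type alternates between
#' laps.  For a given lap, all sensors share the same ground truth and force
#' channels (one physical lap observed by several sensors).
#'
#' @param config a [sim_config].
#' @param sensors character vector of sensor locations to render per lap.
#' @return An object of class `cohort`: a list of entries, each with elements
#'   `trial`, `truth`, `subject_id`, `lap`, `sensor`, `intensity`,
#'   `friction`; the config is attached as an attribute.
#' @examples
#' co <- generate_cohort(sim_config(n_subjects = 2, laps_per_subject = 1,
#'                                  lap_duration = 15))
#' length(co)
#' @export
generate_cohort <- function(config, sensors = "upper_back") {
  validate_sim_config(config)
  stopifnot(all(sensors %in% SENSOR_LOCATIONS))
  subjects <- sprintf("SJ%d", seq_len(config$n_subjects))
  subj_seeds <- seed_stream(config$seed, config$n_subjects)
  out <- list()
  for (i in seq_along(subjects)) {
    style <- if (config$subject_style_sd > 0)
      draw_subject_style(config, subj_seeds[i]) else neutral_style()
    lap_seeds <- seed_stream(subj_seeds[i], config$laps_per_subject)
    for (lap in seq_len(config$laps_per_subject)) {
      intensity <- if (lap <= config$laps_per_subject / 2) "low" else "high"
      friction <- if (lap %% 2L == 1L) "type1" else "type3"
      for (sensor in sensors) {
        tr <- generate_trial(config, subjects[i], seed = lap_seeds[lap],
                             sensor = sensor, intensity = intensity,
                             friction = friction, style = style)
        out[[length(out) + 1L]] <- list(trial = tr$trial, truth = tr$truth,
                                        subject_id = subjects[i], lap = lap,
                                        sensor = sensor,
                                        intensity = intensity,
                                        friction = friction)
      }
    }
  }
  structure(out, class = "cohort", config = config)
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cohort: %d trials (%d subjects x %d laps), sensors: %s>\n",
              length(x), cfg$n_subjects, cfg$laps_per_subject,
              paste(unique(vapply(x, `[[`, "", "sensor")), collapse = ", ")))
  invisible(x)
}

#' Subjects present in a cohort
#' @param cohort a `cohort`.
#' @return Character vector of unique subject ids, in order of appearance.
#' @export
cohort_subjects <- function(cohort) {
  unique(vapply(cohort, `[[`, "", "subject_id"))
}
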