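#' Configuration for the synthetic skating-trial generator
#'
#' Defines the statistical conditions of a simulated roller-ski skating
#' session: cohort size, lap length, sampling rates, cycle-duration
#' distribution, pole/ski duty fractions, sensor noise, downhill (non-cyclic)
#' fraction and subject-to-subject style variation.  The defaults target the
#' field conditions the method was developed for: a 1.078 s mean cycle with a
#' pole duty fraction of 0.393 gives a mean pole contact time of 424 ms and a
#' pole swing time of 654 ms; the ski duty of 0.77 gives a ski contact time
#' near 829 ms.
#'
#' @param n_subjects number of simulated athletes.
#' @param laps_per_subject laps per athlete (first half low intensity, second
#'   half high, ski friction type alternating, mirroring a 2 low + 2 high lap
#'   protocol when 4).
#' @param lap_duration lap length in seconds.
#' @param sample_rate_imu IMU sampling rate in Hz for chest/sacrum sensors
#'   (the upper-back sensor records natively at 100 Hz).
#' @param sample_rate_force force (pole grip and insole) sampling rate in Hz.
#' @param cycle_duration_mean,cycle_duration_sd mean and SD of the cycle
#'   duration in seconds; durations are drawn from a normal truncated at
#'   3 SD and floored at 0.4 s.
#' @param pole_duty fraction of the cycle spent in pole ground contact.
#' @param ski_duty fraction of the cycle spent in ski ground contact (left
#'   and right skis are offset by half a cycle and may overlap).
#' @param noise_sd_accel accelerometer noise SD in m/s^2.
#' @param noise_sd_gyro gyroscope noise SD in deg/s.
#' @param downhill_fraction fraction of the lap spent in a non-cyclic
#'   downhill segment: no pole contacts, skis continuously on the ground.
#' @param subject_style_sd scale of per-subject perturbation of waveform
#'   amplitudes, phases, duty and cycle duration.
#' @param seed master seed; every derived random draw fans out from it.
#' @return An object of class `sim_config` (validated named list).
#' @examples
#' cfg <- sim_config(n_subjects = 2, laps_per_subject = 1, lap_duration = 30)
#' cfg$cycle_duration_mean * cfg$pole_duty  # mean pole contact time, s
#' @export
sim_config <- function(n_subjects = 9L,
                       laps_per_subject = 4L,
                       lap_duration = 300,
                       sample_rate_imu = 512,
                       sample_rate_force = 100,
                       cycle_duration_mean = 1.078,
                       cycle_duration_sd = 0.08,
                       pole_duty = 0.393,
                       ski_duty = 0.77,
                       noise_sd_accel = 1.0,
                       noise_sd_gyro = 20,
                       downhill_fraction = 0.10,
                       subject_style_sd = 0.10,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              laps_per_subject = as.integer(laps_per_subject),
              lap_duration = as.numeric(lap_duration),
              sample_rate_imu = as.numeric(sample_rate_imu),
              sample_rate_force = as.numeric(sample_rate_force),
              cycle_duration_mean = as.numeric(cycle_duration_mean),
              cycle_duration_sd = as.numeric(cycle_duration_sd),
              pole_duty = as.numeric(pole_duty),
              ski_duty = as.numeric(ski_duty),
              noise_sd_accel = as.numeric(noise_sd_accel),
              noise_sd_gyro = as.numeric(noise_sd_gyro),
              downhill_fraction = as.numeric(downhill_fraction),
              subject_style_sd = as.numeric(subject_style_sd),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  need_pos <- c("n_subjects", "laps_per_subject", "lap_duration",
                "sample_rate_imu", "sample_rate_force", "cycle_duration_mean")
  for (f in need_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("invalid sim_config: `%s` must be a positive scalar", f))
  }
  need_nonneg <- c("cycle_duration_sd", "noise_sd_accel", "noise_sd_gyro",
                   "subject_style_sd")
  for (f in need_nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("invalid sim_config: `%s` must be non-negative", f))
  }
  for (f in c("pole_duty", "ski_duty")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop(sprintf("invalid sim_config: `%s` must lie in (0, 1)", f))
  }
  v <- cfg$downhill_fraction
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1)
    stop("invalid sim_config: `downhill_fraction` must lie in [0, 1)")
  if (is.na(cfg$seed))
    stop("invalid sim_config: `seed` must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d subjects x %d laps of %g s\n",
              x$n_subjects, x$laps_per_subject, x$lap_duration))
  cat(sprintf("  cycle: %.3f +/- %.3f s, pole duty %.3f, ski duty %.3f\n",
              x$cycle_duration_mean, x$cycle_duration_sd,
              x$pole_duty, x$ski_duty))
  cat(sprintf("  rates: IMU %g Hz (upper back 100 Hz), force %g Hz\n",
              x$sample_rate_imu, x$sample_rate_force))
  cat(sprintf("  noise: accel %g m/s^2, gyro %g deg/s; downhill %.0f%%; style sd %.2f; seed %d\n",
              x$noise_sd_accel, x$noise_sd_gyro, 100 * x$downhill_fraction,
              x$subject_style_sd, x$seed))
  invisible(x)
}
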