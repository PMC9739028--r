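test_that("sim_config validates fields by name", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(pole_duty = 1.2), "pole_duty")
  expect_error(sim_config(ski_duty = 0), "ski_duty")
  expect_error(sim_config(lap_duration = -5), "lap_duration")
  expect_error(sim_config(downhill_fraction = 1), "downhill_fraction")
  expect_error(sim_config(noise_sd_accel = -1), "noise_sd_accel")
})

test_that("noise-free deterministic limit: CT equals duty times duration", {
  cfg <- clean_config()
  tr <- generate_trial(cfg, "SJ1")
  ph <- compute_phases(tr$truth$pole)
  expect_gt(nrow(ph), 20)
  expect_equal(ph$ct_ms, rep(1000 * cfg$pole_duty * cfg$cycle_duration_mean,
                             nrow(ph)), tolerance = 1e-9)
  # strictly periodic: consecutive inter-ON intervals identical
  on <- tr$truth$pole$time[tr$truth$pole$kind == "ON"]
  expect_equal(diff(on), rep(cfg$cycle_duration_mean, length(on) - 1),
               tolerance = 1e-9)
})

test_that("generation is bit-identical under a repeated seed", {
  cfg <- tiny_config(seed = 7)
  a <- generate_trial(cfg, "SJ1", seed = 123)
  b <- generate_trial(cfg, "SJ1", seed = 123)
  expect_identical(a$trial$accel, b$trial$accel)
  expect_identical(a$trial$pole_force_left, b$trial$pole_force_left)
  expect_identical(a$truth, b$truth)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
})

test_that("mean generated pole contact time tracks duty x cycle duration", {
  # 424 ms = 0.393 * 1078 ms; averaged over many cycles and subjects
  cfg <- sim_config(n_subjects = 10, laps_per_subject = 1, lap_duration = 80,
                    subject_style_sd = 0.05, seed = 21)
  cts <- unlist(lapply(sprintf("SJ%d", 1:10), function(s) {
    tr <- generate_trial(cfg, s)
    compute_phases(tr$truth$pole)$ct_ms
  }))
  expect_gt(length(cts), 500)
  expect_lt(abs(mean(cts) - 424) / 424, 0.02)
})

test_that("cohort structure: counts, per-subject styles, lap metadata", {
  cfg <- sim_config(n_subjects = 3, laps_per_subject = 4, lap_duration = 10,
                    seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co, 12L)
  expect_identical(cohort_subjects(co), sprintf("SJ%d", 1:3))
  # intensity split and friction alternation
  sj1 <- Filter(function(e) e$subject_id == "SJ1", co)
  expect_identical(vapply(sj1, `[[`, "", "intensity"),
                   c("low", "low", "high", "high"))
  expect_identical(vapply(sj1, `[[`, "", "friction"),
                   c("type1", "type3", "type1", "type3"))
  # same subject's bodyweight (a style parameter) is constant across laps
  bw <- vapply(sj1, function(e) e$trial$bodyweight, 0)
  expect_identical(bw, rep(bw[1], 4))
  # different subjects get different styles
  bw_all <- vapply(co, function(e) e$trial$bodyweight, 0)
  expect_identical(length(unique(bw_all)), 3L)
})

test_that("zero style spread makes subjects' waveform templates identical", {
  cfg <- sim_config(n_subjects = 2, laps_per_subject = 1, lap_duration = 10,
                    subject_style_sd = 0, noise_sd_accel = 0,
                    noise_sd_gyro = 0, cycle_duration_sd = 0, seed = 3)
  co <- generate_cohort(cfg)
  expect_identical(co[[1]]$trial$accel, co[[2]]$trial$accel)
  expect_identical(co[[1]]$trial$gyro, co[[2]]$trial$gyro)
})

test_that("phase accounting: CT + FT telescopes to the inter-ON interval", {
  tr <- generate_trial(tiny_config(), "SJ1", seed = 9)
  for (eff in names(tr$truth)) {
    ev <- tr$truth[[eff]]
    ph <- compute_phases(ev)
    if (!nrow(ph)) next
    on <- ev$time[ev$kind == "ON"]
    expect_equal(ph$ct_ms + ph$ft_ms, 1000 * diff(on)[seq_len(nrow(ph))],
                 tolerance = 1e-9)
  }
})

test_that("downhill segment has no pole cycles and one long ski contact", {
  cfg <- sim_config(n_subjects = 1, laps_per_subject = 1, lap_duration = 40,
                    downhill_fraction = 0.3, seed = 17)
  tr <- generate_trial(cfg, "SJ1")
  L <- cfg$lap_duration
  dh <- c((L - 0.3 * L) / 2, (L + 0.3 * L) / 2)
  pole_on <- tr$truth$pole$time[tr$truth$pole$kind == "ON"]
  expect_false(any(pole_on >= dh[1] & pole_on < dh[2]))
  ski <- compute_phases(tr$truth$left_ski)
  expect_gte(max(ski$ct_ms), 0.3 * L * 1000 - 1)
  # pole force stays under the 5% threshold throughout the downhill
  t_f <- (seq_along(tr$trial$pole_force_left) - 1) / tr$trial$force_sample_rate
  in_dh <- t_f >= dh[1] & t_f < dh[2]
  expect_true(all(tr$trial$pole_force_left[in_dh] <
                    0.05 * tr$trial$bodyweight))
})
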