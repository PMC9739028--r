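test_that("resampling lengths, identity and spectral fidelity", {
  x <- sin(2 * pi * 2 * (0:5119) / 512)  # 2 Hz tone, 10 s at 512 Hz
  y <- resample_signal(x, 512, 100)
  expect_length(y, 1000L)
  ref <- sin(2 * pi * 2 * (0:999) / 100)
  expect_gt(stats::cor(y, ref), 0.999)
  expect_identical(resample_signal(x, 512, 512), x)
  expect_error(resample_signal(numeric(0), 512, 100), "empty")
})

test_that("resampling preserves a constant series", {
  z <- resample_signal(rep(3.5, 512), 512, 100)
  expect_lt(max(abs(z - 3.5)), 1e-9)
})

test_that("feature assembly standardises with training-only constants", {
  tr <- generate_trial(tiny_config(), "SJ1", seed = 2)$trial
  f <- assemble_features(tr)
  expect_identical(nrow(f$values), 6L)
  expect_lt(max(abs(rowMeans(f$values))), 1e-9)
  expect_lt(max(abs(apply(f$values, 1, sd) - 1)), 1e-9)
  expect_identical(rownames(f$values),
                   c("accel_x", "accel_y", "accel_z",
                     "gyro_x", "gyro_y", "gyro_z"))

  # constants fitted on training data are unaffected by test data, and a
  # constant test channel stays finite under training constants
  te <- generate_trial(tiny_config(), "SJ2", seed = 3)$trial
  norm1 <- fit_normalization(list(tr))
  te2 <- te
  te2$accel[1, ] <- 0
  norm2 <- fit_normalization(list(tr))
  expect_identical(norm1, norm2)
  f_te <- assemble_features(te2, norm = norm1)
  expect_true(all(is.finite(f_te$values)))

  # zero-variance channel during fitting is rejected with the channel named
  bad <- tr
  bad$gyro[2, ] <- 5
  expect_error(fit_normalization(list(bad)), "gyro_y")
})

test_that("label alignment pads or truncates by at most two samples", {
  b <- binary_phase(c(0L, 1L, 1L, 0L), 100, "pole")
  expect_identical(align_labels(b, 4L)$values, b$values)
  expect_identical(align_labels(b, 3L)$values, c(0L, 1L, 1L))
  expect_identical(align_labels(b, 6L)$values, c(0L, 1L, 1L, 0L, 0L, 0L))
  expect_error(align_labels(b, 7L), "more than 2 samples")
})
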