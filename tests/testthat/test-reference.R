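test_that("threshold crossing follows the stated ON/OFF convention", {
  f <- c(rep(0, 10), rep(100, 50), rep(0, 40))
  ev <- extract_events(f, 100, 800, 0.05)
  expect_equal(ev$time, c(0.10, 0.60))
  expect_equal(ev$kind, c("ON", "OFF"))

  expect_length(extract_events(rep(0, 100), 100, 800, 0.05), 0L)

  # constant exactly at threshold: in contact from sample 0, never released
  ev2 <- extract_events(rep(40, 100), 100, 800, 0.05)
  expect_equal(ev2$time, 0)
  expect_equal(ev2$kind, "ON")

  expect_length(extract_events(numeric(0), 100, 800, 0.05), 0L)
  expect_error(extract_events(c(1, NA), 100, 800, 0.05), "non-finite")
  expect_error(extract_events(f, 100, -1, 0.05), "bodyweight")
  expect_error(extract_events(f, 100, 800, 1.5), "threshold_fraction")
})

test_that("extract_events output always alternates ON/OFF", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      f <- abs(rnorm(500, 30, 30))
      ev <- extract_events(f, 100, 800, 0.05)
      if (length(ev)) {
        expect_identical(ev$kind, rep_len(c("ON", "OFF"), length(ev)))
        expect_true(all(diff(ev$time) > 0))
      }
    }
  })
})

test_that("reference extraction recovers generator truth within one sample", {
  cfg <- tiny_config()
  tr <- generate_trial(cfg, "SJ1", seed = 13)
  ref <- extract_reference(tr$trial)
  for (eff in names(ref)) {
    expect_identical(length(ref[[eff]]), length(tr$truth[[eff]]))
    expect_identical(ref[[eff]]$kind, tr$truth[[eff]]$kind)
    err <- abs(ref[[eff]]$time - tr$truth[[eff]]$time) *
      tr$trial$force_sample_rate
    expect_lt(max(err), 1 + 1e-9)
  }
})
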