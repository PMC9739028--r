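test_that("event_list enforces alternation, ordering and finiteness", {
  ev <- event_list(c(0.1, 0.6), c("ON", "OFF"), "pole")
  expect_s3_class(ev, "event_list")
  expect_length(ev, 2L)
  expect_error(event_list(c(0.6, 0.1), c("ON", "OFF")), "increasing")
  expect_error(event_list(c(0.1, 0.6), c("OFF", "ON")), "alternate")
  expect_error(event_list(c(0.1, 0.6), c("ON", "ON")), "alternate")
  expect_error(event_list(c(0.1, NA), c("ON", "OFF")), "finite")
  expect_length(event_list(effector = "left_ski"), 0L)
})

test_that("events_to_binary paints half-open sample intervals", {
  ev <- event_list(c(0.10, 0.60), c("ON", "OFF"), "pole")
  b <- events_to_binary(ev, 100, 100)
  expect_identical(which(b$values == 1L), 11:60)  # samples 10..59, 0-based
  expect_identical(sum(events_to_binary(event_list(effector = "pole"),
                                        50, 100)$values), 0L)
  # final unpaired ON paints to the end
  b2 <- events_to_binary(event_list(0.10, "ON", "pole"), 100, 100)
  expect_identical(which(b2$values == 1L), 11:100)
  expect_error(events_to_binary(ev, 50, 100), "beyond the sequence end")
})

test_that("binary_to_events scans transitions", {
  v <- integer(100); v[11:60] <- 1L
  ev <- binary_to_events(binary_phase(v, 100, "pole"))
  expect_equal(ev$time, c(0.10, 0.60))
  expect_equal(ev$kind, c("ON", "OFF"))
  all1 <- binary_to_events(binary_phase(rep(1L, 50), 100, "pole"))
  expect_equal(all1$time, 0)
  expect_equal(all1$kind, "ON")
  alt <- binary_to_events(binary_phase(rep(c(1L, 0L), 5), 100, "pole"))
  expect_length(alt, 10L)  # one ON/OFF pair per 1-sample block
  expect_equal(alt$kind, rep(c("ON", "OFF"), 5))
  # a trailing 1-sample block at the end stays open (no OFF)
  tail1 <- binary_to_events(binary_phase(rep(c(0L, 1L), 5), 100, "pole"))
  expect_length(tail1, 9L)
})

test_that("events -> binary -> events is the identity inside the window", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      ev <- rand_event_list(dur = 8)
      back <- binary_to_events(events_to_binary(ev, 800, 100))
      expect_equal(back$time, ev$time)
      expect_identical(back$kind, ev$kind)
    }
  })
})
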