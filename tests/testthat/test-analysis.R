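ev <- function(t, kind, eff = "pole") event_list(t, kind, eff)
ons <- function(t, eff = "pole")
  event_list(t, rep(c("ON", "OFF"), length.out = length(t)), eff)

# build an ON-only comparison by interleaving dummy OFFs is awkward; instead
# events at odd positions are ON by construction, so tests place target times
# at ON slots with OFFs in between.

test_that("nearest-reference attribution, missed, extra and the tie rule", {
  ref <- ev(c(1.00, 1.50, 2.00, 2.50, 3.00), c("ON", "OFF", "ON", "OFF", "ON"))
  ml <- ev(c(1.05, 1.50, 1.98), c("ON", "OFF", "ON"))
  m <- match_events(ml, ref, "ON")
  expect_identical(m$n_ref, 3L)
  expect_identical(m$n_ml, 2L)
  expect_equal(m$pairs$error_ms, c(50, -20))
  expect_identical(m$n_missed, 1L)  # 3.00 unattributed
  expect_identical(m$n_extra, 0L)
  expect_identical(m$n_ref, nrow(m$pairs) + m$n_missed)

  # identical lists: zero errors, nothing missed or extra
  m0 <- match_events(ref, ref, "ON")
  expect_true(all(m0$pairs$error_ms == 0))
  expect_identical(m0$n_missed + m0$n_extra, 0L)

  # equidistant ML events: earlier ML event pairs, the other is extra
  ref1 <- ev(1.00, "ON")
  ml2 <- event_list(c(0.90, 1.05, 1.10), c("ON", "OFF", "ON"), "pole")
  mt <- match_events(ml2, ref1, "ON")
  expect_equal(mt$pairs$error_ms, -100)
  expect_identical(mt$n_extra, 1L)
  expect_identical(mt$n_missed, 0L)

  expect_error(match_events(ev(1, "ON", "pole"), ev(1, "ON", "left_ski"),
                            "ON"),
               "effector mismatch")
})

test_that("attribution matches the brute-force oracle on random small sets", {
  withr::with_seed(31, {
    for (rep in 1:200) {
      n_ref <- sample(1:4, 1)
      n_ml <- sample(1:4, 1)
      rt <- sort(sample(seq(0.5, 20, by = 0.5), n_ref))
      mt <- sort(sample(seq(0.25, 20, by = 0.5), n_ml))
      ref <- ons(as.vector(rbind(rt, rt + 0.2)))
      ml <- ons(as.vector(rbind(mt, mt + 0.2)))
      got <- match_events(ml, ref, "ON")
      want <- oracle_match(mt, rt)
      expect_identical(got$n_missed, as.integer(want$missed))
      expect_identical(got$n_extra, as.integer(want$extra))
      if (nrow(got$pairs))
        expect_equal(unname(as.matrix(got$pairs[, 1:2])),
                     unname(want$pairs))
      expect_identical(got$n_ref, nrow(got$pairs) + got$n_missed)
    }
  })
})

test_that("degradation: deleting or duplicating one ML event moves one count", {
  rt <- seq(1, 10, by = 1)
  ref <- ons(as.vector(rbind(rt, rt + 0.4)))
  base <- match_events(ref, ref, "ON")
  # delete one ON (and its OFF)
  keep <- rep(TRUE, length(ref$time)); keep[7:8] <- FALSE
  ml_del <- event_list(ref$time[keep], ref$kind[keep], "pole")
  m_del <- match_events(ml_del, ref, "ON")
  expect_identical(m_del$n_missed, base$n_missed + 1L)
  expect_identical(m_del$n_extra, base$n_extra)
  # duplicate one ON nearby
  ml_dup <- event_list(sort(c(ref$time, 4.05, 4.1)),
                       rep(c("ON", "OFF"), 11), "pole")
  m_dup <- match_events(ml_dup, ref, "ON")
  expect_identical(m_dup$n_extra, base$n_extra + 1L)
  expect_identical(m_dup$n_missed, base$n_missed)
})

test_that("a constant shift moves the mean error exactly, counts unchanged", {
  rt <- seq(1, 20, by = 1)
  ref <- ons(as.vector(rbind(rt, rt + 0.4)))
  for (k in c(-3L, 2L, 5L)) {
    sh <- k / 100
    ml <- event_list(ref$time + sh, ref$kind, "pole")
    m <- match_events(ml, ref, "ON")
    expect_equal(mean(m$pairs$error_ms), 10 * k, tolerance = 1e-9)
    expect_identical(m$n_missed, 0L)
    expect_identical(m$n_extra, 0L)
  }
})

test_that("phase computation and errors follow the stated definitions", {
  e <- ev(c(1.00, 1.42, 1.65, 2.10), c("ON", "OFF", "ON", "OFF"))
  ph <- compute_phases(e)
  expect_identical(nrow(ph), 1L)  # trailing CT has no following ON: omitted
  expect_equal(ph$ct_ms, 420)
  expect_equal(ph$ft_ms, 230)
  expect_identical(nrow(compute_phases(ev(1, "ON"))), 0L)

  ref <- ev(c(1.00, 1.42, 2.00, 2.42, 3.00, 3.42),
            rep(c("ON", "OFF"), 3))
  ml <- ev(c(1.00, 1.43, 2.00, 2.41, 3.00, 3.40), rep(c("ON", "OFF"), 3))
  pe <- phase_errors(ml, ref)
  expect_equal(pe$ct_error_ms, c(10, -10))
  expect_equal(pe$ct_rel_pct, 100 * c(10, -10) / 420, tolerance = 1e-6)
  pe0 <- phase_errors(ref, ref)
  expect_true(all(pe0$ct_error_ms == 0) && all(pe0$ft_error_ms == 0))

  # a cycle whose ON is missing from ML is excluded
  ml_miss <- ev(c(1.00, 1.42, 3.00, 3.42), rep(c("ON", "OFF"), 2))
  pe_m <- phase_errors(ml_miss, ref)
  expect_identical(nrow(pe_m), 1L)
})

test_that("relative CT error example: 430 vs 420 ms is +2.38%", {
  ref <- ev(c(1.00, 1.42, 2.00, 2.43, 3.00), c("ON", "OFF", "ON", "OFF", "ON"))
  ml <- ev(c(1.00, 1.43, 2.00, 2.43, 3.00), c("ON", "OFF", "ON", "OFF", "ON"))
  pe <- phase_errors(ml, ref)
  expect_equal(pe$ct_error_ms[1], 10)
  expect_equal(pe$ct_rel_pct[1], 100 * 10 / 420, tolerance = 1e-6)
})

test_that("summaries pool events, not subject means", {
  mk <- function(subject, errs_ms) {
    rt <- seq_along(errs_ms)
    ref <- ons(as.vector(rbind(rt, rt + 0.4)))
    ml <- event_list(ref$time + rep(errs_ms / 1000, each = 2), ref$kind,
                     "pole")
    list(subject_id = subject, sensor = "upper_back", effector = "pole",
         lap = 1L, events_ml = ml, events_ref = ref, truth = ref)
  }
  evl <- evaluate_predictions(list(mk("A", c(10, -10)),
                                   mk("B", c(30, 30, 30))))
  s <- summarize_errors(evl)
  a <- s[s$subject == "A", ]
  expect_equal(a$on_mean_ms, 0)
  expect_equal(a$on_sd_ms, sqrt(sum((c(10, -10))^2) / 1), tolerance = 1e-6)
  all_row <- s[s$subject == "All", ]
  pooled <- c(10, -10, 30, 30, 30)
  expect_equal(all_row$on_mean_ms, mean(pooled))
  expect_equal(all_row$on_sd_ms, sd(pooled))
  expect_false(isTRUE(all.equal(all_row$on_mean_ms,
                                mean(c(0, 30)))))  # not mean of subject means
  expect_equal(all_row$on_missed_pct, 0)
})

test_that("missed percentage is per hundred reference events", {
  rt <- seq(1, 20, by = 1)
  ref <- ons(as.vector(rbind(rt, rt + 0.4)))
  keep <- rep(TRUE, 40); keep[c(5, 6)] <- FALSE  # drop one cycle
  ml <- event_list(ref$time[keep], rep(c("ON", "OFF"), 19), "pole")
  evl <- evaluate_predictions(list(list(subject_id = "A",
                                        sensor = "upper_back",
                                        effector = "pole", lap = 1L,
                                        events_ml = ml, events_ref = ref,
                                        truth = ref)))
  s <- summarize_errors(evl)
  expect_equal(s$on_missed_pct[s$subject == "All"], 100 * 1 / 20)
})
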