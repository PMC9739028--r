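test_that("architecture contracts: shapes, softmax, seeding", {
  cfg <- lstm_config(hidden_units = 8, epochs = 2, seed = 4)
  m <- build_lstm(cfg)
  x <- matrix(rnorm(6 * 50), 6, 50)
  p <- predict_proba(m, x)
  expect_identical(dim(p), c(2L, 50L))
  expect_lt(max(abs(colSums(p) - 1)), 1e-12)
  pred <- predict(m, x)
  expect_length(pred, 50L)
  expect_true(all(pred$values %in% c(0L, 1L)))
  # same seed -> identical initial predictions
  expect_identical(predict_proba(build_lstm(cfg), x), p)
  expect_error(predict_proba(m, matrix(0, 5, 10)), "channels")
  expect_error(lstm_config(hidden_units = 0), "hidden_units")
  expect_error(lstm_config(n_features = 5), "n_features")
})

test_that("training is deterministic and learns the separable limit", {
  tr <- generate_trial(clean_config(), "SJ1", sensor = "upper_back")
  f <- assemble_features(tr$trial)
  lab <- align_labels(events_to_binary(tr$truth$pole,
                                       length(tr$trial$pole_force_left), 100),
                      f)
  cfg <- lstm_config(hidden_units = 32, epochs = 30, seed = 5)
  m <- lstm_labeler(list(f), list(lab), cfg, effector = "pole")
  expect_gt(mean(predict(m, f)$values == lab$values), 0.99)
  m2 <- lstm_labeler(list(f), list(lab), cfg, effector = "pole")
  expect_identical(m$epoch_loss, m2$epoch_loss)
  expect_identical(m$params, m2$params)
  expect_true(all(diff(m$epoch_loss) <= 0) || m$epoch_loss[1] >
                m$epoch_loss[length(m$epoch_loss)])
})

test_that("degenerate all-zero labels collapse to the zero class", {
  x <- matrix(rnorm(6 * 300), 6, 300)
  m <- lstm_labeler(list(x), list(integer(300)),
                    lstm_config(hidden_units = 8, epochs = 20, seed = 2,
                                window_length = 100))
  expect_true(all(predict(m, x)$values == 0L))
})

test_that("loso plan enumerates folds and model counts", {
  plan <- loso_plan(sprintf("SJ%d", 1:9),
                    sensors = c("upper_back", "sternum", "sacrum"),
                    effectors = c("pole", "left_ski", "right_ski"))
  expect_identical(plan$n_models, 81L)
  expect_length(plan$folds, 9L)
  for (f in plan$folds) {
    expect_false(f$test_subject %in% f$training_subjects)
    expect_length(f$training_subjects, 8L)
  }
  expect_identical(loso_plan(c("a", "b"), effectors = "pole")$n_models, 2L)
  expect_error(loso_plan("solo"), "at least 2")
})

test_that("run_loso holds each subject out of its own training set", {
  cfg <- tiny_config(lap_duration = 15)
  co <- generate_cohort(cfg)
  res <- run_loso(co, config = lstm_config(hidden_units = 8, epochs = 2,
                                           seed = 1),
                  effectors = "pole")
  expect_length(res$models, 2L)
  expect_length(res$predictions, 2L)
  for (key in names(res$models)) {
    held <- strsplit(key, "/", fixed = TRUE)[[1]][1]
    expect_false(held %in% res$models[[key]]$training_subjects)
  }
  for (p in res$predictions) {
    key <- paste(p$subject_id, p$sensor, p$effector, sep = "/")
    expect_false(p$subject_id %in% res$models[[key]]$training_subjects)
  }
})
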