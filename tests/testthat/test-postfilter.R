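test_that("block filter hand cases: merge then drop, strict boundaries", {
  # 10-sample gap (< 20) between two 40-blocks merges into one 90-block
  x <- c(rep(1, 40), rep(0, 10), rep(1, 40), rep(0, 10))
  expect_identical(filter_blocks(x), c(rep(1L, 90), rep(0L, 10)))

  # a block of exactly 30 samples is not "longer than 30": removed
  expect_identical(filter_blocks(c(rep(0, 5), rep(1, 30), rep(0, 5))),
                   rep(0L, 40))
  expect_identical(filter_blocks(c(rep(0, 5), rep(1, 31), rep(0, 4))),
                   c(rep(0L, 5), rep(1L, 31), rep(0L, 4)))

  # a gap of exactly 20 samples is not "less than 20": not merged
  b <- c(rep(1, 31), rep(0, 20), rep(1, 31))
  expect_identical(filter_blocks(b), as.integer(b))
  b19 <- c(rep(1, 31), rep(0, 19), rep(1, 31))
  expect_identical(filter_blocks(b19), rep(1L, 81))

  expect_identical(filter_blocks(rep(0L, 50)), rep(0L, 50))
  expect_identical(filter_blocks(integer(0)), integer(0))
})

test_that("chained gaps merge fully in one run-based pass", {
  x <- c(rep(1, 31), rep(0, 5), rep(1, 2), rep(0, 5), rep(1, 31))
  expect_identical(filter_blocks(x), rep(1L, 74))
})

test_that("leading and trailing zeros are never filled", {
  x <- c(rep(0, 5), rep(1, 40), rep(0, 5))
  y <- filter_blocks(x)
  expect_identical(y[1:5], rep(0L, 5))
  expect_identical(y[46:50], rep(0L, 5))
  # a sequence ending inside a gap keeps the gap
  x2 <- c(rep(1, 40), rep(0, 3))
  expect_identical(filter_blocks(x2), c(rep(1L, 40), rep(0L, 3)))
})

test_that("filter matches the run-enumeration oracle and is idempotent", {
  withr::with_seed(11, {
    for (rep in 1:300) {
      n <- sample(1:120, 1)
      x <- sample(0:1, n, replace = TRUE)
      for (prm in list(c(20L, 30L), c(4L, 3L), c(1L, 0L))) {
        a <- filter_blocks(x, prm[1], prm[2])
        expect_identical(a, oracle_filter(x, prm[1], prm[2]))
        expect_identical(filter_blocks(a, prm[1], prm[2]), a)
        # monotonicity across stages: merged >= input, final <= merged
        merged <- oracle_filter(x, prm[1], 0L)
        expect_true(all(merged >= x))
        expect_true(all(a <= merged))
      }
    }
  })
})

test_that("binary_phase inputs keep their class and metadata", {
  b <- binary_phase(c(rep(1L, 40), rep(0L, 10), rep(1L, 40)), 100, "pole")
  y <- filter_blocks(b)
  expect_s3_class(y, "binary_phase")
  expect_identical(y$sample_rate, 100)
  expect_identical(y$effector, "pole")
  expect_identical(sum(y$values), 90L)
})
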