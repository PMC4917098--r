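test_that("clump boundaries separate exactly the y-row changes along x", {
  # strictly monotone points, 2 rows: the single boundary at the row change
  s <- paired_sample(1:10, 1:10)
  expect_equal(build_clumps(s, equipartition(s$y, 2)), 5L)

  # alternating rows at every step: n - 1 boundaries
  alt <- paired_sample(1:10, rep(c(0, 10), 5) + (1:10) / 100)
  expect_equal(build_clumps(alt, equipartition(alt$y, 2)), 1:9)

  # random samples: boundaries are exactly the positions where the row id of
  # x-ordered points changes
  for (seed in 1:5) {
    s <- small_sample(40, seed)
    yp <- equipartition(s$y, 3)
    rows_in_x_order <- yp$bin[order(s$x)]
    expect_equal(build_clumps(s, yp), which(diff(rows_in_x_order) != 0))
  }
})

test_that("superclump coarsening respects the c * l candidate cap", {
  s <- independent_pair(300, seed = 5)
  yp <- equipartition(s$y, 2)
  full <- build_clumps(s, yp)
  capped <- build_clumps(s, yp, max_bins = 4)
  expect_lte(length(capped), 5 * 4 - 1)
  expect_true(all(capped %in% full))
})

test_that("column DP attains the exhaustive-search optimum on small samples", {
  for (seed in 1:6) {
    s <- small_sample(10 + (seed %% 3), seed)
    for (r in 2:3) {
      yp <- equipartition(s$y, r)
      dp <- optimize_x_axis(s, yp, max_bins = 4, use_superclumps = FALSE)
      oracle <- exhaustive_best_I(s, yp, max_bins = 4)
      expect_equal(unname(dp), oracle, tolerance = 1e-10)
    }
  }
})

test_that("optimal MI is non-decreasing in the allowed bin count", {
  for (seed in 1:4) {
    s <- independent_pair(120, seed = seed)
    I <- optimize_x_axis(s, equipartition(s$y, 3), max_bins = 8)
    expect_true(all(diff(I) >= -1e-12))
    expect_true(all(I >= 0))
  }
  # noiseless linear, 2 rows: a single extra cut already reaches 1 bit
  lin <- paired_sample(1:50 / 50, 1:50 / 50)
  I <- optimize_x_axis(lin, equipartition(lin$y, 2), max_bins = 2)
  expect_equal(unname(I), 1)
})

test_that("ApproxMaxMI scores 1 on noiseless monotone data and is symmetric", {
  s <- sample_function("exponential", 500, seed = 3)
  res <- approx_max_mi(s)
  expect_equal(res$mic, 1, tolerance = 1e-12)
  expect_equal(unname(res$best_shape), c(2, 2))

  r1 <- approx_max_mi(independent_pair(200, seed = 8))
  r2 <- approx_max_mi(paired_sample(independent_pair(200, seed = 8)$y,
                                    independent_pair(200, seed = 8)$x))
  expect_equal(r1$mic, r2$mic, tolerance = 1e-12)
  expect_equal(r1$matrix, t(r2$matrix), tolerance = 1e-12)

  vals <- r1$matrix[!is.na(r1$matrix)]
  expect_true(all(vals >= 0 & vals <= 1))
  # under the floor budget every searched shape respects nx * ny <= B
  idx <- which(!is.na(r1$matrix), arr.ind = TRUE)
  expect_true(all(idx[, 1] * idx[, 2] <= attr(r1$matrix, "B")))

  expect_error(approx_max_mi(paired_sample(1:3, 1:3)),
               class = "chimic_invalid_input")
})
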