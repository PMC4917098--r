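test_that("flanking chi-square test matches closed forms", {
  res <- chi_square_test(matrix(c(0, 5, 5, 0), 2))
  expect_equal(unname(res$statistic), 6.4)
  expect_equal(unname(res$parameter), 1)
  expect_equal(res$p.value, 0.0114, tolerance = 2e-3)
  expect_true(res$corrected)

  flat <- chi_square_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)

  # 4 * (4.5^2 / 5) with continuity correction
  res10 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(unname(res10$statistic), 16.2)
  expect_equal(res10$p.value,
               pchisq(16.2, 1, lower.tail = FALSE))
})

test_that("flanking test agrees with stats::chisq.test on r x 2 tables", {
  for (seed in 1:8) {
    r <- 2 + seed %% 4
    m <- random_rx2_table(r, seed)
    mine <- chi_square_test(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = r == 2))
    expect_equal(unname(mine$statistic), unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value)
    expect_equal(unname(mine$parameter), unname(ref$parameter))
  }
})

test_that("zero margins exclude cells instead of producing NaN", {
  m <- matrix(c(0, 4, 6, 0, 3, 5), nrow = 3, byrow = TRUE)
  m[1, ] <- 0  # empty row
  res <- chi_square_test(m)
  expect_true(is.finite(res$statistic))
  expect_equal(unname(res$parameter), 2)

  allzero <- chi_square_test(matrix(0L, 2, 2))
  expect_equal(unname(allzero$statistic), 0)
  expect_equal(allzero$p.value, 1)

  # proportional columns always give statistic 0
  prop <- chi_square_test(matrix(c(6, 2, 4, 3, 1, 2), ncol = 2))
  expect_equal(unname(prop$statistic), 0)
})

test_that("flanking_table restricts to the two columns around the new cut", {
  s <- small_sample(40, 2)
  yp <- equipartition(s$y, 3)
  xp <- equipartition(s$x, 4)
  for (cut in xp$cuts) {
    ft <- flanking_table(s, yp, xp, cut)
    expect_equal(ncol(ft$counts), 2)
    expect_equal(nrow(ft$counts), yp$bins)
    expect_equal(ft$total, sum(ft$counts))
  }
  k <- xp$cuts[2]
  ft <- flanking_table(s, yp, xp, k)
  full <- count_contingency(s, xp, yp)
  expect_equal(ft$counts, full$counts[, 2:3])
  expect_error(flanking_table(s, yp, xp, 999),
               class = "chimic_invalid_input")
})

test_that("chi-square-terminated insertion stops early where the DP would not", {
  # noiseless linear with 2 rows: the single useful endpoint gives 2 bins
  lin <- sample_function("linear", 1000, seed = 4)
  res <- chimic_x_axis(lin, equipartition(lin$y, 2))
  expect_equal(res$partition$bins, 2L)
  expect_equal(unname(res$I[1]), 1)

  # noisy linear: a handful of bins, far below the DP's 31-column budget
  noisy <- sample_function("linear", 1000, noise_level = 0.5, seed = 11)
  resn <- chimic_x_axis(noisy, equipartition(noisy$y, 2))
  expect_gte(resn$partition$bins, 3L)
  expect_lte(resn$partition$bins, 8L)
  # every accepted endpoint rejected independence; the final candidate failed
  np <- length(resn$p_values)
  expect_true(all(resn$p_values[-np] < 0.01))
  expect_gte(resn$p_values[np], 0.01)

  # weak structure: one clean low block, then rows mixed evenly along x.
  # After the first endpoint no further split can reject independence, so
  # the text-literal (untested first endpoint) variant keeps exactly 2 bins.
  deg <- paired_sample(x = c(1:8, rep(9:12, each = 2)),
                       y = c(1:4, 101:104, rbind(5:8, 105:108)))
  resd <- chimic_x_axis(deg, equipartition(deg$y, 2),
                        termination_config(test_first = FALSE))
  expect_equal(resd$partition$bins, 2L)
  expect_gte(resd$p_values[1], 0.01)
})

test_that("ChiMIC recovers MIC = 1 for every noiseless catalog function", {
  for (f in names(function_catalog())) {
    s <- sample_function(f, 1000, seed = 42)
    expect_equal(chimic_mic(s)$mic, 1, tolerance = 1e-12,
                 label = paste("chimic mic for", f))
  }
})

test_that("ChiMIC never exceeds ApproxMaxMI on shared grid shapes", {
  for (seed in 1:10) {
    s <- independent_pair(150, seed = 100 + seed)
    ca <- approx_max_mi(s)$matrix
    cc <- chimic_mic(s)$matrix
    common_l <- seq_len(min(nrow(ca), nrow(cc)))
    common_r <- seq_len(min(ncol(ca), ncol(cc)))
    a <- ca[common_l, common_r]
    b <- cc[common_l, common_r]
    both <- !is.na(a) & !is.na(b)
    expect_true(all(b[both] <= a[both] + 1e-9))
    expect_lte(chimic_mic(s)$mic, approx_max_mi(s)$mic + 1e-9)
  }
})

test_that("MIC results are deterministic for a fixed sample", {
  s <- sample_power_study("circular", 200, 1, seed = 6)
  expect_identical(chimic_mic(s), chimic_mic(s))
  expect_identical(approx_max_mi(s), approx_max_mi(s))
})
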