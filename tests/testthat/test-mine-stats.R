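test_that("MIC extraction scans the matrix with deterministic tie-breaks", {
  m1 <- matrix(NA_real_, 2, 2)
  m1[2, 2] <- 1
  expect_equal(mic_from_matrix(m1),
               list(mic = 1, best_shape = c(nx = 2, ny = 2)))

  m2 <- matrix(NA_real_, 3, 2)
  m2[2, 2] <- 0.4
  m2[3, 2] <- 0.6
  res <- mic_from_matrix(m2)
  expect_equal(res$mic, 0.6)
  expect_equal(unname(res$best_shape), c(3, 2))

  # ties resolved toward the smallest cell count, then smallest nx
  m3 <- matrix(NA_real_, 4, 4)
  m3[4, 2] <- m3[2, 4] <- m3[3, 3] <- 0.9
  m3[2, 2] <- 0.5
  expect_equal(unname(mic_from_matrix(m3)$best_shape), c(2, 4))

  # random matrices: equals a direct scan
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(30), 5, 6)
    m[sample(30, 10)] <- NA
    expect_equal(mic_from_matrix(m)$mic, max(m, na.rm = TRUE))
  }
  expect_error(mic_from_matrix(matrix(NA_real_, 2, 2)),
               class = "chimic_invalid_input")
})

test_that("MCN finds the smallest qualifying grid and is monotone in epsilon", {
  m <- matrix(NA_real_, 4, 4)
  m[2, 2] <- 0.7
  m[3, 2] <- 0.95
  m[4, 4] <- 1.0
  expect_equal(mcn(m, epsilon = 0), log2(16))
  expect_equal(mcn(m, epsilon = 0.05), log2(6))   # 0.95 >= 0.95 * 1
  expect_equal(mcn(m, epsilon = 0.3), log2(4))
  eps <- seq(0, 1, by = 0.1)
  vals <- vapply(eps, function(e) mcn(m, epsilon = e), 0)
  expect_true(all(diff(vals) <= 1e-12))
  # strict grid-size filter
  expect_equal(mcn(m, epsilon = 0, b_max = 16), 2)  # 4x4 excluded, floor
  # one-minus-mic mode: qualifying threshold is MIC^2
  m2 <- matrix(NA_real_, 3, 3)
  m2[2, 2] <- 0.5
  m2[3, 3] <- 0.8
  # threshold is MIC^2 = 0.64 > 0.5, so only the 3x3 grid qualifies
  expect_equal(mcn(m2, mode = "one-minus-mic"), log2(9))
})

test_that("noiseless relationships have their characteristic MCN values", {
  # equispaced design: the population minimal grids (2x2, 3x2, 4x2)
  lin <- chimic_mic(sample_function("linear", 1000, x_design = "grid"))
  par <- chimic_mic(sample_function("parabolic", 1000, x_design = "grid"))
  sin2 <- chimic_mic(sample_function("sin_two_period", 1000,
                                     x_design = "grid"))
  expect_equal(mcn(lin), 2)
  expect_equal(mcn(par), log2(6))
  expect_equal(mcn(sin2), 3)
})

test_that("random-x sampling can add one boundary sliver column to the MCN", {
  # where sin(4*pi*x) meets the sample median at a domain edge, a few
  # random draws can force a fifth column; the MCN is then log2(10)
  vals <- vapply(1:6, function(sd) {
    mcn(chimic_mic(sample_function("sin_two_period", 1000, seed = sd)))
  }, 0)
  expect_true(all(vals %in% c(3, log2(10))))
})

test_that("independent pairs sit near the MCN floor of 2 under ChiMIC", {
  set.seed(77)
  vals <- replicate(120, mcn(chimic_mic(independent_pair(100))))
  expect_gte(min(vals), 2)
  expect_lte(mean(vals), 2.6)
})
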