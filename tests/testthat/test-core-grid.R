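test_that("equipartition balances distinct values and respects the tie rule", {
  p <- equipartition(rnorm(10), 2)
  expect_equal(sort(tabulate(p$bin, p$bins)), c(5, 5))

  p3 <- equipartition(seq_len(10), 3)
  expect_equal(tabulate(p3$bin, p3$bins), c(3, 4, 3))

  # all-identical values: no legal cut anywhere
  pid <- equipartition(rep(1, 10), 2)
  expect_equal(pid$bins, 1L)

  expect_error(equipartition(1:10, 1), class = "chimic_invalid_input")
  expect_error(equipartition(1:10, 11), class = "chimic_invalid_input")
})

test_that("tied values never straddle a cut", {
  v <- c(1, 1, 1, 1, 2, 2, 3, 3, 3, 4)
  for (r in 2:5) {
    p <- equipartition(v, r)
    for (cut in p$cuts) {
      sorted <- sort(v)
      expect_true(sorted[cut] != sorted[cut + 1])
    }
  }
})

test_that("contingency counting matches geometry and conserves n", {
  diag4 <- paired_sample(1:4, 1:4)
  ct <- count_contingency(diag4, equipartition(diag4$x, 2),
                          equipartition(diag4$y, 2))
  expect_equal(unname(ct$counts), matrix(c(2L, 0L, 0L, 2L), 2))

  corners <- paired_sample(c(0, 0, 1, 1), c(0, 1, 0, 1))
  ct2 <- count_contingency(corners, equipartition(corners$x, 2),
                           equipartition(corners$y, 2))
  expect_equal(unname(ct2$counts), matrix(1L, 2, 2))

  for (seed in 1:5) {
    s <- small_sample(30, seed)
    xp <- equipartition(s$x, sample(2:6, 1))
    yp <- equipartition(s$y, sample(2:6, 1))
    ct <- count_contingency(s, xp, yp)
    expect_equal(ct$total, s$n)
    expect_equal(unname(rowSums(ct$counts)), unname(ct$row_sums))
    expect_equal(unname(colSums(ct$counts)), unname(ct$col_sums))
  }

  expect_error(count_contingency(diag4, equipartition(1:6, 2),
                                 equipartition(diag4$y, 2)),
               class = "chimic_invalid_input")
})

test_that("mutual information matches closed forms and the entropy oracle", {
  expect_equal(mutual_information(matrix(c(5, 5, 5, 5), 2)), 0)
  expect_equal(mutual_information(matrix(c(2, 0, 0, 2), 2)), 1)

  # direct four-term evaluation for {3,1;1,3}
  hand <- 2 * (3 / 8) * log2((3 / 8) / 0.25) +
    2 * (1 / 8) * log2((1 / 8) / 0.25)
  expect_equal(mutual_information(matrix(c(3, 1, 1, 3), 2)), hand)

  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(rpois(12, 4), 3, 4)
    m[1, 1] <- m[1, 1] + 1  # guarantee nonzero total
    expect_equal(mutual_information(m), mi_entropy_oracle(m))
    expect_gte(mutual_information(m), 0)
    expect_lte(mutual_information(m), log2(3) + 1e-12)
  }
})

test_that("normalization maps grid MI to [0, 1] with min-based scaling", {
  expect_equal(normalized_score(1, 2, 2), 1)
  expect_equal(normalized_score(1, 32, 2), 1)
  expect_equal(normalized_score(log2(3), 3, 3), 1)
  expect_error(normalized_score(0.5, 1, 3), class = "chimic_invalid_input")
  expect_error(normalized_score(-0.1, 2, 2), class = "chimic_invalid_input")
})

test_that("grid statistics are invariant under increasing marginal transforms", {
  s <- independent_pair(150, seed = 31)
  s2 <- paired_sample(exp(s$x), s$y^3)
  for (fit in list(chimic_mic, approx_max_mi)) {
    r1 <- fit(s)
    r2 <- fit(s2)
    expect_equal(r1$mic, r2$mic, tolerance = 1e-12)
    expect_equal(r1$matrix, r2$matrix, tolerance = 1e-12)
  }
})
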