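#' Termination settings for the ChiMIC endpoint search
#'
#' @param alpha Significance threshold in (0, 1) for the flanking-column
#'   chi-square test; an endpoint whose test has `p >= alpha` is rejected
#'   and the column search for that row partition stops. The default 0.01
#'   sits just below the p-value (0.0114) of the most extreme 2 x 2 table
#'   whose expected counts reach the classical minimum of five.
#' @param apply_b_cap Keep the `B(n)` bound on the row sweep (row counts 2
#'   through `floor(B/2)`); the column insertion depth is always governed by
#'   the chi-square rule alone. When `FALSE` the row sweep extends to
#'   `floor(n/2)`.
#' @param test_first Also test the first endpoint: its flanking columns are
#'   the two bins it creates, so a row partition whose best single cut does
#'   not already reject independence contributes no grid at all.
#' @return A `termination_config` list.
#' @export
termination_config <- function(alpha = 0.01, apply_b_cap = TRUE,
                               test_first = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_invalid("alpha must lie strictly between 0 and 1")
  structure(list(alpha = alpha, apply_b_cap = isTRUE(apply_b_cap),
                 test_first = isTRUE(test_first)),
            class = "termination_config")
}

#' Chi-square independence test on an r x 2 contingency table
#'
#' The ChiMIC termination statistic:
#' `sum_ij (|f_ij - n_i T_j / N| - h)^2 / (n_i T_j / N)` over cells with
#' positive expected count, with the Yates continuity correction `h = 0.5`
#' for 2 x 2 tables (`h = 0` otherwise), `r - 1` degrees of freedom, and the
#' upper-tail chi-square p-value.
#'
#' @param table A [count_contingency()] result or count matrix with two
#'   columns and at least two rows.
#' @param correct Apply the continuity correction; defaults to `TRUE` exactly
#'   when the table is 2 x 2.
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   `p.value` and a logical `corrected` element.
#' @examples
#' chi_square_test(matrix(c(0, 5, 5, 0), 2))$p.value  # 0.0114
#' @export
chi_square_test <- function(table, correct = NULL) {
  f <- as_count_matrix(table)
  if (ncol(f) != 2L) stop_invalid("table must have exactly 2 columns")
  if (nrow(f) < 2L) stop_invalid("table must have at least 2 rows")
  r <- nrow(f)
  if (is.null(correct)) correct <- r == 2L
  N <- sum(f)
  if (N == 0) {
    stat <- 0
    p <- 1
  } else {
    e <- outer(rowSums(f), colSums(f)) / N
    h <- if (correct) 0.5 else 0
    d <- pmax(abs(f - e) - h, 0)
    keep <- e > 0
    stat <- sum(d[keep]^2 / e[keep])
    p <- stats::pchisq(stat, df = r - 1, lower.tail = FALSE)
  }
  structure(
    list(statistic = c("X-squared" = stat), parameter = c(df = r - 1),
         p.value = p, corrected = correct,
         method = paste0("Chi-square test on r x 2 flanking columns",
                         if (correct) " with Yates continuity correction"),
         data.name = deparse(substitute(table))),
    class = "htest")
}

#' Extract the r x 2 table flanking an accepted endpoint
#'
#' Restricts the grid's counts to the two x-columns separated by `new_cut`
#' (the columns the cut created when it subdivided its bin), giving the
#' table on which [chi_square_test()] decides whether the endpoint is
#' useful.
#'
#' @param sample A [paired_sample()].
#' @param ypart,xpart `axis_partition` objects for the y rows and the
#'   x-partition containing `new_cut`.
#' @param new_cut A cut position present in `xpart$cuts`.
#' @return A `contingency_table` with `ypart$bins` rows and 2 columns.
#' @export
flanking_table <- function(sample, ypart, xpart, new_cut) {
  sample <- as_paired_sample(sample)
  k <- match(as.integer(new_cut), xpart$cuts)
  if (is.na(k)) stop_invalid("new_cut is not a cut of xpart")
  full <- count_contingency(sample, xpart, ypart)
  contingency_table(full$counts[, c(k, k + 1L), drop = FALSE])
}

#' ChiMIC column search for one row partition
#'
#' Greedy conditional endpoint insertion: the first endpoint is the single
#' cut (drawn from the clump boundaries) maximizing mutual information; each
#' later candidate is the best cut given all accepted cuts frozen, and is
#' kept only if the chi-square test on its two flanking columns has
#' `p < alpha`. The search stops at the first rejected candidate or when no
#' candidates remain.
#'
#' @inheritParams build_clumps
#' @param termination A [termination_config()].
#' @return List with `partition` (the accepted x `axis_partition`), `I`
#'   (mutual information in bits at each visited column count, starting at
#'   2), and `p_values` (flanking-test p-values in insertion order,
#'   including the final rejected one if any).
#' @export
chimic_x_axis <- function(sample, ypart, termination = termination_config(),
                          config = optimizer_config()) {
  sample <- as_paired_sample(sample)
  if (ypart$n != sample$n) stop_invalid("ypart does not match the sample")
  res <- .cpp_chimic_x_axis(sample$x, ypart$bin - 1L, ypart$bins,
                            termination$alpha, termination$test_first)
  I <- res$I
  if (length(I)) names(I) <- as.character(seq_along(I) + 1L)
  list(partition = axis_partition_from_cuts(sample$x, res$cuts),
       I = I, p_values = res$p_values)
}

#' MIC by the ChiMIC chi-square-terminated search
#'
#' Runs the chi-square-terminated column search of [chimic_x_axis()] for
#' every row count from 2 up to `floor(B/2)` in both axis orientations, scores all
#' intermediate grids actually visited, and takes the maximum normalized
#' score. Because each visited grid is a greedily grown partition rather
#' than the DP optimum, every characteristic-matrix entry is bounded above
#' by the corresponding [approx_max_mi()] entry.
#'
#' @inheritParams approx_max_mi
#' @param termination A [termination_config()].
#' @return A `mic_result` (see [approx_max_mi()]).
#' @examples
#' s <- independent_pair(100, seed = 1)
#' chimic_mic(s)$mic  # small: few endpoints survive the chi-square test
#' @export
chimic_mic <- function(sample, termination = termination_config(),
                       config = optimizer_config()) {
  sample <- as_paired_sample(sample)
  if (sample$n < 4L)
    stop_invalid("need at least 4 points to form a 2x2 grid")
  B <- grid_bound(sample$n, config)
  rmax <- if (termination$apply_b_cap) floor(B / 2) else floor(sample$n / 2)
  tri <- .cpp_cm_chimic(sample$x, sample$y, termination$alpha,
                        as.integer(rmax), termination$test_first, B,
                        config$c, rounding_code(config))
  mic_result(tri, B, "ChiMIC", config, sample$n,
             termination = termination)
}
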