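#' Configuration for the grid-size bound and superclump coarsening
#'
#' Both optimizers restrict the grids they visit through the maximal grid
#' size `B(n) = n^a` (the ChiMIC column search ignores it; see
#' [chimic_mic()]). The row sweep covers row counts 2 through `floor(B/2)`
#' and each row count gets a column budget of `B/r` rounded per
#' `budget_rounding`. The default `"floor"` enforces the bound
#' `nx * ny <= B` strictly; `"round"` and `"ceil"` admit slightly larger
#' grids (e.g. 2 x 32 at n = 1000, where `B = 63.1`), which some reference
#' implementations allow. `B` is floored at 4 so a 2 x 2 grid is always
#' searchable.
#'
#' @param a Positive exponent of the grid-size bound `B(n) = n^a`
#'   (default 0.6).
#' @param c Positive integer superclump multiplier: at most `c * l` candidate
#'   column cuts are retained when optimizing toward `l` columns (default 5).
#' @param budget_rounding How the per-row column budget `B/r` is rounded:
#'   `"round"`, `"floor"`, or `"ceil"`.
#' @param b_cap Optional explicit numeric override for `B` (bypasses `n^a`).
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(a = 0.6, c = 5,
                             budget_rounding = c("floor", "round", "ceil"),
                             b_cap = NULL) {
  budget_rounding <- match.arg(budget_rounding)
  if (!is.numeric(a) || a <= 0) stop_invalid("a must be positive")
  c <- as.integer(c)
  if (is.na(c) || c < 1L) stop_invalid("c must be a positive integer")
  if (!is.null(b_cap) && (!is.numeric(b_cap) || b_cap < 4))
    stop_invalid("b_cap must be numeric and at least 4")
  structure(list(a = a, c = c, budget_rounding = budget_rounding,
                 b_cap = b_cap),
            class = "optimizer_config")
}

grid_bound <- function(n, cfg) {
  if (!is.null(cfg$b_cap)) return(as.numeric(cfg$b_cap))
  max(n^cfg$a, 4)
}

rounding_code <- function(cfg) {
  match(cfg$budget_rounding, c("floor", "round", "ceil")) - 1L
}

#' Candidate column cuts: clump boundaries
#'
#' Given a row partition of the y-axis, the only x-cut positions that can
#' increase mutual information are the boundaries between clumps — maximal
#' runs of consecutive (in x-order) points lying in the same y-row. Points
#' tied on x are atomic and never split.
#'
#' @param sample A [paired_sample()].
#' @param ypart An [equipartition()] of `sample$y`.
#' @param max_bins Optional column target; when given, the clump set is
#'   coarsened to at most `c * max_bins` superclump candidates.
#' @param config An [optimizer_config()] (used for `c` when coarsening).
#' @return Integer vector of candidate cut positions in x-order count space.
#' @export
build_clumps <- function(sample, ypart, max_bins = NULL,
                         config = optimizer_config()) {
  sample <- as_paired_sample(sample)
  if (ypart$n != sample$n)
    stop_invalid("ypart does not match the sample")
  pos <- .cpp_clumps(sample$x, ypart$bin - 1L)
  if (!is.null(max_bins))
    pos <- .cpp_superclumps(pos, sample$n, config$c * as.integer(max_bins))
  pos
}

#' Optimal column partitions by dynamic programming
#'
#' The ApproxMaxMI inner step: given an equipartition of the y-axis, finds
#' for every column count `t = 2..max_bins` the maximum mutual information
#' achievable by an x-partition with at most `t` bins whose cuts are drawn
#' from the (superclump-coarsened) clump candidates. The returned sequence
#' is non-decreasing in `t`.
#'
#' @inheritParams build_clumps
#' @param max_bins Largest column count to optimize for (at least 2).
#' @param use_superclumps Coarsen candidates to `c * max_bins` superclumps
#'   (the standard behaviour; disable for exact DP on small samples).
#' @return Named numeric vector of mutual informations (bits) for column
#'   counts `2..max_bins`.
#' @export
optimize_x_axis <- function(sample, ypart, max_bins,
                            config = optimizer_config(),
                            use_superclumps = TRUE) {
  sample <- as_paired_sample(sample)
  max_bins <- as.integer(max_bins)
  if (is.na(max_bins) || max_bins < 2L)
    stop_invalid("max_bins must be at least 2")
  if (ypart$n != sample$n) stop_invalid("ypart does not match the sample")
  I <- .cpp_optimize_x_axis(sample$x, ypart$bin - 1L, ypart$bins,
                            max_bins, config$c, use_superclumps)
  names(I) <- as.character(2:max_bins)
  I
}

#' MIC by the ApproxMaxMI dynamic-programming sweep
#'
#' Sweeps every row count from 2 up to `floor(B/2)` in both axis orientations,
#' equipartitioning one axis into `r` bins and DP-optimizing the other up to
#' the per-row column budget, then normalizes each grid's mutual information
#' by `log2(min(nx, ny))`. The MIC is the maximum entry of the resulting
#' characteristic matrix.
#'
#' @param sample A [paired_sample()] (or anything coercible; `n >= 4`).
#' @param config An [optimizer_config()].
#' @return A `mic_result`: list with `mic`, `best_shape` (`c(nx, ny)`),
#'   `matrix` (the characteristic matrix; `NA` entries were not searched),
#'   `algorithm`, `config` and `n`.
#' @examples
#' s <- paired_sample(1:40, (1:40)^2)
#' approx_max_mi(s)$mic  # 1: noiseless monotone relationship
#' @export
approx_max_mi <- function(sample, config = optimizer_config()) {
  sample <- as_paired_sample(sample)
  if (sample$n < 4L)
    stop_invalid("need at least 4 points to form a 2x2 grid")
  B <- grid_bound(sample$n, config)
  tri <- .cpp_cm_approx(sample$x, sample$y, B, config$c,
                        rounding_code(config))
  mic_result(tri, B, "ApproxMaxMI", config, sample$n)
}
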