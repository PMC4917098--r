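# Characteristic-matrix assembly and the statistics computed from it.

# tri: data.frame with nx, ny, score (one row per computed grid shape).
# An empty frame is legal for ChiMIC: when no endpoint anywhere rejects
# independence the search accepts no grid and the MIC is reported as 0.
characteristic_matrix <- function(tri, B) {
  if (!nrow(tri))
    return(structure(matrix(NA_real_, 2, 2), B = B,
                     class = "characteristic_matrix"))
  M <- matrix(NA_real_, nrow = max(tri$nx), ncol = max(tri$ny))
  M[cbind(tri$nx, tri$ny)] <- tri$score
  structure(M, B = B, class = "characteristic_matrix")
}

mic_result <- function(tri, B, algorithm, config, n, termination = NULL) {
  M <- characteristic_matrix(tri, B)
  best <- if (nrow(tri)) best_entry(M)
          else list(score = 0, shape = c(nx = NA_integer_, ny = NA_integer_))
  structure(
    list(mic = best$score, best_shape = best$shape, matrix = M,
         algorithm = algorithm, config = config,
         termination = termination, n = n),
    class = "mic_result")
}

# Maximum computed entry; ties (to within fp tolerance of the max) broken by
# smallest cell count nx*ny, then smallest nx.
best_entry <- function(M, tol = 1e-12) {
  idx <- which(!is.na(M), arr.ind = TRUE)
  if (!nrow(idx)) stop_invalid("characteristic matrix has no computed entry")
  score <- M[idx]
  top <- max(score)
  cand <- idx[score >= top - tol, , drop = FALSE]
  ord <- order(cand[, 1] * cand[, 2], cand[, 1])
  shape <- unname(cand[ord[1], ])
  list(score = top, shape = c(nx = shape[1], ny = shape[2]))
}

#' Extract the MIC from a characteristic matrix
#'
#' @param matrix A `characteristic_matrix` (as stored in a `mic_result`) or
#'   a plain numeric matrix indexed by `(nx, ny)` with `NA` for shapes that
#'   were not searched.
#' @return A list with `mic` (the maximum computed entry) and `best_shape`
#'   (`c(nx, ny)` of the entry attaining it: smallest cell count, then
#'   smallest `nx`, on ties).
#' @export
mic_from_matrix <- function(matrix) {
  best <- best_entry(as.matrix(matrix))
  list(mic = best$score, best_shape = best$shape)
}

#' Minimum cell number (MCN) of an association
#'
#' The complexity statistic
#' `MCN(D, eps) = min{ log2(nx * ny) : M[nx, ny] >= (1 - eps) * MIC(D) }`
#' over the computed entries of the characteristic matrix: the (log2) size
#' of the smallest grid whose score comes within a factor `1 - eps` of the
#' MIC. Simple relationships need few cells (2 for linear, log2(6) for a
#' parabola, 3 for a two-period sinusoid); independent data sit at the
#' floor of 2.
#'
#' @param x A `mic_result` from [approx_max_mi()] or [chimic_mic()], or a
#'   characteristic matrix.
#' @param epsilon Robustness parameter in `[0, 1]` (used in `"fixed"` mode).
#' @param mode `"fixed"` uses `epsilon` as given; `"one-minus-mic"` sets
#'   `epsilon = 1 - MIC(D)`, so grids with score at least `MIC^2` qualify.
#' @param b_max Optional strict grid-size filter: only entries with
#'   `nx * ny < b_max` qualify. By default no extra filter is applied — the
#'   matrix already contains only the grids the optimizer searched.
#' @return The MCN in bits (log2 of a cell count), at least 2. If no entry
#'   qualifies (a degenerate matrix), the 2 x 2 floor log2(4) = 2 is
#'   returned.
#' @examples
#' s <- sample_function("linear", 200, seed = 1)
#' mcn(chimic_mic(s))  # 2
#' @export
mcn <- function(x, epsilon = 0, mode = c("fixed", "one-minus-mic"),
                b_max = NULL) {
  mode <- match.arg(mode)
  M <- if (inherits(x, "mic_result")) x$matrix else as.matrix(x)
  idx <- which(!is.na(M), arr.ind = TRUE)
  if (!nrow(idx)) return(2)
  mic <- best_entry(M)$score
  if (mode == "one-minus-mic") epsilon <- 1 - mic
  if (epsilon < 0 || epsilon > 1)
    stop_invalid("epsilon must lie in [0, 1]")
  cells <- idx[, 1] * idx[, 2]
  ok <- M[idx] >= (1 - epsilon) * mic - 1e-12
  if (!is.null(b_max)) ok <- ok & cells < b_max
  if (!any(ok)) return(2)
  log2(min(cells[ok]))
}

#' @export
print.mic_result <- function(x, ...) {
  cat("MIC (", x$algorithm, "), n = ", x$n, "\n", sep = "")
  cat("  mic        :", format(x$mic, digits = 6), "\n")
  cat("  best grid  :", x$best_shape[1], "x", x$best_shape[2], "\n")
  cat("  matrix     :", sum(!is.na(x$matrix)), "computed shapes, B =",
      format(attr(x$matrix, "B"), digits = 5), "\n")
  cat("  mcn (eps=0):", format(mcn(x), digits = 4), "\n")
  invisible(x)
}
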