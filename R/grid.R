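#' Equipartition an axis into bins of near-equal counts
#'
#' Splits the rank-sorted values into `r` bins whose sizes differ by at most
#' one when all values are distinct. Tied values are atomic: a cut may never
#' separate equal values, so each ideal cut is moved to the nearest tie-legal
#' position (ties between candidates resolved toward the smaller position)
#' and the achieved bin count can fall below `r`.
#'
#' @param values Numeric vector (length `n >= 2`).
#' @param r Target number of bins, `2 <= r <= n`.
#' @return An object of class `axis_partition`: list with `cuts` (strictly
#'   increasing count positions in `1..n-1`; a cut at `p` splits the first
#'   `p` rank-sorted points from the rest), `bins` (achieved bin count),
#'   `n`, and `bin` (1-based bin id per original point).
#' @examples
#' equipartition(1:10, 3)$bins
#' @export
equipartition <- function(values, r) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop_invalid("need at least 2 values")
  r <- as.integer(r)
  if (is.na(r) || r < 2L || r > n)
    stop_invalid("r must satisfy 2 <= r <= n (got r = ", r, ", n = ", n, ")")
  cuts <- .cpp_equip_cuts(values, r)
  axis_partition_from_cuts(values, cuts)
}

axis_partition_from_cuts <- function(values, cuts) {
  cuts <- as.integer(cuts)
  n <- length(values)
  if (length(cuts) && (any(cuts < 1L) || any(cuts > n - 1L) ||
                       any(diff(cuts) <= 0L)))
    stop_invalid("cuts must be strictly increasing positions in 1..n-1")
  bin <- .cpp_assign_bins(as.numeric(values), cuts) + 1L
  structure(list(cuts = cuts, bins = length(cuts) + 1L, n = n, bin = bin),
            class = "axis_partition")
}

#' @export
print.axis_partition <- function(x, ...) {
  cat("axis_partition:", x$bins, "bins over", x$n, "points\n")
  cat("  cut positions:", paste(x$cuts, collapse = " "), "\n")
  cat("  bin sizes:", paste(tabulate(x$bin, x$bins), collapse = " "), "\n")
  invisible(x)
}

#' Cross-tabulate a sample over two axis partitions
#'
#' Counts points per grid cell for a (row = y-bin, column = x-bin) grid.
#'
#' @param sample A [paired_sample()].
#' @param xpart,ypart `axis_partition` objects built on `sample$x` and
#'   `sample$y` respectively.
#' @return Object of class `contingency_table`: list with `counts` (an
#'   r-by-l integer matrix, rows indexing y-bins), `row_sums`, `col_sums`
#'   and `total`.
#' @export
count_contingency <- function(sample, xpart, ypart) {
  sample <- as_paired_sample(sample)
  if (xpart$n != sample$n || ypart$n != sample$n)
    stop_invalid("partition size does not match the sample (n = ",
                 sample$n, ")")
  counts <- matrix(0L, nrow = ypart$bins, ncol = xpart$bins)
  for (i in seq_len(sample$n))
    counts[ypart$bin[i], xpart$bin[i]] <- counts[ypart$bin[i], xpart$bin[i]] + 1L
  contingency_table(counts)
}

contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop_invalid("cell counts must be non-negative")
  structure(list(counts = counts, row_sums = rowSums(counts),
                 col_sums = colSums(counts), total = sum(counts)),
            class = "contingency_table")
}

as_count_matrix <- function(table) {
  if (inherits(table, "contingency_table")) return(table$counts)
  as.matrix(table)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("contingency_table:", nrow(x$counts), "x", ncol(x$counts),
      "grid, N =", x$total, "\n")
  print(x$counts)
  invisible(x)
}

#' Grid mutual information in bits
#'
#' Evaluates `I = sum_ij (f_ij/N) log2((f_ij/N) / ((n_i/N)(T_j/N)))` over the
#' cells of a contingency table, with `0 log 0` terms defined as 0.
#'
#' @param table A [count_contingency()] result or a plain count matrix.
#' @return Mutual information in bits; non-negative, and at most
#'   `log2(min(nrow, ncol))`.
#' @examples
#' mutual_information(matrix(c(2, 0, 0, 2), 2))  # 1 bit
#' @export
mutual_information <- function(table) {
  f <- as_count_matrix(table)
  N <- sum(f)
  if (N < 1) stop_invalid("table must contain at least one point")
  p <- f / N
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Normalize a grid mutual information to the MIC scale
#'
#' Divides the mutual information of an `nx x ny` grid by
#' `log2(min(nx, ny))`, the largest value any grid of that shape can attain,
#' giving a score in `[0, 1]`.
#'
#' @param I Mutual information in bits (non-negative).
#' @param nx,ny Number of x-bins and y-bins (each at least 2).
#' @return The normalized score `I / log2(min(nx, ny))`.
#' @export
normalized_score <- function(I, nx, ny) {
  if (any(nx < 2) || any(ny < 2))
    stop_invalid("nx and ny must both be at least 2")
  if (any(I < 0)) stop_invalid("I must be non-negative")
  I / log2(pmin(nx, ny))
}
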