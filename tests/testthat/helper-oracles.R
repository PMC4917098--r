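# Independent oracles used across the suite. These deliberately take
# different computational routes from the package internals.

# Mutual information via the entropy decomposition H(P) + H(Q) - H(P,Q).
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_entropy_oracle <- function(counts) {
  counts <- as.matrix(counts)
  N <- sum(counts)
  entropy_bits(rowSums(counts) / N) + entropy_bits(colSums(counts) / N) -
    entropy_bits(counts / N)
}

# Bin id per x-rank (1..n) given cut positions in count space.
bins_from_cuts <- function(n, cuts) {
  if (!length(cuts)) return(rep(1L, n))
  rowSums(outer(seq_len(n), cuts, FUN = ">")) + 1L
}

# Exhaustive search over every subset of at most max_bins - 1 cut positions
# (all n-1 positions, not just clump boundaries), maximizing grid mutual
# information against a fixed row partition. Only feasible for small n.
exhaustive_best_I <- function(sample, ypart, max_bins) {
  n <- sample$n
  xo <- order(sample$x)
  rows <- ypart$bin[xo]
  positions <- seq_len(n - 1L)
  best <- numeric(max_bins - 1L)  # indexed by bin count - 1
  for (k in 1:(max_bins - 1L)) {
    combs <- utils::combn(positions, k, simplify = FALSE)
    top <- 0
    for (cs in combs) {
      cols <- bins_from_cuts(n, cs)
      top <- max(top, mi_entropy_oracle(table(rows, cols)))
    }
    best[k] <- max(top, if (k > 1) best[k - 1L] else 0)
  }
  best  # entries for bin counts 2..max_bins (max over <= that many bins)
}

# Seeded small sample with distinct x values (no ties on either axis).
small_sample <- function(n, seed) {
  set.seed(seed)
  paired_sample(sample(seq_len(n)) + runif(n, -0.2, 0.2), rnorm(n))
}

# Random nondegenerate r x 2 count table.
random_rx2_table <- function(r, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(2 * r, 6) + 1L, nrow = r)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
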