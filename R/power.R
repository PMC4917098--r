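#' Permutation null for a paired sample
#'
#' Keeps `x` fixed and uniformly permutes `y`, destroying any association
#' while preserving both marginals.
#'
#' @param sample A [paired_sample()].
#' @param seed Optional integer seed.
#' @return A [paired_sample()] with the same multisets of values.
#' @export
permute_null <- function(sample, seed = NULL) {
  sample <- as_paired_sample(sample)
  with_seed(seed, paired_sample(sample$x, sample$y[sample.int(sample$n)]))
}

#' Configuration for power estimation
#'
#' Defaults follow the reference protocol: sample size 400, 500 trials per
#' condition, 25 noise amplitudes spaced logarithmically in `[1, 10]`, and
#' rejection above the 95th percentile of the pooled permutation-null
#' distribution.
#'
#' @param n Sample size per trial.
#' @param trials Number of Monte-Carlo trials (at least 1).
#' @param amplitudes Positive, sorted noise amplitudes.
#' @param quantile Null quantile used as the rejection cutoff, in (0, 1).
#' @param seed Integer seed for the whole experiment.
#' @return A `power_config` list.
#' @export
power_config <- function(n = 400, trials = 500,
                         amplitudes = 10^seq(0, 1, length.out = 25),
                         quantile = 0.95, seed = 1) {
  trials <- as.integer(trials)
  if (is.na(trials) || trials < 1L) stop_invalid("trials must be >= 1")
  if (quantile <= 0 || quantile >= 1)
    stop_invalid("quantile must lie in (0, 1)")
  if (any(amplitudes <= 0) || is.unsorted(amplitudes))
    stop_invalid("amplitudes must be positive and sorted")
  structure(list(n = as.integer(n), trials = trials,
                 amplitudes = as.numeric(amplitudes),
                 quantile = quantile, seed = seed),
            class = "power_config")
}

#' Statistical power of a bivariate statistic at one condition
#'
#' Generates `trials` true datasets of the given relationship and one
#' permuted null per true dataset; the nulls are pooled into a single null
#' distribution, and power is the fraction of true-data statistic values
#' strictly exceeding its `quantile` quantile.
#'
#' @param stat A function mapping a [paired_sample()] to a single number
#'   (e.g. `function(s) chimic_mic(s)$mic`).
#' @param relationship A [sample_power_study()] relationship name, or
#'   `"independent"` for the type-I calibration setting (power should then
#'   sit near `1 - quantile`).
#' @param amplitude Noise amplitude `a` (ignored for `"independent"`).
#' @param cfg A [power_config()].
#' @return The power estimate in `[0, 1]`.
#' @export
estimate_power <- function(stat, relationship, amplitude,
                           cfg = power_config()) {
  gen <- if (identical(relationship, "independent"))
    function() independent_pair(cfg$n)
  else
    function() sample_power_study(relationship, cfg$n, amplitude)
  with_seed(cfg$seed, {
    true_vals <- numeric(cfg$trials)
    null_vals <- numeric(cfg$trials)
    for (t in seq_len(cfg$trials)) {
      s <- gen()
      true_vals[t] <- stat(s)
      null_vals[t] <- stat(permute_null(s))
    }
    cutoff <- stats::quantile(null_vals, cfg$quantile, names = FALSE)
    mean(true_vals > cutoff)
  })
}

#' Power sweep over relationships and amplitudes
#'
#' Convenience wrapper running [estimate_power()] for every combination of
#' relationship and amplitude in the configuration, for one or several
#' statistics.
#'
#' @param stats Named list of statistic functions.
#' @param relationships Character vector of [sample_power_study()] names.
#' @param cfg A [power_config()]; each condition uses a seed derived from
#'   `cfg$seed` so conditions are independent but reproducible.
#' @return A data.frame with columns `statistic`, `relationship`,
#'   `amplitude`, `power`, `trials`.
#' @export
power_sweep <- function(stats, relationships = c("linear", "parabolic",
                                                 "sinusoidal", "circular",
                                                 "checkerboard"),
                        cfg = power_config()) {
  if (is.function(stats)) stats <- list(stat = stats)
  rows <- list()
  cond <- 0L
  for (rel in relationships) {
    for (a in cfg$amplitudes) {
      cond <- cond + 1L
      cfg_i <- cfg
      cfg_i$seed <- (cfg$seed + 7919L * cond) %% .Machine$integer.max
      for (sname in names(stats)) {
        rows[[length(rows) + 1L]] <- data.frame(
          statistic = sname, relationship = rel, amplitude = a,
          power = estimate_power(stats[[sname]], rel, a, cfg_i),
          trials = cfg$trials, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
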