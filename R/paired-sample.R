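#' Construct a paired bivariate sample
#'
#' The basic data object consumed by every statistic in the package: `n`
#' ordered `(x, y)` pairs together with the stable rank orders of each axis.
#' All grid statistics depend on the data only through these rank orders, so
#' they are invariant under strictly increasing transforms of either axis.
#'
#' @param x,y Numeric vectors of equal length (at least 2), no missing or
#'   non-finite values.
#' @return An object of class `paired_sample`: a list with elements `x`, `y`,
#'   `n`, and the stable ascending permutations `x_order`, `y_order`.
#' @examples
#' s <- paired_sample(runif(20), runif(20))
#' s$n
#' @export
paired_sample <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop_invalid("x and y must have the same length (got ",
                 length(x), " and ", length(y), ")")
  if (length(x) < 2L)
    stop_invalid("a paired sample needs at least 2 points")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("x and y must be finite and non-missing")
  structure(
    list(x = x, y = y, n = length(x),
         x_order = order(x), y_order = order(y)),
    class = "paired_sample")
}

as_paired_sample <- function(s) {
  if (inherits(s, "paired_sample")) return(s)
  if (is.list(s) && !is.null(s$x) && !is.null(s$y))
    return(paired_sample(s$x, s$y))
  if (is.matrix(s) || is.data.frame(s))
    return(paired_sample(s[[1]], s[[2]]))
  stop_invalid("cannot interpret input as a paired sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat("paired_sample: n =", x$n, "points\n")
  cat("  x: [", format(min(x$x)), ",", format(max(x$x)), "]\n")
  cat("  y: [", format(min(x$y)), ",", format(max(x$y)), "]\n")
  invisible(x)
}
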