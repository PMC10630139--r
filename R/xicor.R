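#' Chatterjee cross rank coefficient
#'
#' Computes Chatterjee's rank-based dependence coefficient \eqn{\xi_n(x, y)},
#' which approaches 1 when `y` is a (noisy) measurable function of `x` and 0
#' when the two are independent. Unlike correlation it is asymmetric:
#' `xicor(x, y)` asks how well `y` is explained by `x`.
#'
#' Ties in `x` are broken uniformly at random (a single draw controlled by
#' `seed`). Ties in `y` are handled by the general-ties formula
#' \deqn{\xi = 1 - \frac{n \sum_i |r_{i+1} - r_i|}{2 \sum_i l_i (n - l_i)},}
#' with \eqn{r_i = \#\{j : y_j \le y_{(i)}\}} and
#' \eqn{l_i = \#\{j : y_j \ge y_{(i)}\}} after sorting by `x`. This is
#' required here because the treatment vector is binary. Without ties in `y`
#' the formula reduces to \eqn{1 - 3\sum|r_{i+1}-r_i|/(n^2-1)}.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param seed Integer seed for the random tie-break in `x`.
#' @return A single number in \eqn{[-0.5, 1]}. A constant `y` makes the
#'   denominator zero; the sentinel 0 is returned with a warning.
#' @export
xicor <- function(x, y, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  ord <- with_seed(seed, order(x, sample.int(n)))
  ys <- y[ord]
  # doubles throughout: the sums overflow 32-bit integers for n in the 1000s
  r <- as.numeric(rank(ys, ties.method = "max"))  # #{j : y_j <= y_(i)}
  l <- n + 1 - as.numeric(rank(ys, ties.method = "min"))  # #{j : y_j >= y_(i)}
  denom <- 2 * sum(l * (n - l))
  if (denom == 0) {
    warning("xicor: constant y, returning sentinel 0")
    return(0)
  }
  1 - n * sum(abs(diff(r))) / denom
}
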