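#' Pairwise cost and Gibbs kernel between two cell sets
#'
#' Builds the Euclidean distance matrix between rows of `S0` (control) and
#' `S1` (treated) and the entropic-OT Gibbs kernel
#' \eqn{A_{ij} = \exp(-d_{ij}^2 / s)}.
#'
#' @param S0,S1 Numeric matrices sharing a column count.
#' @param smoothness Positive kernel bandwidth `s` (already scaled by the
#'   number of dimensions when called from [ot_match()]).
#' @return A list of class `cost_matrix` with `dist`, `kernel`, `log_kernel`
#'   (\eqn{-d^2/s}, kept for the stabilized solver), and `smoothness`.
#' @export
build_cost <- function(S0, S1, smoothness) {
  if (smoothness <= 0) stop("smoothness must be positive")
  S0 <- as.matrix(S0); S1 <- as.matrix(S1)
  stopifnot(ncol(S0) == ncol(S1))
  d2 <- cross_dist2(S0, S1)
  # snap numerically-zero distances (identical points) to exactly zero so
  # the kernel is exactly 1 there
  if (max(d2) > 0) d2[d2 < 1e-9 * max(d2)] <- 0
  lk <- -d2 / smoothness
  structure(list(dist = sqrt(d2), kernel = exp(lk), log_kernel = lk,
                 smoothness = smoothness),
            class = "cost_matrix")
}

#' Sinkhorn--Knopp scaling to prescribed marginals
#'
#' Alternately rescales rows and columns of a positive kernel until the
#' transport plan's marginals match `r` (rows) and `c` (columns) within `tol`
#' (max absolute deviation) or `max_iter` is reached. Kernel entries are
#' floored at 1e-300; if any row or column of the kernel lies entirely at the
#' floor the plain iteration cannot work and the call errors with guidance,
#' unless `log_kernel` is supplied, in which case a log-domain stabilized
#' iteration is used instead. The same fallback triggers automatically if the
#' plain iteration overflows. Both routes agree within `tol`.
#'
#' @param kernel Positive n0 x n1 matrix (e.g. `build_cost()$kernel`).
#' @param r,c Row/column marginals, nonnegative, each summing to 1.
#' @param tol Convergence tolerance on the marginals (default 1e-2).
#' @param max_iter Iteration cap (default 5000).
#' @param log_kernel Optional log of the kernel, enabling the stabilized
#'   fallback for severely underflowing kernels.
#' @return An object of class `matching_plan`: `plan` (n0 x n1, sums to 1),
#'   `row_marginal`, `col_marginal`, `converged`, `iterations`.
#' @export
sinkhorn <- function(kernel, r, c, tol = 1e-2, max_iter = 5000L,
                     log_kernel = NULL) {
  stopifnot(nrow(kernel) == length(r), ncol(kernel) == length(c))
  if (abs(sum(r) - 1) > 1e-8 || abs(sum(c) - 1) > 1e-8)
    stop("marginals must each sum to 1")
  floor_v <- 1e-300
  K <- pmax(kernel, floor_v)
  degenerate <- any(apply(K, 1L, max) <= floor_v) ||
    any(apply(K, 2L, max) <= floor_v)
  if (degenerate && is.null(log_kernel))
    stop("kernel fully underflowed in a row/column; increase smoothness")
  # a kernel spanning more dynamic range than doubles can scale through is
  # handled in the stabilized branch even though no row is fully floored
  extreme <- !is.null(log_kernel) && min(log_kernel) < -500

  if (!degenerate && !extreme) {
    u <- rep(1, length(r)); v <- rep(1, length(c))
    it <- 0L; converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      Kv <- as.vector(K %*% v)
      u <- r / Kv
      Ku <- as.vector(crossprod(K, u))
      v <- c / Ku
      if (!all(is.finite(u)) || !all(is.finite(v))) { u <- NULL; break }
      if (it %% 5L == 0L || it == max_iter) {
        rowdev <- max(abs(u * as.vector(K %*% v) - r))
        coldev <- max(abs(v * as.vector(crossprod(K, u)) - c))
        if (max(rowdev, coldev) < tol) { converged <- TRUE; break }
      }
    }
    if (!is.null(u)) {
      M <- u * K * rep(v, each = length(r))
      M <- M / sum(M)
      return(new_matching_plan(M, r, c, converged, it))
    }
    if (is.null(log_kernel)) stop("Sinkhorn overflow; increase smoothness")
  }

  # Absorption-stabilized iteration: plain row/column scaling on the
  # potential-shifted kernel exp(lk + f + g'), with the scalings absorbed
  # into the log potentials (via exact logsumexp updates) whenever they
  # drift towards overflow.
  lk <- log_kernel
  lr <- log(pmax(r, 1e-300)); lc <- log(pmax(c, 1e-300))
  g <- rep(0, length(c))
  f <- lr - row_logsumexp(sweep(lk, 2L, g, "+"))
  g <- lc - col_logsumexp(f + lk)
  Ks <- exp(f + sweep(lk, 2L, g, "+"))
  u <- rep(1, length(r)); v <- rep(1, length(c))
  it <- 0L; converged <- FALSE
  # small instances go straight to exact log-domain updates: the scaled
  # kernel can lock onto a wrong support when its dynamic range exceeds
  # what doubles represent, and at this size exactness costs nothing
  exact_mode <- length(lk) <= 10000L
  prev_dev <- Inf
  deviation <- function() {
    lM <- f + sweep(lk, 2L, g, "+")
    max(max(abs(exp(row_logsumexp(lM)) - r)),
        max(abs(exp(col_logsumexp(lM)) - c)))
  }
  absorb <- function() {
    f <<- lr - row_logsumexp(sweep(lk, 2L, g, "+"))
    g <<- lc - col_logsumexp(f + lk)
    Ks <<- exp(f + sweep(lk, 2L, g, "+"))
    u <<- rep(1, length(r)); v <<- rep(1, length(c))
  }
  while (it < max_iter) {
    it <- it + 1L
    if (exact_mode) {
      # pure log-domain alternation: slower per step but immune to the
      # zero-support lock-in of the scaled kernel
      f <- lr - row_logsumexp(sweep(lk, 2L, g, "+"))
      g <- lc - col_logsumexp(f + lk)
      if (it %% 10L == 0L || it == max_iter) {
        if (deviation() < tol) { converged <- TRUE; break }
      }
      next
    }
    Kv <- as.vector(Ks %*% v)
    u <- r / Kv
    Ku <- as.vector(crossprod(Ks, u))
    v <- c / Ku
    bad <- !all(is.finite(u)) || !all(is.finite(v))
    if (bad || max(abs(log(pmax(abs(u), 1e-300)))) > 200 ||
        max(abs(log(pmax(abs(v), 1e-300)))) > 200 ||
        it %% 200L == 0L) {
      # fold current scalings into the potentials where possible, then
      # re-derive both potentials exactly; if a full absorption cycle made
      # no headway the scaled-kernel dynamics are stuck (entries underflown
      # to zero pin the support) and only exact updates can proceed
      if (!bad) { f <- f + log(u); g <- g + log(v) }
      absorb()
      dev <- deviation()
      # switch to exact updates only on a genuine stall and only where an
      # exact iteration is cheap; large peaked kernels stay on the scaled
      # iteration, whose periodic re-absorption lets the support migrate
      if (dev >= prev_dev && length(lk) <= 10000L) exact_mode <- TRUE
      prev_dev <- dev
      next
    }
    if (it %% 10L == 0L || it == max_iter) {
      rowdev <- max(abs(u * as.vector(Ks %*% v) - r))
      coldev <- max(abs(v * as.vector(crossprod(Ks, u)) - c))
      if (max(rowdev, coldev) < tol) { converged <- TRUE; break }
    }
  }
  M <- if (exact_mode) exp(f + sweep(lk, 2L, g, "+")) else
    (u * Ks) * rep(v, each = length(r))
  M <- M / sum(M)
  new_matching_plan(M, r, c, converged, it)
}

new_matching_plan <- function(M, r, c, converged, iterations) {
  structure(list(plan = M, row_marginal = r, col_marginal = c,
                 converged = converged, iterations = iterations),
            class = "matching_plan")
}

#' @export
print.matching_plan <- function(x, ...) {
  cat(sprintf("matching_plan: %d control x %d treated, %s after %d iterations\n",
              nrow(x$plan), ncol(x$plan),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Entropic optimal-transport matching in confounder space
#'
#' Composes [build_cost()] and [sinkhorn()]. The effective kernel bandwidth is
#' `smoothness_per_dim * ncol(S0)`, so the per-dimension smoothness stays
#' comparable as the number of confounder components changes. Marginals
#' default to uniform; a `weights` list (`w0`, `w1`, nonnegative, any positive
#' totals) is normalized internally.
#'
#' @param S0,S1 Control / treated confounder source matrices.
#' @param weights Optional list with nonnegative vectors `w0` (length
#'   `nrow(S0)`) and `w1` (length `nrow(S1)`).
#' @param smoothness_per_dim Per-dimension bandwidth (default 1e-4; useful
#'   values usually lie in 1e-6..1e-3).
#' @param tol,max_iter Passed to [sinkhorn()].
#' @param smoothness_relative Alternative parameterization: when non-NULL,
#'   the bandwidth is `smoothness_relative * max(D^2)` (a regularization
#'   level relative to the max-normalized squared cost, the convention used
#'   by generic entropic-OT solvers) and `smoothness_per_dim` is ignored.
#' @return A `matching_plan`.
#' @export
ot_match <- function(S0, S1, weights = NULL, smoothness_per_dim = 1e-4,
                     tol = 1e-2, max_iter = 5000L,
                     smoothness_relative = NULL) {
  S0 <- as.matrix(S0); S1 <- as.matrix(S1)
  n0 <- nrow(S0); n1 <- nrow(S1)
  if (is.null(weights)) {
    r <- rep(1 / n0, n0); c <- rep(1 / n1, n1)
  } else {
    stopifnot(length(weights$w0) == n0, length(weights$w1) == n1,
              all(weights$w0 >= 0), all(weights$w1 >= 0),
              sum(weights$w0) > 0, sum(weights$w1) > 0)
    r <- weights$w0 / sum(weights$w0)
    c <- weights$w1 / sum(weights$w1)
  }
  s <- if (is.null(smoothness_relative)) smoothness_per_dim * ncol(S0) else
    smoothness_relative * max(cross_dist2(S0, S1))
  cost <- build_cost(S0, S1, s)
  sinkhorn(cost$kernel, r, c, tol = tol, max_iter = max_iter,
           log_kernel = cost$log_kernel)
}
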