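#' Independent component analysis of a PC embedding
#'
#' Factors a cells x p embedding into statistically independent source
#' components with symmetric FastICA (logcosh contrast) after PCA whitening.
#' Sources are mutually uncorrelated by construction (the rotation is kept
#' orthonormal by symmetric decorrelation at every step) and the run is fully
#' deterministic given `seed`. On nonconvergence the initialization is redrawn
#' from up to two further seeds; if none converges the last iterate is
#' returned with a warning.
#'
#' @param embedding Numeric matrix (cells x p), e.g. `pca_embedding()` scores.
#' @param rank Number of components to extract (`<= ncol(embedding)`).
#' @param seed Integer seed for the random orthonormal initialization.
#' @param max_iter,tol FastICA iteration controls.
#' @return An object of class `ica_decomposition` with `sources` (cells x
#'   rank, S), `unmixing` (p x rank, B with `S = (X - center) B`), `center`,
#'   `converged`, and placeholders `coefficients`, `confounder_idx`,
#'   `treatment_idx`, `threshold` filled by [partition_components()].
#' @export
ica_decompose <- function(embedding, rank, seed = 1L,
                          max_iter = 500L, tol = 1e-6) {
  x <- as.matrix(embedding)
  n <- nrow(x); p <- ncol(x)
  if (rank > p) stop("rank must not exceed the embedding dimension")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  # PCA whitening to `rank` dimensions: z = xc K, cov(z) = I.
  eg <- eigen(crossprod(xc) / n, symmetric = TRUE)
  d <- sqrt(pmax(eg$values[seq_len(rank)], .Machine$double.eps))
  K <- eg$vectors[, seq_len(rank), drop = FALSE] %*% diag(1 / d, rank)
  z <- xc %*% K

  sym_decorrelate <- function(w) {
    e <- eigen(tcrossprod(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)), rank) %*%
      crossprod(e$vectors, w)
  }
  run <- function(s) {
    w <- with_seed(s, matrix(rnorm(rank * rank), rank, rank))
    w <- sym_decorrelate(w)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      wx <- z %*% t(w)              # n x rank source estimates
      g <- tanh(wx)
      gp <- colMeans(1 - g^2)
      w1 <- crossprod(g, z) / n - gp * w
      w1 <- sym_decorrelate(w1)
      delta <- max(abs(abs(diag(tcrossprod(w1, w))) - 1))
      w <- w1
      if (delta < tol) { conv <- TRUE; break }
    }
    list(w = w, converged = conv)
  }
  res <- run(seed)
  try_seed <- seed
  while (!res$converged && try_seed < seed + 2L) {
    try_seed <- try_seed + 1L
    res <- run(try_seed)
  }
  if (!res$converged)
    warning("FastICA did not converge after 3 initializations; ",
            "returning last iterate")
  B <- K %*% t(res$w)
  structure(list(sources = xc %*% B, unmixing = B, center = ctr,
                 converged = res$converged, coefficients = NULL,
                 confounder_idx = NULL, treatment_idx = NULL,
                 threshold = NULL, seed = seed),
            class = "ica_decomposition")
}

#' Partition independent components into confounder and treatment sets
#'
#' Scores every source component against the binary treatment vector with the
#' Chatterjee coefficient [xicor()] and flags components with coefficient
#' below `threshold` as confounder variation; the rest are treatment-
#' associated. A higher threshold tolerates fewer false-positive treatment
#' signals (matching becomes more local); a lower threshold tolerates fewer
#' false-positive confounders (matching becomes coarser).
#'
#' @param decomp An `ica_decomposition` from [ica_decompose()].
#' @param treatment Binary vector, one entry per cell.
#' @param threshold Cutoff in (0, 1) on the coefficient (default 0.5).
#' @param seed Seed for the xicor tie-break.
#' @return The decomposition with `coefficients`, `confounder_idx`,
#'   `treatment_idx`, and `threshold` filled in.
#' @export
partition_components <- function(decomp, treatment, threshold = 0.5,
                                 seed = decomp$seed) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  z <- as_binary_treatment(treatment)
  r <- ncol(decomp$sources)
  co <- vapply(seq_len(r),
               function(i) xicor(decomp$sources[, i], z, seed = seed),
               numeric(1))
  conf <- which(co < threshold)
  if (length(conf) == 0L)
    stop("no confounder signal; lower threshold or raise rank")
  decomp$coefficients <- co
  decomp$confounder_idx <- conf
  decomp$treatment_idx <- setdiff(seq_len(r), conf)
  decomp$threshold <- threshold
  decomp
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("ica_decomposition: %d cells x %d components%s\n",
              nrow(x$sources), ncol(x$sources),
              if (x$converged) "" else " (not converged)"))
  if (!is.null(x$coefficients))
    cat(sprintf("  %d confounder / %d treatment-associated (threshold %.3g)\n",
                length(x$confounder_idx), length(x$treatment_idx), x$threshold))
  invisible(x)
}
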