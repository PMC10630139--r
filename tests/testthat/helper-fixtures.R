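# Shared fixtures, built in code at test time.

# Brute-force rank-counting Chatterjee coefficient: the independent oracle.
# x must be free of ties so the permutation is unambiguous.
xicor_oracle <- function(x, y) {
  stopifnot(!anyDuplicated(x))
  n <- length(x)
  ys <- y[order(x)]
  r <- vapply(seq_len(n), function(i) sum(ys <= ys[i]), numeric(1))
  l <- vapply(seq_len(n), function(i) sum(ys >= ys[i]), numeric(1))
  denom <- 2 * sum(l * (n - l))
  if (denom == 0) return(0)
  1 - n * sum(abs(diff(r))) / denom
}

# Exact entropic-free OT cost <M, D^2> for uniform marginals by enumerating
# all permutation couplings (Birkhoff: some permutation is optimal).
lp_ot_cost <- function(d2) {
  n <- nrow(d2)
  stopifnot(n == ncol(d2), n <= 7)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, mean(d2[cbind(seq_len(n), p)]))
  best
}

# Small two-state dataset with a clean treatment shift, for pipeline tests.
make_shift_dataset <- function(n_per = 100L, n_conf_genes = 60L,
                               n_shift_genes = 20L, shift = 0.8,
                               noise_sd = 0.4, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per
  state <- rep(1:2, each = n_per)
  base <- matrix(rnorm(n * n_conf_genes, mean = 2, sd = noise_sd),
                 n, n_conf_genes)
  base[state == 2, seq_len(20)] <- base[state == 2, seq_len(20)] + 1.5
  resp <- matrix(rnorm(n * n_shift_genes, mean = 2, sd = noise_sd),
                 n, n_shift_genes)
  x0 <- cbind(base, resp)
  x1 <- x0
  x1[, n_conf_genes + seq_len(n_shift_genes)] <-
    x1[, n_conf_genes + seq_len(n_shift_genes)] + shift
  values <- rbind(x0, x1)
  colnames(values) <- c(paste0("conf", seq_len(n_conf_genes)),
                        paste0("shift", seq_len(n_shift_genes)))
  expression_dataset(values, rep(c(0L, 1L), each = n), counts = FALSE,
                     cell_labels = factor(rep(state, 2L)))
}

small_sim <- function(seed = 1L, n_cells = 400L, ...) {
  simulate_dataset(simulation_config(
    n_cells = n_cells, n_confounder_genes = 150L, n_response_genes = 80L,
    seed = seed, ...))
}

# First-PC scores of a centered matrix (independent of the package PCA).
pca_scores1 <- function(x) {
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 1)
  p$x[, 1]
}

# Largest principal angle (degrees) between the column spans of two matrices.
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(scale(A, scale = FALSE)))
  qb <- qr.Q(qr(scale(B, scale = FALSE)))
  d <- min(ncol(qa), ncol(qb))
  s <- svd(crossprod(qa, qb))$d[seq_len(d)]
  max(acos(pmin(pmax(s, -1), 1))) * 180 / pi
}

lognorm_of <- function(ds) {
  libs <- rowSums(ds$values)
  log1p(ds$values / libs * median(libs))
}

# Ground truth: response genes carrying any cluster signature.
gene_is_signature <- function(sim) {
  colSums(abs(sim$response_signatures)) > 0
}
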