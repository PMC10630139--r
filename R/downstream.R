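#' Synergy matrix for a combinatorial treatment
#'
#' For two treatments A and B and their combination AB, all run against the
#' SAME control population, the synergy matrix is the deviation of the
#' combined effect from additivity:
#' \deqn{\Psi = D_{AB} - (D_A + D_B).}
#' When the ITEs were computed on log1p-normalized expression the additive
#' null on the log scale corresponds to multiplicative synergy on counts;
#' on library-size-normalized (non-log) values it tests additive synergy.
#'
#' @param ite_A,ite_B,ite_AB ITE matrices (from [compute_ite()] or
#'   `fit$ite`), all with direction `counterfactual_for_control`, identical
#'   shapes, and the same control-cell ordering.
#' @return A list of class `synergy_matrix` with `psi` (cells x genes) and
#'   `mode` (`"multiplicative"` for log input, else `"additive"`).
#' @export
synergy_matrix <- function(ite_A, ite_B, ite_AB) {
  mats <- list(ite_A, ite_B, ite_AB)
  dims <- lapply(mats, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("ITE matrices must share dimensions and control population")
  dirs <- vapply(mats, function(m) {
    d <- attr(m, "direction")
    if (is.null(d)) "counterfactual_for_control" else d
  }, character(1))
  if (!all(dirs == "counterfactual_for_control"))
    stop("synergy requires direction = counterfactual_for_control for all ITEs")
  rn <- lapply(mats, rownames)
  if (!is.null(rn[[1]]) &&
      !all(vapply(rn, identical, logical(1), rn[[1]])))
    stop("ITE matrices reference different control cells")
  spaces <- vapply(mats, function(m) {
    s <- attr(m, "space"); if (is.null(s)) "expression" else s
  }, character(1))
  psi <- unclass(ite_AB) - unclass(ite_A) - unclass(ite_B)
  attributes(psi) <- list(dim = dim(psi), dimnames = dimnames(psi))
  structure(list(psi = psi,
                 mode = if (all(spaces == "expression")) "multiplicative"
                        else "additive"),
            class = "synergy_matrix")
}

#' Per-gene synergy score
#'
#' Absolute value of the cell-averaged synergy, \eqn{|\bar\Psi_{g}|}. Under
#' the relaxed null that cells do not have opposite-signed synergy, a large
#' score flags a synergistic gene; sign cancellation across cells is
#' intentional.
#'
#' @param psi A `synergy_matrix` (or bare cells x genes matrix).
#' @return Named nonnegative numeric vector, one score per gene.
#' @export
gene_synergy_score <- function(psi) {
  m <- if (inherits(psi, "synergy_matrix")) psi$psi else as.matrix(psi)
  if (nrow(m) < 1L) stop("need at least one cell")
  abs(colMeans(m))
}

#' Per-cell synergy score over strongly synergistic genes
#'
#' Euclidean norm of each cell's synergy row restricted to genes whose
#' [gene_synergy_score()] is at least `gene_threshold` (default 0.15).
#'
#' @param psi A `synergy_matrix`.
#' @param gene_threshold Gene score cutoff.
#' @return Nonnegative numeric vector, one score per cell.
#' @export
cell_synergy_score <- function(psi, gene_threshold = 0.15) {
  m <- if (inherits(psi, "synergy_matrix")) psi$psi else as.matrix(psi)
  gs <- gene_synergy_score(psi)
  sel <- which(gs >= gene_threshold)
  if (length(sel) == 0L)
    stop(sprintf("no gene passes threshold %.3g (max score %.3g)",
                 gene_threshold, max(gs)))
  sqrt(rowSums(m[, sel, drop = FALSE]^2))
}

#' Coarse-grained matching between response and control clusters
#'
#' Aggregates a cell-level matching plan into a response-cluster x
#' control-cluster matrix: entry (a, b) is the total transport mass between
#' treated cells in response cluster a and control cells in control cluster
#' b. The row-normalized view attributes each response mode to control
#' clusters; the column-normalized view gives each control cluster's
#' likelihood over response modes.
#'
#' @param plan A `matching_plan` (rows = control, columns = treated).
#' @param response_labels Categorical labels on the treated axis (e.g. Leiden
#'   clusters of the ITE matrix).
#' @param control_labels Categorical labels on the control axis (cell
#'   subtypes).
#' @return A list of class `coarse_matching` with `matrix` (row-normalized),
#'   `col_normalized`, `mass` (raw), and the label levels.
#' @export
coarse_grain_matching <- function(plan, response_labels, control_labels) {
  M <- if (inherits(plan, "matching_plan")) plan$plan else as.matrix(plan)
  rl <- droplevels(as.factor(response_labels))
  cl <- droplevels(as.factor(control_labels))
  stopifnot(length(rl) == ncol(M), length(cl) == nrow(M))
  if (nlevels(as.factor(response_labels)) > nlevels(rl) ||
      nlevels(as.factor(control_labels)) > nlevels(cl))
    warning("empty label level(s) dropped")
  Ra <- outer(rl, levels(rl), "==") * 1          # treated x A
  Cb <- outer(cl, levels(cl), "==") * 1          # control x B
  mass <- t(Ra) %*% t(M) %*% Cb                  # A x B
  dimnames(mass) <- list(levels(rl), levels(cl))
  rs <- rowSums(mass)
  zero <- rs == 0
  if (any(zero)) {
    warning("response cluster(s) with zero mass dropped: ",
            paste(rownames(mass)[zero], collapse = ", "))
    mass <- mass[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  cs <- colSums(mass)
  cs[cs == 0] <- 1
  structure(list(matrix = mass / rs,
                 col_normalized = sweep(mass, 2L, cs, "/"),
                 mass = mass,
                 response_labels = rl, control_labels = cl),
            class = "coarse_matching")
}

#' Cluster cells by treatment response
#'
#' Leiden clustering of an ITE matrix (on its top principal components),
#' grouping cells with similar estimated treatment responses. These labels
#' are the natural response-side input to [coarse_grain_matching()].
#'
#' @param ite ITE matrix (reference cells x genes).
#' @param resolution Leiden resolution (default 0.3: response modes are
#'   typically few and coarse).
#' @param n_pcs,k Graph construction parameters.
#' @param seed Seed.
#' @return Integer cluster label per ITE row.
#' @export
cluster_ite <- function(ite, resolution = 0.3, n_pcs = 20L, k = 15L,
                        seed = 1L) {
  m <- as.matrix(ite)
  emb <- pca_embed(m, min(n_pcs, ncol(m), nrow(m) - 1L))$scores
  leiden_cluster(emb, resolution = resolution, k = min(k, nrow(m) - 1L),
                 seed = seed)
}

#' Attribution regression of expression on treatment and confounders
#'
#' Fits the per-gene linear model
#' \deqn{X = \alpha z + \beta c + \gamma c z + \mathrm{const}}
#' by ordinary least squares, where z is the treatment indicator and c the
#' confounder design (one-hot labels or continuous sources). The interaction
#' term \eqn{\gamma c z} captures confounder-specific treatment effects; its
#' strength is summarized as the l2-norm ratio between the interaction's
#' fitted values and the residual, which stays meaningful when the residual
#' carries latent-factor effects rather than iid noise.
#'
#' @param expr Numeric vector (one gene) or cells x genes matrix.
#' @param treatment Binary vector per cell.
#' @param confounder Vector, factor, or design matrix of confounders.
#' @return For a single gene, a list of class `attribution_fit` with
#'   `alpha`, `beta`, `gamma`, `intercept`, `ratio`, `ratio_infinite`,
#'   `residual_norm`. For a matrix, a data.frame with one row per gene
#'   (`alpha`, `ratio`, `ratio_infinite`, plus `beta`/`gamma` norms).
#' @export
attribution_regression <- function(expr, treatment, confounder) {
  z <- as_binary_treatment(treatment)
  C <- if (is.factor(confounder) || is.character(confounder)) {
    stats::model.matrix(~ factor(confounder))[, -1, drop = FALSE]
  } else as.matrix(confounder)
  stopifnot(nrow(C) == length(z))
  CZ <- C * z
  design <- cbind(intercept = 1, z = z, C, CZ)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("rank-deficient design: confounder columns collinear with treatment")
  Y <- as.matrix(expr)
  if (nrow(Y) != length(z)) stop("expr rows must match treatment length")
  fit <- qr.coef(qrd, Y)
  res <- Y - design %*% fit
  p <- ncol(C)
  gamma_rows <- (2L + p + 1L):(2L + 2L * p)
  gamma_fit <- CZ %*% fit[gamma_rows, , drop = FALSE]
  gnorm <- sqrt(colSums(gamma_fit^2))
  rnorm_ <- sqrt(colSums(res^2))
  inf_flag <- rnorm_ < 1e-10
  ratio <- ifelse(inf_flag, Inf, gnorm / rnorm_)
  if (ncol(Y) == 1L) {
    structure(list(alpha = unname(fit[2L, 1L]),
                   beta = unname(fit[3:(2L + p), 1L]),
                   gamma = unname(fit[gamma_rows, 1L]),
                   intercept = unname(fit[1L, 1L]),
                   ratio = unname(ratio[1L]),
                   ratio_infinite = unname(inf_flag[1L]),
                   residual_norm = unname(rnorm_[1L])),
              class = "attribution_fit")
  } else {
    data.frame(gene = if (is.null(colnames(Y)))
                 paste0("gene", seq_len(ncol(Y))) else colnames(Y),
               alpha = fit[2L, ],
               beta_norm = sqrt(colSums(fit[3:(2L + p), , drop = FALSE]^2)),
               gamma_norm = sqrt(colSums(fit[gamma_rows, , drop = FALSE]^2)),
               ratio = as.numeric(ratio),
               ratio_infinite = as.logical(inf_flag),
               row.names = NULL)
  }
}

#' @export
print.attribution_fit <- function(x, ...) {
  cat(sprintf("attribution_fit: alpha=%.4g, ratio=%s\n", x$alpha,
              if (x$ratio_infinite) "Inf (interpolating fit)"
              else sprintf("%.4g", x$ratio)))
  invisible(x)
}

#' Exact/approximate Wilcoxon signed-rank test against zero
#'
#' Two-sided one-sample signed-rank test of `x` against location 0. Zeros are
#' dropped; ties in `|x|` get average ranks. For n <= 12 the null is
#' enumerated exactly over all sign flips (so tied data still get exact
#' p-values, e.g. p = 2/32 for five concordant equal values); beyond that a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x Numeric vector.
#' @return List with `statistic` (V), `p_value`, `n` (nonzero values),
#'   `exact`.
#' @export
signed_rank_test <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) return(list(statistic = NA_real_, p_value = NA_real_,
                           n = 0L, exact = TRUE))
  rk <- rank(abs(x))
  V <- sum(rk[x > 0])
  mu <- n * (n + 1) / 4
  if (n <= 12L) {
    # all 2^n sign assignments; V under each
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vnull <- as.vector(signs %*% rk)
    p_low <- mean(Vnull <= V + 1e-9)
    p_high <- mean(Vnull >= V - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(statistic = V, p_value = p, n = n, exact = TRUE))
  }
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  zstat <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(zstat)))
  list(statistic = V, p_value = p, n = n, exact = FALSE)
}

#' Select differentially expressed genes from an ITE matrix
#'
#' Per gene, a two-sided Wilcoxon signed-rank test of the matched ITE values
#' against zero; a gene passes when `p < p_threshold` and the absolute mean
#' ITE exceeds `delta_threshold`. The defaults (1e-5, 0.5 on log-normalized
#' differences) give a gene list ready for external enrichment tools.
#'
#' @param ite ITE matrix (cells x genes).
#' @param p_threshold P-value cutoff (default 1e-5).
#' @param delta_threshold Cutoff on |mean ITE| (default 0.5).
#' @return data.frame sorted by p then effect size: `gene`, `effect` (mean
#'   ITE), `median_effect`, `p`, `pass`.
#' @export
select_de_genes <- function(ite, p_threshold = 1e-5, delta_threshold = 0.5) {
  m <- as.matrix(ite)
  if (nrow(m) < 6L) stop("need at least 6 cells for the signed-rank test")
  res <- apply(m, 2L, function(v) signed_rank_test(v)$p_value)
  eff <- colMeans(m)
  med <- apply(m, 2L, stats::median)
  pass <- !is.na(res) & res < p_threshold & abs(eff) > delta_threshold
  out <- data.frame(
    gene = if (is.null(colnames(m))) paste0("gene", seq_len(ncol(m)))
           else colnames(m),
    effect = eff, median_effect = med, p = res, pass = pass,
    row.names = NULL)
  out[order(out$p, -abs(out$effect)), ]
}
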