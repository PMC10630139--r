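#' Counterfactual cell matching and individual treatment effects
#'
#' Fits the full causal matching model to a two-condition single-cell
#' experiment: a PC embedding of the (log-normalized) expression matrix is
#' factored into independent components, components are split into confounder
#' vs treatment-associated variation by thresholding the Chatterjee
#' coefficient against the treatment label, control and treated cells are
#' matched by entropy-regularized optimal transport in the confounder
#' subspace only, and the matching plan is used to impute counterfactual
#' expression and per-cell, per-gene individual treatment effects (ITE).
#'
#' With `balance = "auto"` a reweighting preprocessing is run first to handle
#' treatment-induced differential abundance: treated cells are aligned to the
#' mean of their `k` nearest control neighbours in PC space, the aligned cell
#' set is Leiden-clustered, and within every cluster the more abundant
#' condition is subsampled to the other's size (clusters present in only one
#' condition are dropped). The ICA and its component filter are then fitted on
#' the balanced subsample; with `apply_to_full = TRUE` (the default) the
#' fitted unmixing is applied to all cells so matching and ITE cover the full
#' dataset. `balance = "labels"` instead reweights the OT marginals so each
#' level of `labels` carries equal total mass in both conditions
#' (see [weights_from_labels()]).
#'
#' @param object An [expression_dataset()], or a numeric cells x genes matrix
#'   (then `treatment` is required).
#' @param treatment Binary vector when `object` is a bare matrix.
#' @param rank Number of independent components (signal dimensions). The
#'   default 30 sits in the 20--50 range that works robustly; see
#'   [estimate_rank()] for data-driven selection via `rank_method`.
#' @param rank_method `"prespecified"` (default) or `"biwhitening"` (requires
#'   count input; falls back to `rank` if no signal is detected).
#' @param threshold Chatterjee-coefficient cutoff in (0,1) separating
#'   confounder from treatment-associated components (default 0.5).
#' @param smoothness_per_dim Per-dimension OT kernel bandwidth (default 1e-4).
#' @param tol,max_iter Sinkhorn controls (defaults 1e-2, 5000).
#' @param balance `"none"`, `"auto"` (cluster-balanced subsampling), or
#'   `"labels"` (marginal reweighting by `labels`).
#' @param labels Per-cell confounder labels for `balance = "labels"` (defaults
#'   to the dataset's `cell_labels`).
#' @param k Neighbours for the alignment step of `balance = "auto"`
#'   (default 20).
#' @param resolution Leiden resolution for the balancing clusters (default 1).
#' @param apply_to_full Apply the subsample-fitted unmixing to all cells
#'   (default TRUE).
#' @param n_pcs Dimension of the PC embedding fed to ICA (default = `rank`).
#' @param ite_space `"expression"` (default; log-normalized gene space) or
#'   `"pc"`.
#' @param direction Whose counterfactual the ITE rows describe:
#'   `"counterfactual_for_control"` (rows = control cells, default) or
#'   `"counterfactual_for_treated"`.
#' @param filter_components Set to `FALSE` to skip the confounder filter and
#'   transport on all components (the full-OT ablation).
#' @param smoothness_relative Optional relative OT regularization passed to
#'   [ot_match()]; overrides `smoothness_per_dim` when set. Used by the
#'   full-OT ablation, which conventionally regularizes at a fixed level
#'   (0.1) of the max-normalized squared cost.
#' @param seed Integer seed controlling ICA initialization, xicor tie-breaks,
#'   and the balancing subsample.
#' @return An object of class `sccot` with components `decomposition`
#'   (`ica_decomposition`), `plan` (`matching_plan`), `ite` (matrix with
#'   attributes `direction` and `space`), `embedding` (all-cell PC scores),
#'   `confounder` (all-cell confounder sources), `treatment`, `expr`
#'   (log-normalized expression), `balance` (a `w_preprocess` state or NULL),
#'   and `config`.
#' @seealso [synergy_matrix()], [attribution_regression()],
#'   [select_de_genes()], [simulate_dataset()]
#' @examples
#' sim <- simulate_dataset(simulation_config(n_cells = 300,
#'   n_confounder_genes = 120, n_response_genes = 60, seed = 1))
#' fit <- sccot(sim$dataset, rank = 8, seed = 1)
#' fit
#' @export
sccot <- function(object, treatment = NULL, rank = 30L,
                  rank_method = c("prespecified", "biwhitening"),
                  threshold = 0.5, smoothness_per_dim = 1e-4,
                  tol = 1e-2, max_iter = 5000L,
                  balance = c("none", "auto", "labels"), labels = NULL,
                  k = 20L, resolution = 1, apply_to_full = TRUE,
                  n_pcs = NULL, ite_space = c("expression", "pc"),
                  direction = c("counterfactual_for_control",
                                "counterfactual_for_treated"),
                  filter_components = TRUE, smoothness_relative = NULL,
                  seed = 1L) {
  rank_method <- match.arg(rank_method)
  balance <- match.arg(balance)
  ite_space <- match.arg(ite_space)
  direction <- match.arg(direction)
  ds <- if (inherits(object, "expression_dataset")) object else
    expression_dataset(object, treatment)
  z <- ds$treatment

  expr <- if (ds$counts) lognormalize(ds$values) else ds$values
  if (rank_method == "biwhitening") {
    if (!ds$counts) stop("biwhitening rank estimation requires count input")
    re <- estimate_rank(ds$values, method = "biwhitening")
    if (re$rank >= 1L) rank <- min(re$rank, min(dim(expr)))
  }
  rank <- as.integer(rank)
  if (is.null(n_pcs)) n_pcs <- rank
  n_pcs <- min(n_pcs, nrow(expr) - 1L, ncol(expr))
  if (rank > n_pcs) stop("rank must not exceed n_pcs")
  pca <- pca_embed(expr, n_pcs)
  X <- pca$scores

  bal <- NULL
  fit_idx <- seq_len(nrow(X))
  if (balance == "auto") {
    aligned <- X
    aligned[z == 1, ] <- knn_align(X[z == 0, , drop = FALSE],
                                   X[z == 1, , drop = FALSE], k = k)
    bal <- balanced_subsample(aligned, z, resolution = resolution, seed = seed)
    bal$k <- k
    fit_idx <- bal$kept_indices
  }

  decomp <- ica_decompose(X[fit_idx, , drop = FALSE], rank, seed = seed)
  if (filter_components) {
    decomp <- partition_components(decomp, z[fit_idx], threshold = threshold,
                                   seed = seed)
  } else {
    r <- ncol(decomp$sources)
    decomp$coefficients <- vapply(seq_len(r), function(i)
      xicor(decomp$sources[, i], z[fit_idx], seed = seed), numeric(1))
    decomp$confounder_idx <- seq_len(r)
    decomp$treatment_idx <- integer(0)
    decomp$threshold <- NA_real_
  }

  use_full <- (balance != "auto") || apply_to_full
  if (use_full) {
    S_all <- sweep(X, 2L, decomp$center, "-") %*% decomp$unmixing
    keep <- seq_len(nrow(X))
  } else {
    S_all <- decomp$sources
    keep <- fit_idx
  }
  Sc <- S_all[, decomp$confounder_idx, drop = FALSE]
  zk <- z[keep]
  i0 <- which(zk == 0); i1 <- which(zk == 1)

  weights <- NULL
  if (balance == "labels") {
    lab <- if (is.null(labels)) ds$cell_labels else as.factor(labels)
    if (is.null(lab)) stop("balance = 'labels' requires labels")
    weights <- weights_from_labels(lab[keep], zk)
  }

  plan <- ot_match(Sc[i0, , drop = FALSE], Sc[i1, , drop = FALSE],
                   weights = weights,
                   smoothness_per_dim = smoothness_per_dim,
                   tol = tol, max_iter = max_iter,
                   smoothness_relative = smoothness_relative)

  mat <- if (ite_space == "expression") expr[keep, , drop = FALSE] else
    X[keep, , drop = FALSE]
  ite <- compute_ite(mat[i0, , drop = FALSE], mat[i1, , drop = FALSE],
                     plan, direction = direction, space = ite_space)

  structure(list(
    decomposition = decomp, plan = plan, ite = ite,
    embedding = X, confounder = Sc, treatment = z, expr = expr,
    cell_index = keep, control_index = keep[i0], treated_index = keep[i1],
    balance = bal, dataset = ds,
    config = list(rank = rank, rank_method = rank_method,
                  threshold = threshold,
                  smoothness_per_dim = smoothness_per_dim, tol = tol,
                  max_iter = max_iter, balance = balance, k = k,
                  resolution = resolution, apply_to_full = apply_to_full,
                  n_pcs = n_pcs, ite_space = ite_space,
                  direction = direction,
                  filter_components = filter_components,
                  smoothness_relative = smoothness_relative, seed = seed),
    call = match.call()),
    class = "sccot")
}

#' Individual treatment effects from a matching plan
#'
#' For the control direction, each control cell's counterfactual treated
#' expression is the plan-row-weighted average of treated cells,
#' \eqn{\hat x_i = (M_{i\cdot}/\sum_j M_{ij})\, X_1}, and
#' \eqn{ITE_i = \hat x_i - x_{0,i}}. The treated direction uses the
#' column-normalized transpose symmetrically, \eqn{ITE_j = x_{1,j} - \hat
#' x_j}. Either way positive entries mean treatment increases expression.
#' Scaling any plan row (column) by a constant leaves the result unchanged.
#'
#' @param expr0,expr1 Control / treated expression (or embedding) matrices.
#' @param plan A `matching_plan` (or bare n0 x n1 matrix).
#' @param direction Which population the rows describe.
#' @param space Bookkeeping tag (`"expression"` or `"pc"`).
#' @return Matrix of class `ite_matrix` with attributes `direction`, `space`.
#' @export
compute_ite <- function(expr0, expr1, plan,
                        direction = c("counterfactual_for_control",
                                      "counterfactual_for_treated"),
                        space = "expression") {
  direction <- match.arg(direction)
  M <- if (inherits(plan, "matching_plan")) plan$plan else as.matrix(plan)
  expr0 <- as.matrix(expr0); expr1 <- as.matrix(expr1)
  stopifnot(nrow(M) == nrow(expr0), ncol(M) == nrow(expr1))
  if (direction == "counterfactual_for_control") {
    rs <- rowSums(M)
    if (any(rs == 0)) stop("zero row in plan: cannot normalize")
    ite <- (M / rs) %*% expr1 - expr0
  } else {
    cs <- colSums(M)
    if (any(cs == 0)) stop("zero column in plan: cannot normalize")
    ite <- expr1 - crossprod(M, expr0) / cs
  }
  structure(ite, direction = direction, space = space, class = c("ite_matrix", "matrix"))
}

#' Marginal weights from confounder labels
#'
#' Builds OT marginal weights such that within each label cells are weighted
#' uniformly and each label's total mass is equal across the two conditions
#' and proportional to the label's pooled frequency.
#'
#' @param labels Per-cell categorical labels.
#' @param treatment Binary vector aligned with `labels`.
#' @return A list with `w0` (control weights) and `w1` (treated weights),
#'   each summing to 1.
#' @export
weights_from_labels <- function(labels, treatment) {
  z <- as_binary_treatment(treatment)
  lab <- as.factor(labels)
  stopifnot(length(lab) == length(z))
  lev <- levels(droplevels(lab))
  n0l <- table(factor(lab[z == 0], levels = lev))
  n1l <- table(factor(lab[z == 1], levels = lev))
  missing <- lev[n0l == 0 | n1l == 0]
  if (length(missing))
    stop("label(s) missing from one condition: ",
         paste(missing, collapse = ", "))
  pooled <- (n0l + n1l) / length(z)
  w0 <- as.numeric(pooled[lab[z == 0]] / n0l[lab[z == 0]])
  w1 <- as.numeric(pooled[lab[z == 1]] / n1l[lab[z == 1]])
  list(w0 = w0 / sum(w0), w1 = w1 / sum(w1))
}

#' Align treated cells to their nearest control neighbours
#'
#' Replaces each treated cell's embedding by the mean embedding of its `k`
#' nearest control cells (Euclidean), removing the treatment displacement
#' while preserving confounder position.
#'
#' @param X0 Control embedding (n0 x d).
#' @param X1 Treated embedding (n1 x d).
#' @param k Number of neighbours, `1 <= k <= nrow(X0)`.
#' @return n1 x d matrix of aligned treated embeddings.
#' @export
knn_align <- function(X0, X1, k = 20L) {
  if (k < 1) stop("k must be >= 1")
  X0 <- as.matrix(X0); X1 <- as.matrix(X1)
  if (k > nrow(X0)) stop("k must not exceed the number of control cells")
  nn <- knn_indices(X1, X0, k)
  t(apply(nn, 1L, function(idx) colMeans(X0[idx, , drop = FALSE])))
}

#' Cluster-balanced subsampling of an aligned embedding
#'
#' Leiden-clusters the (aligned) embedding of all cells, then within each
#' cluster randomly subsamples the condition with more cells down to the
#' other condition's count; clusters where one condition is absent are
#' dropped entirely. The retained cells have, per cluster, equal control and
#' treated counts, making the confounder signal independent of the treatment
#' event.
#'
#' @param aligned Numeric matrix, all cells x dims (treated rows already
#'   aligned into the control manifold).
#' @param treatment Binary vector per cell.
#' @param resolution Leiden resolution (> 0).
#' @param seed Seed for clustering and the subsample draws.
#' @param knn_k Neighbours for the clustering graph (default 15).
#' @return A list of class `w_preprocess`: `aligned_embedding`,
#'   `leiden_labels`, `kept_indices`, `resolution`, `seed`.
#' @export
balanced_subsample <- function(aligned, treatment, resolution = 1, seed = 1L,
                               knn_k = 15L) {
  if (resolution <= 0) stop("resolution must be positive")
  z <- as_binary_treatment(treatment)
  aligned <- as.matrix(aligned)
  stopifnot(nrow(aligned) == length(z))
  lab <- leiden_cluster(aligned, resolution = resolution, k = knn_k,
                        seed = seed)
  kept <- integer(0)
  with_seed(seed + 1L, {
    for (a in sort(unique(lab))) {
      i0 <- which(lab == a & z == 0)
      i1 <- which(lab == a & z == 1)
      if (length(i0) == 0L || length(i1) == 0L) next  # subsample to zero
      if (length(i0) > length(i1)) {
        i0 <- sort(sample(i0, length(i1)))
      } else if (length(i1) > length(i0)) {
        i1 <- sort(sample(i1, length(i0)))
      }
      kept <- c(kept, i0, i1)
    }
  })
  if (length(kept) == 0L) stop("conditions do not overlap in any cluster")
  structure(list(aligned_embedding = aligned, leiden_labels = lab,
                 kept_indices = sort(kept), resolution = resolution,
                 seed = seed, k = NA_integer_),
            class = "w_preprocess")
}

#' Extract the individual-treatment-effect matrix
#' @param object A fitted `sccot` object.
#' @param ... Unused.
#' @return The ITE matrix (cells of the reference population x genes).
#' @export
ite <- function(object, ...) UseMethod("ite")

#' @export
ite.sccot <- function(object, ...) object$ite

#' @export
print.sccot <- function(x, ...) {
  d <- x$decomposition
  cat("Counterfactual OT matching fit (sccot)\n")
  cat(sprintf("  cells: %d control / %d treated; genes: %d\n",
              length(x$control_index), length(x$treated_index),
              ncol(x$expr)))
  cat(sprintf("  components: %d total, %d confounder, %d treatment-associated",
              ncol(d$sources), length(d$confounder_idx),
              length(d$treatment_idx)))
  if (!is.na(d$threshold)) cat(sprintf(" (threshold %.3g)", d$threshold))
  cat("\n")
  cat(sprintf("  transport: %s after %d iterations; ITE %d x %d (%s, %s)\n",
              if (x$plan$converged) "converged" else "NOT converged",
              x$plan$iterations, nrow(x$ite), ncol(x$ite),
              attr(x$ite, "space"), attr(x$ite, "direction")))
  if (!is.null(x$balance))
    cat(sprintf("  balancing: %d of %d cells kept in %d clusters\n",
                length(x$balance$kept_indices), nrow(x$embedding),
                length(unique(x$balance$leiden_labels))))
  invisible(x)
}

#' @export
summary.sccot <- function(object, ...) {
  d <- object$decomposition
  out <- list(
    n_control = length(object$control_index),
    n_treated = length(object$treated_index),
    n_genes = ncol(object$expr),
    coefficients = d$coefficients,
    confounder_idx = d$confounder_idx,
    treatment_idx = d$treatment_idx,
    threshold = d$threshold,
    plan_converged = object$plan$converged,
    plan_iterations = object$plan$iterations,
    mean_abs_ite = mean(abs(object$ite)),
    top_effect_genes = head(colnames(object$ite)[
      order(-abs(colMeans(object$ite)))], 10L),
    config = object$config)
  class(out) <- "summary.sccot"
  out
}

#' @export
print.summary.sccot <- function(x, ...) {
  cat("sccot fit summary\n")
  cat(sprintf("  %d control / %d treated cells, %d genes\n",
              x$n_control, x$n_treated, x$n_genes))
  cat("  component dependence coefficients (xicor vs treatment):\n")
  print(round(x$coefficients, 3))
  cat(sprintf("  confounder components: %s\n",
              paste(x$confounder_idx, collapse = " ")))
  cat(sprintf("  treatment-associated:  %s\n",
              if (length(x$treatment_idx))
                paste(x$treatment_idx, collapse = " ") else "(none)"))
  cat(sprintf("  mean |ITE| = %.4f\n", x$mean_abs_ite))
  cat("  top effect genes:", paste(x$top_effect_genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.sccot <- function(object, ...) object$decomposition$coefficients

#' Counterfactual expression imputed by the matching plan
#'
#' @param object A fitted `sccot` object.
#' @param direction Which population to impute counterfactuals for; defaults
#'   to the fit's direction.
#' @param ... Unused.
#' @return Matrix of counterfactual expression (reference cells x genes).
#' @export
predict.sccot <- function(object,
                          direction = object$config$direction, ...) {
  i0 <- match(object$control_index, object$cell_index)
  i1 <- match(object$treated_index, object$cell_index)
  mat <- if (object$config$ite_space == "expression")
    object$expr[object$cell_index, , drop = FALSE]
  else object$embedding[object$cell_index, , drop = FALSE]
  eff <- compute_ite(mat[i0, , drop = FALSE], mat[i1, , drop = FALSE],
                     object$plan, direction = direction,
                     space = object$config$ite_space)
  if (direction == "counterfactual_for_control")
    mat[i0, , drop = FALSE] + unclass(eff)
  else
    mat[i1, , drop = FALSE] - unclass(eff)
}

#' @export
fitted.sccot <- function(object, ...) predict(object)

#' @export
residuals.sccot <- function(object, ...) {
  # observed - counterfactual = -ITE for the control direction,
  # +ITE for the treated direction
  if (attr(object$ite, "direction") == "counterfactual_for_control")
    -unclass(object$ite)
  else unclass(object$ite)
}

#' Plot a fitted matching model
#'
#' Scatter of the first two confounder source components, coloured by
#' treatment group. Under correct matching the two conditions should be well
#' mixed in this space.
#'
#' @param x A fitted `sccot` object.
#' @param dims Which two confounder components to show.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sccot <- function(x, dims = c(1L, 2L), ...) {
  S <- x$confounder
  if (ncol(S) < 2L) stop("need at least two confounder components to plot")
  cols <- c("#1f77b4", "#d62728")[x$treatment[x$cell_index] + 1L]
  graphics::plot(S[, dims[1L]], S[, dims[2L]], col = cols, pch = 16L,
                 cex = 0.5, xlab = paste("confounder component", dims[1L]),
                 ylab = paste("confounder component", dims[2L]), ...)
  graphics::legend("topright", legend = c("control", "treated"),
                   col = c("#1f77b4", "#d62728"), pch = 16L, bty = "n")
}
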