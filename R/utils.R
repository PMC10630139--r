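#' @importFrom stats rnorm runif var sd prcomp quantile rpois rnbinom rgamma
#'   complete.cases aggregate median pnorm coef fitted residuals predict
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Row-wise log-sum-exp of a matrix, guarded against -Inf rows.
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

col_logsumexp <- function(m) row_logsumexp(t(m))

# Squared Euclidean distances between rows of x (n0 x d) and rows of y (n1 x d).
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k nearest rows of `ref` for each row of `query` (Euclidean).
# Blocked so that n_query x n_ref never has to fit tight loops; ties broken by
# index order for determinism.
knn_indices <- function(query, ref, k, block = 1024L) {
  stopifnot(k >= 1L, k <= nrow(ref))
  n <- nrow(query)
  out <- matrix(NA_integer_, n, k)
  rr <- rowSums(ref^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), rr, "+") -
      2 * tcrossprod(query[idx, , drop = FALSE], ref)
    out[idx, ] <- t(apply(d2, 1L, function(v) order(v)[seq_len(k)]))
  }
  out
}

# Undirected kNN graph + Leiden clustering (modularity objective).
# Self is excluded from the neighbour list when query == ref.
leiden_cluster <- function(embedding, resolution = 1, k = 15L, seed = 1L,
                           n_iterations = 5L) {
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  nn <- knn_indices(embedding, embedding, k + 1L)
  edges <- integer(0)
  for (j in 2:(k + 1L)) edges <- c(edges, rbind(seq_len(n), nn[, j]))
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  cl <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = n_iterations))
  as.integer(igraph::membership(cl))
}

# PCA by eigendecomposition of the smaller Gram/covariance side.
# Returns scores (n x npc), rotation, explained variance ratio, and center.
pca_embed <- function(x, npc, center = TRUE, scale. = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  npc <- min(npc, n - 1L, p)
  ctr <- if (center) colMeans(x) else rep(0, p)
  scl <- if (scale.) {
    s <- apply(x, 2L, sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  xc <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  if (p <= n) {
    cv <- crossprod(xc) / (n - 1L)
    eg <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    rot <- eg$vectors[, seq_len(npc), drop = FALSE]
    scores <- xc %*% rot
  } else {
    gm <- tcrossprod(xc) / (n - 1L)
    eg <- eigen(gm, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    u <- eg$vectors[, seq_len(npc), drop = FALSE]
    d <- sqrt(ev[seq_len(npc)] * (n - 1L))
    d[d == 0] <- 1
    scores <- u %*% diag(d, npc)
    rot <- crossprod(xc, u) %*% diag(1 / d, npc)
  }
  list(scores = scores, rotation = rot,
       explained_variance = ev[seq_len(npc)],
       evr = ev[seq_len(npc)] / max(sum(ev), .Machine$double.eps),
       center = ctr, scale = scl)
}

# Library-size normalization to the median depth followed by log1p.
lognormalize <- function(counts) {
  libs <- rowSums(counts)
  libs[libs == 0] <- 1
  target <- stats::median(libs)
  log1p(counts / libs * target)
}
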