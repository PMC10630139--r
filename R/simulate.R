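#' Configuration for the synthetic benchmark generator
#'
#' Describes a two-block gamma-Poisson single-cell count simulation: a
#' confounder block in which cells fall into discrete cell states modulated
#' by shared continuous gene-regulation programs, and a response block that
#' stays at baseline in control cells while each treated cell expresses a
#' response-cluster signature drawn from a state-conditional discrete
#' distribution. The defaults produce 5,000 cells with 1,000 confounder and
#' 500 response genes, 2--5 cell states (default 3) with 2 programs.
#'
#' @param n_cells Number of cells (default 5000).
#' @param n_confounder_genes Confounder-block genes (default 1000).
#' @param n_response_genes Response-block genes (default 500).
#' @param n_states Number of cell states, in \code{[2, 5]} (default 3).
#' @param n_programs Shared gene-regulation programs (default 2).
#' @param n_response_clusters Response modes treated cells can adopt
#'   (default 2).
#' @param response_distributions Optional n_states x n_response_clusters
#'   matrix of per-state response-cluster probabilities (rows sum to 1).
#'   `NULL` (default) draws a random discrete distribution per state;
#'   identical rows make the response state-independent by construction.
#' @param state_de_prob Fraction of confounder genes differentially expressed
#'   per state (default 0.1).
#' @param response_de_prob Fraction of response genes in each cluster
#'   signature (default 0.2).
#' @param response_lfc_sd SD of the Normal(0, sd) log-fold-change signatures
#'   (default 1).
#' @param treat_fraction Fraction of cells assigned to treatment before any
#'   differential-abundance subsampling (default 0.5).
#' @param dispersion Negative-binomial size parameter (default 10; larger =
#'   closer to Poisson).
#' @param da_ratio Differential-abundance retention ratio in \code{[0, 1]}
#'   applied by [apply_differential_abundance()] (default 1 = none).
#' @param downsample_fraction Count-depth retention fraction in \code{(0, 1]}
#'   for [downsample_counts()] (default 1).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 5000L, n_confounder_genes = 1000L,
                              n_response_genes = 500L, n_states = 3L,
                              n_programs = 2L, n_response_clusters = 2L,
                              response_distributions = NULL,
                              state_de_prob = 0.1, response_de_prob = 0.2,
                              response_lfc_sd = 1, treat_fraction = 0.5,
                              dispersion = 10, da_ratio = 1,
                              downsample_fraction = 1, seed = 1L) {
  if (n_states < 2L || n_states > 5L) stop("n_states must be in [2, 5]")
  if (da_ratio < 0 || da_ratio > 1) stop("da_ratio must be in [0, 1]")
  if (downsample_fraction <= 0 || downsample_fraction > 1)
    stop("downsample_fraction must be in (0, 1]")
  if (!is.null(response_distributions)) {
    response_distributions <- as.matrix(response_distributions)
    if (nrow(response_distributions) != n_states)
      stop("response_distributions needs one row per state")
    if (any(response_distributions < 0) ||
        any(abs(rowSums(response_distributions) - 1) > 1e-8))
      stop("response_distributions rows must be probability vectors")
    n_response_clusters <- ncol(response_distributions)
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a benchmark dataset with ground truth
#'
#' Generates counts per [simulation_config()]: confounder genes follow
#' gamma-distributed baseline means with state-specific log-fold-changes and
#' two shared continuous program effects; response genes sit at baseline for
#' control cells and add the drawn response cluster's signature for treated
#' cells. Counts are negative binomial (gamma-Poisson) around per-cell
#' library factors. The returned ground truth labels every evaluation in
#' [run_benchmark()].
#'
#' @param config A `simulation_config`.
#' @return A list of class `simulated_dataset` with `dataset`
#'   (an [expression_dataset()] with `cell_labels` = true state),
#'   `true_state`, `true_response_cluster` (NA for control cells),
#'   `block_index` (factor `confounder`/`response` per gene),
#'   `response_distributions`, `response_signatures` (cluster x response-gene
#'   log-fold-change matrix), and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_cells; gC <- cfg$n_confounder_genes; gR <- cfg$n_response_genes
    S <- cfg$n_states; K <- cfg$n_response_clusters

    state <- sample.int(S, n, replace = TRUE)
    z <- as.integer(runif(n) < cfg$treat_fraction)
    if (!any(z == 0)) z[1L] <- 0L
    if (!any(z == 1)) z[1L] <- 1L
    lib <- exp(rnorm(n, 0, 0.2))                      # per-cell depth factor

    # confounder block: baseline + state LFCs + shared programs
    muC <- rgamma(gC, shape = 2, scale = 1) + 0.05
    state_lfc <- matrix(0, S, gC)
    for (s in seq_len(S)) {
      de <- runif(gC) < cfg$state_de_prob
      state_lfc[s, de] <- rnorm(sum(de), 0, 1)
    }
    prog_load <- matrix(0, cfg$n_programs, gC)
    for (pr in seq_len(cfg$n_programs)) {
      on <- runif(gC) < 0.1
      prog_load[pr, on] <- rnorm(sum(on), 0, 1)
    }
    prog_act <- matrix(rnorm(n * cfg$n_programs, 0, 0.3), n)
    logmuC <- matrix(log(muC), n, gC, byrow = TRUE) +
      state_lfc[state, , drop = FALSE] + prog_act %*% prog_load
    rateC <- lib * exp(logmuC)

    # per-state response distributions and per-treated-cell cluster draws
    rd <- cfg$response_distributions
    if (is.null(rd)) {
      rd <- matrix(rgamma(S * K, shape = 1), S, K)
      rd <- rd / rowSums(rd)
    }
    resp <- rep(NA_integer_, n)
    for (s in seq_len(S)) {
      idx <- which(state == s & z == 1)
      if (length(idx))
        resp[idx] <- sample.int(K, length(idx), replace = TRUE,
                                prob = rd[s, ])
    }

    # response block: baseline everywhere; treated cells add their cluster's
    # signature (Normal(0, sd) LFCs on a random subset of genes)
    muR <- rgamma(gR, shape = 2, scale = 1) + 0.05
    clust_lfc <- matrix(0, K, gR)
    for (kk in seq_len(K)) {
      de <- runif(gR) < cfg$response_de_prob
      clust_lfc[kk, de] <- rnorm(sum(de), 0, cfg$response_lfc_sd)
    }
    logmuR <- matrix(log(muR), n, gR, byrow = TRUE)
    treated <- which(z == 1)
    logmuR[treated, ] <- logmuR[treated, , drop = FALSE] +
      clust_lfc[resp[treated], , drop = FALSE]
    rateR <- lib * exp(logmuR)

    counts <- cbind(
      matrix(rnbinom(n * gC, size = cfg$dispersion, mu = rateC), n, gC),
      matrix(rnbinom(n * gR, size = cfg$dispersion, mu = rateR), n, gR))
    colnames(counts) <- c(paste0("conf_g", seq_len(gC)),
                          paste0("resp_g", seq_len(gR)))
    rownames(counts) <- paste0("cell", seq_len(n))

    ds <- expression_dataset(counts, z, counts = TRUE,
                             cell_labels = factor(state))
    colnames(clust_lfc) <- paste0("resp_g", seq_len(gR))
    structure(list(dataset = ds,
                   true_state = factor(state),
                   true_response_cluster = resp,
                   block_index = factor(rep(c("confounder", "response"),
                                            c(gC, gR))),
                   response_distributions = rd,
                   response_signatures = clust_lfc,
                   config = cfg),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d cells x %d genes (%d confounder + %d response)\n",
              nrow(x$dataset$values), ncol(x$dataset$values),
              sum(x$block_index == "confounder"),
              sum(x$block_index == "response")))
  cat(sprintf("  states: %d; response clusters: %d; treated cells: %d\n",
              nlevels(x$true_state), ncol(x$response_distributions),
              sum(x$dataset$treatment == 1)))
  invisible(x)
}

#' Impose differential abundance on a simulated dataset
#'
#' For `ceiling(n_states/2)` randomly chosen states, treated cells are
#' subsampled without replacement to exactly `round(da_ratio * n)` retained
#' cells. `da_ratio = 1` leaves the dataset untouched; `da_ratio = 0` removes
#' the chosen states from the treated condition entirely (missing cell
#' types).
#'
#' @param sim A `simulated_dataset`.
#' @param da_ratio Retention ratio in \code{[0, 1]}.
#' @param seed Seed for state choice and subsampling.
#' @return The subsetted `simulated_dataset`, with `da_states` recording the
#'   affected states.
#' @export
apply_differential_abundance <- function(sim, da_ratio, seed = 1L) {
  stopifnot(inherits(sim, "simulated_dataset"))
  if (da_ratio < 0 || da_ratio > 1) stop("da_ratio must be in [0, 1]")
  S <- nlevels(sim$true_state)
  if (S < 2L) stop("need at least 2 states")
  if (da_ratio == 1) return(sim)
  with_seed(seed, {
    hit <- sample(levels(sim$true_state), ceiling(S / 2))
    z <- sim$dataset$treatment
    drop <- integer(0)
    for (s in hit) {
      idx <- which(sim$true_state == s & z == 1)
      keep_n <- round(da_ratio * length(idx))
      if (keep_n < length(idx))
        drop <- c(drop, sample(idx, length(idx) - keep_n))
    }
    keep <- setdiff(seq_along(z), drop)
    out <- sim
    out$dataset <- subset_cells(sim$dataset, keep)
    out$true_state <- droplevels(sim$true_state[keep])
    out$true_response_cluster <- sim$true_response_cluster[keep]
    out$da_states <- hit
    out
  })
}

#' Downsample total counts by hypergeometric thinning
#'
#' Keeps exactly `round(fraction * sum(counts))` of the count units, drawn
#' uniformly without replacement across the whole matrix (multivariate
#' hypergeometric), which preserves the relative gene/cell structure in
#' expectation and emulates reduced sequencing depth.
#'
#' @param counts Nonnegative integer matrix.
#' @param fraction Fraction of total counts to keep, in \code{(0, 1]}.
#' @param seed Seed.
#' @return Thinned integer matrix of the same shape.
#' @export
downsample_counts <- function(counts, fraction, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (fraction > 1 || fraction <= 0) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(counts)
  total <- sum(counts)
  keep <- round(fraction * total)
  with_seed(seed, {
    # sample `keep` of the `total` units; map unit ids to matrix entries
    units <- sort(sample.int(total, keep))
    cs <- cumsum(as.vector(counts))
    bins <- findInterval(units - 1L, cs) + 1L
    out <- tabulate(bins, nbins = length(cs))
    matrix(out, nrow(counts), ncol(counts),
           dimnames = dimnames(counts))
  })
}
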