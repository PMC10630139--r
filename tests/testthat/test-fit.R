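test_that("compute_ite arithmetic and invariances", {
  # 1 control cell [1], treated [3],[5], uniform row -> counterfactual 4
  p <- matrix(c(.5, .5), 1, 2)
  expect_equal(as.vector(compute_ite(matrix(1), matrix(c(3, 5)), p)),
               3)
  # treated == control with identity plan -> zero ITE
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(max(abs(compute_ite(x, x, diag(5) / 5))), 0)
  # scaling a plan row leaves the ITE unchanged
  set.seed(31)
  M <- matrix(runif(15), 3, 5)
  x0 <- matrix(rnorm(6), 3, 2); x1 <- matrix(rnorm(10), 5, 2)
  M2 <- M; M2[2, ] <- M2[2, ] * 7
  expect_equal(unclass(compute_ite(x0, x1, M)),
               unclass(compute_ite(x0, x1, M2)))
  # zero plan row errors
  M3 <- M; M3[1, ] <- 0
  expect_error(compute_ite(x0, x1, M3), "zero row")
  # treated direction: rows = treated cells
  it <- compute_ite(x0, x1, M, direction = "counterfactual_for_treated")
  expect_equal(nrow(it), 5)
})

test_that("label weights equalize per-label mass across conditions", {
  lab <- factor(c(rep("A", 10), rep("B", 10), rep("A", 30), rep("B", 10)))
  z <- rep(c(0L, 1L), c(20, 40))
  w <- weights_from_labels(lab, z)
  expect_equal(sum(w$w0), 1)
  expect_equal(sum(w$w1), 1)
  # each treated A cell gets pooled_freq(A)/n1A = (2/3)/30 = 1/45
  expect_equal(w$w1[1], (2 / 3) / 30, tolerance = 1e-12)
  # per-label mass equal across conditions
  expect_equal(sum(w$w0[lab[z == 0] == "A"]), sum(w$w1[lab[z == 1] == "A"]))
  # balanced labels give uniform weights
  wb <- weights_from_labels(factor(rep(c("A", "B"), each = 10)),
                            rep(c(0L, 1L), 10))
  expect_true(all(abs(wb$w0 - wb$w0[1]) < 1e-12))
  expect_error(weights_from_labels(factor(c("A", "A", "B", "A")),
                                   c(0, 0, 0, 1)), "B")
})

test_that("knn alignment averages the nearest control cells", {
  X0 <- matrix(c(0, 2), 2, 1)
  expect_equal(as.vector(knn_align(X0, matrix(0.9), k = 2)), 1.0)
  expect_equal(as.vector(knn_align(X0, matrix(0.1), k = 1)), 0)
  # k = n0 maps every treated cell to the control centroid
  set.seed(32)
  X0b <- matrix(rnorm(20), 10, 2)
  al <- knn_align(X0b, matrix(rnorm(6), 3, 2), k = 10)
  expect_equal(al, matrix(colMeans(X0b), 3, 2, byrow = TRUE))
  expect_error(knn_align(X0b, matrix(0, 1, 2), k = 0), "k must be")
})

test_that("balanced subsampling equalizes conditions per cluster", {
  set.seed(33)
  # two well-separated clusters, imbalanced treatment in cluster 2,
  # cluster 3 control-only
  emb <- rbind(matrix(rnorm(40 * 2), 40, 2),
               matrix(rnorm(60 * 2, mean = 8), 60, 2),
               matrix(rnorm(30 * 2, mean = -8), 30, 2))
  z <- c(rep(c(0L, 1L), each = 20), rep(0L, 40), rep(1L, 20), rep(0L, 30))
  st <- balanced_subsample(emb, z, resolution = 1, seed = 5, knn_k = 10)
  lab <- st$leiden_labels
  for (a in unique(lab[st$kept_indices])) {
    kept_a <- intersect(which(lab == a), st$kept_indices)
    expect_equal(sum(z[kept_a] == 0), sum(z[kept_a] == 1))
  }
  # control-only cluster dropped entirely
  iso <- which(seq_along(z) > 100)
  expect_length(intersect(iso, st$kept_indices), 0)
  # deterministic given seed
  st2 <- balanced_subsample(emb, z, resolution = 1, seed = 5, knn_k = 10)
  expect_identical(st$kept_indices, st2$kept_indices)
})

test_that("constant-shift construction is recovered within 10%", {
  ds <- make_shift_dataset(shift = 0.8, seed = 2)
  fit <- suppressWarnings(sccot(ds, rank = 8, seed = 1))
  truth <- c(rep(0, 60), rep(0.8, 20))
  rel <- apply(fit$ite, 1, function(r) sqrt(sum((r - truth)^2)) /
                 sqrt(sum(truth^2)))
  expect_lt(max(rel), 0.10)
  # treatment-shift direction flagged treatment-associated, not confounder
  expect_gt(length(fit$decomposition$treatment_idx), 0)
})

test_that("fit methods are coherent", {
  ds <- make_shift_dataset(seed = 3)
  fit <- sccot(ds, rank = 6, seed = 1)
  expect_s3_class(fit, "sccot")
  expect_output(print(fit), "Counterfactual")
  s <- summary(fit)
  expect_s3_class(s, "summary.sccot")
  expect_length(coef(fit), 6)
  expect_equal(dim(fitted(fit)), dim(fit$ite))
  expect_equal(residuals(fit), -unclass(fit$ite))
  # counterfactual = observed + ITE for the control direction
  i0 <- fit$control_index
  expect_equal(predict(fit), fit$expr[i0, ] + unclass(fit$ite))
  # same seed reproduces the fit
  fit2 <- sccot(ds, rank = 6, seed = 1)
  expect_identical(fit$ite, fit2$ite)
})

test_that("null data yields ITEs at matched-noise level under label permutation", {
  # no treatment effect: a single response cluster with zero signatures
  sim <- small_sim(seed = 4, n_cells = 300, n_response_clusters = 1,
                   response_lfc_sd = 0)
  fit <- sccot(sim$dataset, rank = 8, seed = 1)
  set.seed(9)
  zperm <- sample(sim$dataset$treatment)
  dsp <- expression_dataset(sim$dataset$values, zperm, counts = TRUE)
  fitp <- sccot(dsp, rank = 8, seed = 1)
  # mean |ITE| comparable between true and permuted labels (both pure noise)
  ratio <- mean(abs(fit$ite)) / mean(abs(fitp$ite))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("balanced variant matches the standard fit when abundance is even", {
  sim <- small_sim(seed = 6, n_cells = 500)
  f1 <- sccot(sim$dataset, rank = 8, seed = 1,
              direction = "counterfactual_for_treated")
  f2 <- sccot(sim$dataset, rank = 8, seed = 1, balance = "auto",
              resolution = 0.6, direction = "counterfactual_for_treated")
  expect_gte(cor(as.vector(f1$ite), as.vector(f2$ite)), 0.9)
  # determinism of the balancing subsample
  f3 <- sccot(sim$dataset, rank = 8, seed = 1, balance = "auto",
              resolution = 0.6, direction = "counterfactual_for_treated")
  expect_identical(f2$balance$kept_indices, f3$balance$kept_indices)
})

test_that("missing cell states are excluded from the balanced ICA fit", {
  sim <- small_sim(seed = 7, n_cells = 600, n_states = 2)
  da <- apply_differential_abundance(sim, 0, seed = 3)
  f <- sccot(da$dataset, rank = 8, seed = 1, balance = "auto",
             resolution = 0.6)
  # the state with no treated cells should be largely absent from fitting
  gone <- da$da_states
  fit_states <- da$true_state[f$balance$kept_indices]
  frac_gone <- mean(fit_states %in% gone)
  expect_lt(frac_gone, 0.2)
})

test_that("label-weighted fit balances marginal mass by cell type", {
  sim <- small_sim(seed = 8, n_cells = 400)
  f <- sccot(sim$dataset, rank = 8, seed = 1, balance = "labels")
  expect_equal(sum(f$plan$row_marginal), 1, tolerance = 1e-9)
  lab <- sim$true_state
  z <- sim$dataset$treatment
  for (lv in levels(lab)) {
    m0 <- sum(f$plan$row_marginal[lab[z == 0] == lv])
    m1 <- sum(f$plan$col_marginal[lab[z == 1] == lv])
    expect_equal(m0, m1, tolerance = 1e-9)
  }
})
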