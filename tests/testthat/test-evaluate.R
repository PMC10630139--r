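test_that("ASW batch score separates mixed from split embeddings", {
  set.seed(61)
  cloud <- matrix(rnorm(400), 200, 2)
  # interleaved identical clouds -> well mixed
  expect_gt(asw_batch(rbind(cloud, cloud + rnorm(400, 0, 0.01)),
                      rep(c("a", "b"), each = 200)), 0.9)
  # well-separated clouds -> poor mixing
  expect_lt(asw_batch(rbind(cloud, cloud + 12),
                      rep(c("a", "b"), each = 200)), 0.2)
  # random label permutation looks mixed on any embedding
  emb <- rbind(cloud, cloud + 12)
  expect_gt(asw_batch(emb, sample(rep(c("a", "b"), 200))), 0.85)
  expect_error(asw_batch(cloud, rep("a", 200)), "2 batches")
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(62)
  for (i in 1:3) {
    x <- matrix(rnorm(60 * 3), 60, 3)
    lab <- sample(1:3, 60, replace = TRUE)
    ours <- sccot:::silhouette_widths(x, lab)
    ref <- cluster::silhouette(lab, dist(x))[, "sil_width"]
    expect_equal(ours, unname(ref), tolerance = 1e-6)
  }
})

test_that("PCR score reflects covariate dependence", {
  set.seed(63)
  z <- rep(c(0, 1), each = 500)
  # embedding equal to the covariate indicator: fully explained
  expect_lt(pcr_score(cbind(z, z), factor(z)), 1e-8)
  # independent isotropic gaussian: near 1
  expect_gt(pcr_score(matrix(rnorm(2000 * 5), 2000, 5),
                      factor(rep(c(0, 1), each = 1000))), 0.95)
  expect_error(pcr_score(matrix(1, 10, 2), factor(rep(c(0, 1), 5))),
               "constant")
  expect_error(pcr_score(matrix(rnorm(20), 10, 2), rep(1, 10)), "vary")
})

test_that("appending independent dimensions never decreases the PCR score", {
  set.seed(64)
  z <- factor(rep(c(0, 1), each = 300))
  base <- cbind(as.numeric(z) + rnorm(600, 0, 0.2), rnorm(600))
  s1 <- pcr_score(base, z)
  s2 <- pcr_score(cbind(base, matrix(rnorm(600 * 3, 0, 0.5), 600, 3)), z)
  expect_gte(s2, s1 - 1e-8)
})

test_that("R^2 inside pcr matches lm on a small fixture", {
  set.seed(65)
  emb <- matrix(rnorm(50 * 2), 50, 2)
  cov <- factor(rep(letters[1:2], 25))
  ours <- pcr_score(emb, cov)
  p <- prcomp(emb)
  evr <- p$sdev^2
  r2 <- vapply(1:2, function(k) summary(lm(p$x[, k] ~ cov))$r.squared,
               numeric(1))
  expect_equal(ours, 1 - sum(evr * r2) / sum(evr), tolerance = 1e-10)
})

test_that("ARI matches hand pair-counting and mclust", {
  # 6-point worked example: contingency 2x2 = [[2,1],[0,3]]
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  ct <- c(sum_ij = choose(2, 2) + choose(1, 2) + choose(0, 2) + choose(3, 2))
  sum_a <- 2 * choose(3, 2); sum_b <- choose(2, 2) + choose(4, 2)
  expected <- (4 - sum_a * sum_b / choose(6, 2)) /
    ((sum_a + sum_b) / 2 - sum_a * sum_b / choose(6, 2))
  expect_equal(sccot:::adjusted_rand_index(a, b), expected,
               tolerance = 1e-12)
  expect_equal(sccot:::adjusted_rand_index(a, a), 1)
  skip_if_not_installed("mclust")
  set.seed(66)
  for (i in 1:3) {
    x <- sample(1:4, 100, replace = TRUE)
    y <- sample(1:3, 100, replace = TRUE)
    expect_equal(sccot:::adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-6)
  }
})

test_that("random labels give near-zero ARI at scale", {
  set.seed(67)
  x <- sample(1:3, 5000, replace = TRUE)
  y <- sample(1:3, 5000, replace = TRUE)
  expect_lt(abs(sccot:::adjusted_rand_index(x, y)), 0.05)
})

test_that("ari_ite recovers planted response structure and rejects degenerate truth", {
  set.seed(68)
  ite <- rbind(matrix(rnorm(100 * 10, 0), 100, 10),
               matrix(rnorm(100 * 10, 4), 100, 10))
  truth <- rep(c("a", "b"), each = 100)
  expect_gt(ari_ite(ite, truth, seed = 1), 0.95)
  expect_error(ari_ite(ite, rep("a", 200)), "single truth class")
})

test_that("stratified ITE attribution score detects confounder leakage", {
  set.seed(69)
  n <- 300
  state <- rep(c(1, 2), each = n / 2)
  resp <- rep(rep(c("r1", "r2"), each = n / 4), 2)
  clean <- matrix(rnorm(n * 8), n, 8) +
    outer(as.integer(resp == "r2"), rep(3, 8))
  leaky <- clean + outer(state, rep(2, 8))
  expect_gt(pcr_ite(clean, state, resp), 0.9)
  expect_lt(pcr_ite(leaky, state, resp), 0.5)
})

test_that("benchmark report has a row per config x method x metric", {
  cfg <- simulation_config(n_cells = 250, n_confounder_genes = 100,
                           n_response_genes = 60, seed = 71)
  rep <- suppressWarnings(run_benchmark(list(cfg),
                                        methods = c("standard", "full_ot"),
                                        rank = 8))
  expect_equal(nrow(rep), 2 * 4)
  expect_setequal(unique(rep$metric),
                  c("asw_batch", "pcr_score", "ari_ite", "pcr_ite"))
  expect_true(all(is.finite(rep$value) | nzchar(rep$note)))
})
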