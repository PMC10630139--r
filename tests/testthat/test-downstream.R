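as_ite <- function(m) structure(m, direction = "counterfactual_for_control",
                                space = "expression",
                                class = c("ite_matrix", "matrix"))

test_that("synergy matrix is the deviation from additivity", {
  set.seed(41)
  a <- as_ite(matrix(rnorm(20), 5, 4))
  b <- as_ite(matrix(rnorm(20), 5, 4))
  e <- matrix(rnorm(20), 5, 4)
  # exact additivity -> zero synergy
  s0 <- synergy_matrix(a, b, as_ite(unclass(a) + unclass(b)))
  expect_equal(max(abs(s0$psi)), 0)
  # linearity: psi(a, b, a+b+E) = E for any E
  sE <- synergy_matrix(a, b, as_ite(unclass(a) + unclass(b) + e))
  expect_equal(sE$psi, e)
  # single entry: 5 - (1 + 2) = 2
  s1 <- synergy_matrix(as_ite(matrix(1)), as_ite(matrix(2)),
                       as_ite(matrix(5)))
  expect_equal(s1$psi[1, 1], 2)
  expect_equal(s1$mode, "multiplicative")  # log1p inputs
  expect_error(synergy_matrix(a, b, as_ite(matrix(0, 3, 4))), "dimensions")
})

test_that("gene synergy score averages with intended sign cancellation", {
  psi <- cbind(c(1, -1), c(0.2, 0.2))
  gs <- gene_synergy_score(psi)
  expect_equal(unname(gs), c(0, 0.2))
  expect_equal(unname(gene_synergy_score(matrix(0, 4, 3))), rep(0, 3))
})

test_that("cell synergy score is the norm over passing genes", {
  # gene scores: c(3.5, 0.05, 4): genes 1 and 3 pass at 0.15
  psi <- rbind(c(3, 0.1, 4), c(4, 0, 4))
  s <- cell_synergy_score(psi, gene_threshold = 0.15)
  expect_equal(s, c(5, sqrt(32)))
  expect_error(cell_synergy_score(matrix(1e-3, 2, 2), 0.15), "max score")
})

test_that("coarse-grained matching aggregates and normalizes mass", {
  # block-diagonal plan with matching labels -> identity
  M <- matrix(0, 4, 4)
  M[1:2, 1:2] <- 0.125; M[3:4, 3:4] <- 0.125
  cm <- coarse_grain_matching(M, rep(c("r1", "r2"), each = 2),
                              rep(c("c1", "c2"), each = 2))
  expect_equal(unname(cm$matrix), diag(2))
  expect_equal(sum(cm$mass), 1)
  expect_equal(unname(rowSums(cm$matrix)), c(1, 1))
  # uniform plan: rows proportional to control-cluster sizes
  M2 <- matrix(1 / 24, 6, 4)
  cm2 <- coarse_grain_matching(M2, rep("r1", 4), rep(c("a", "b"), c(2, 4)))
  expect_equal(unname(cm2$matrix[1, ]), c(2, 4) / 6)
})

test_that("attribution regression recovers exact coefficients", {
  set.seed(42)
  n <- 200
  z <- rep(c(0, 1), each = n / 2)
  c1 <- rnorm(n)
  y <- 2 * z + 1 * c1 + 3 * c1 * z + 0.5
  f <- attribution_regression(y, z, c1)
  expect_equal(f$alpha, 2, tolerance = 1e-8)
  expect_equal(f$beta, 1, tolerance = 1e-8)
  expect_equal(f$gamma, 3, tolerance = 1e-8)
  expect_equal(f$intercept, 0.5, tolerance = 1e-8)
  expect_true(f$ratio_infinite)
  expect_equal(f$ratio, Inf)
})

test_that("no interaction keeps the ratio small; pure noise keeps coefficients near zero", {
  set.seed(43)
  n <- 2000
  z <- rep(c(0, 1), each = n / 2)
  c1 <- rnorm(n)
  hits <- replicate(40, {
    y <- 1.5 * z + 0.8 * c1 + rnorm(n)
    attribution_regression(y, z, c1)$ratio
  })
  expect_gte(mean(hits < 0.1), 0.95)
  # pure noise: coefficients within ~3 SEs of zero most of the time
  ok <- replicate(40, {
    y <- rnorm(500)
    f <- attribution_regression(y, rep(c(0, 1), 250), rnorm(500))
    se <- 1 / sqrt(125)  # rough OLS scale
    all(abs(c(f$alpha, f$beta, f$gamma)) < 4 * se)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("matrix input vectorizes attribution over genes", {
  set.seed(44)
  n <- 300
  z <- rep(c(0, 1), each = n / 2)
  c1 <- rnorm(n)
  Y <- cbind(g1 = 2 * z + c1 * z + rnorm(n, 0, 0.1), g2 = rnorm(n))
  tab <- attribution_regression(Y, z, c1)
  expect_equal(nrow(tab), 2)
  expect_gt(tab$ratio[1], tab$ratio[2])
  expect_error(attribution_regression(Y, z, z), "rank-deficient")
})

test_that("signed-rank test matches the exact null and wilcox.test", {
  # 5 concordant (tied) values: exact two-sided floor 2/2^5
  expect_equal(signed_rank_test(rep(1, 5))$p_value, 0.0625)
  # 100 concordant values pass any tiny threshold
  expect_lt(signed_rank_test(rep(1, 100))$p_value, 1e-15)
  # agreement with stats::wilcox.test exact p on tie-free data
  set.seed(45)
  for (i in 1:10) {
    x <- rnorm(sample(6:12, 1))
    expect_equal(signed_rank_test(x)$p_value,
                 wilcox.test(x, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large-n approximation close to wilcox.test's
  x <- rnorm(60, mean = 0.3)
  expect_equal(signed_rank_test(x)$p_value,
               wilcox.test(x, correct = TRUE)$p.value, tolerance = 0.05)
})

test_that("DE gene selection applies both thresholds", {
  set.seed(46)
  n <- 100
  ite <- cbind(up = rnorm(n, 1, 0.05),       # strong effect, tiny p
               weak = rnorm(n, 0.3, 0.05),   # significant but small effect
               null = rnorm(n, 0, 0.05),
               zero = rep(0, n))
  tab <- select_de_genes(ite, p_threshold = 1e-5, delta_threshold = 0.5)
  expect_true(tab$pass[tab$gene == "up"])
  expect_false(tab$pass[tab$gene == "weak"])   # fails delta threshold
  expect_false(tab$pass[tab$gene == "null"])
  expect_false(tab$pass[tab$gene == "zero"])   # undefined p -> fail
  expect_true(is.na(tab$p[tab$gene == "zero"]))
  expect_error(select_de_genes(ite[1:5, ]), "at least 6")
})
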