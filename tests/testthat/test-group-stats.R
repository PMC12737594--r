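test_that("eta-squared reproduces the published questionnaire effect sizes", {
  h <- c(1.35, 8.06, 5.03, 6.34, 1.13, 5.41, 3.41)
  printed <- c(-0.0186, 0.173, 0.0865, 0.124, -0.0249, 0.0974, 0.0403)
  # printed H carries 3 s.f. (+-0.005), i.e. +-0.005/35 ~ 1.4e-4 on eta^2
  expect_true(all(abs(eta_squared_h(h, 3, 38) - printed) < 2e-4))
})

test_that("Kruskal-Wallis wraps the tie-corrected H with effect size", {
  set.seed(4)
  x <- c(rnorm(10), rnorm(10, 3), rnorm(10, 6))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- kruskal_wallis(x, g)
  kt <- kruskal.test(x, factor(g))
  expect_equal(res$statistic, unname(kt$statistic))
  expect_equal(res$p, kt$p.value)
  expect_equal(res$df, 2)
  expect_equal(res$effect, eta_squared_h(res$statistic, 3, 30))
  # identical groups: tiny H, p near 1
  same <- rep(1:10, 3)
  res0 <- kruskal_wallis(same, g)
  expect_lt(res0$statistic, 0.5)
  expect_gt(res0$p, 0.9)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two groups")
})

test_that("Dunn pairwise z matches a direct pooled-rank oracle and Holm is step-down", {
  set.seed(10)
  x <- c(rnorm(8, 0), rnorm(12, 1.5), rnorm(10, 3))
  g <- rep(c("g1", "g2", "g3"), c(8, 12, 10))
  out <- dunn_holm(x, g)
  # oracle: direct formula on pooled ranks for one pair
  r <- rank(x)
  n <- length(x)
  s2 <- n * (n + 1) / 12
  z12 <- (mean(r[g == "g1"]) - mean(r[g == "g2"])) / sqrt(s2 * (1 / 8 + 1 / 12))
  expect_equal(out$z[out$comparison == "g1 vs g2"], z12)
  # Holm: direct step-down formula oracle
  ord <- order(out$p)
  m <- length(out$p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * out$p[ord]))[order(ord)]
  expect_equal(out$p_adjusted, adj)
  # monotone and never below raw
  expect_true(all(out$p_adjusted >= out$p))
  expect_true(!is.unsorted(out$p_adjusted[ord]))
  # degenerate cases
  expect_true(all(dunn_holm(rep(1:5, 3), rep(c("a", "b", "c"), 5))$p_adjusted == 1))
})

test_that("Holm reproduces the published adjusted p from the unrounded raw p", {
  raw <- c(0.00004, 0.01365, 0.481)
  adj <- stats::p.adjust(raw, "holm")  # the adjustment used inside dunn_holm
  expect_equal(adj, c(0.00012, 0.0273, 0.481))
  expect_equal(round(adj[2], 4), 0.0273)  # = 2 x the middle raw p
  expect_equal(p.adjust(0.03, "holm"), 0.03)  # m = 1: identity
})

test_that("Mann-Whitney U, z, and rank-biserial r are internally consistent", {
  # identical multisets: U = n1 n2 / 2
  res <- mann_whitney(1:10, 1:10)
  expect_equal(unname(res$statistic), 50)
  # strong stochastic dominance: small U, small p
  set.seed(6)
  lo <- rnorm(15, 0); hi <- rnorm(15, 5)
  expect_lt(mann_whitney(lo, hi)$statistic, 20)
  expect_lt(mann_whitney(lo, hi)$p, 1e-4)
  # published comparison scale: U = 25.5 at n1 = 14, n2 = 24 gives r ~ 0.70
  z <- (25.5 - 14 * 24 / 2) / sqrt(14 * 24 * 39 / 12)
  expect_equal(abs(z) / sqrt(38), 0.70, tolerance = 0.02 / 0.70)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("Kruskal-Wallis at k = 2 equals the squared Mann-Whitney z on tie-free data", {
  set.seed(12)
  x <- rnorm(14); y <- rnorm(24, 0.8)
  kw <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(14, 24)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  z <- (unname(wt$statistic) - 14 * 24 / 2) / sqrt(14 * 24 * 39 / 12)
  expect_equal(kw$statistic, z^2, tolerance = 1e-6)
  expect_equal(kw$p, wt$p.value, tolerance = 1e-6)
})

test_that("rank tests are invariant under strictly monotone transformations", {
  set.seed(13)
  x <- rnorm(12); y <- rnorm(15, 1); z <- rnorm(9, 2)
  vals <- c(x, y, z); g <- rep(c("a", "b", "c"), c(12, 15, 9))
  trans <- function(v) exp(v) + v^3  # strictly increasing
  expect_equal(kruskal_wallis(trans(vals), g)$statistic,
               kruskal_wallis(vals, g)$statistic)
  expect_equal(dunn_holm(trans(vals), g)$z, dunn_holm(vals, g)$z)
  expect_equal(mann_whitney(trans(x), trans(y))$statistic,
               mann_whitney(x, y)$statistic)
})

test_that("paired Wilcoxon follows the signed-rank conventions", {
  t0 <- c(1, 2, 3, 4, 5, 6)
  res <- wilcoxon_paired(t0, t0 + 0.5)  # uniform increase: maximal V
  expect_equal(unname(res$statistic), 6 * 7 / 2)
  # antisymmetric differences: p close to 1
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  res2 <- wilcoxon_paired(rep(0, 8), d)
  expect_gt(res2$p, 0.9)
  expect_error(wilcoxon_paired(1:5, 1:5), "zero")
  expect_error(wilcoxon_paired(1:6, c(2, 2:6)), "fewer than 5")
})

test_that("the Shapiro-Wilk gate flags skewed samples and honours its domain", {
  set.seed(14)
  skewed <- rlnorm(35, 0, 1)
  expect_false(shapiro_gate(skewed)$normal)
  gauss <- rnorm(1000)
  g <- shapiro_gate(gauss)
  expect_true(g$p >= 0 && g$p <= 1)
  expect_error(shapiro_gate(c(1, 2)), "3 <= n")
  expect_error(shapiro_gate(rep(2, 10)), "constant")
})

test_that("cortisol deltas drop incomplete pairs and keep grouping", {
  pairs <- data.frame(dyad_id = sprintf("d%d", 1:5),
                      t0 = c(1.0, 2.0, NA, 1.2, 0.8),
                      t1 = c(1.5, 2.0, 1.1, NA, 1.3),
                      class = c("S", "P", "U", "U", "S"))
  expect_message(out <- delta_cortisol(pairs), "2 dyad")
  expect_equal(nrow(out), 3)
  expect_equal(out$delta, c(0.5, 0, 0.5))
  expect_error(delta_cortisol(data.frame(dyad_id = "a", t0 = -1, t1 = 1)),
               "non-negative")
})

test_that("significance codes follow the table conventions", {
  expect_equal(signif_code(c(0.0005, 0.005, 0.03, 0.07, 0.5)),
               c("***", "**", "*", ".", "ns"))
})
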