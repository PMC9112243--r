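test_that("Mann-Whitney U: exact branch equals enumeration identities", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 0.1)          # 2/20 labelings at least as extreme
  # U_x + U_y = n_x * n_y for any input
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    ux <- matcare:::u_statistic(x, y)
    uy <- matcare:::u_statistic(y, x)
    expect_equal(ux + uy, length(x) * length(y))
  }
})

test_that("Mann-Whitney exact p equals wilcox.test's exact p", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(mine$statistic),
                 min(ref$statistic, length(x) * length(y) - ref$statistic),
                 ignore_attr = TRUE)
  }
})

test_that("Mann-Whitney approximate branch matches wilcox.test with ties
           and continuity correction", {
  set.seed(43)
  for (i in 1:10) {
    x <- round(rnorm(15, 0, 2), 1); y <- round(rnorm(18, 0.5, 2), 1)
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("t test matches the direct formulas and is antisymmetric", {
  x <- c(1.1, 2.3, 3.1, 4.7, 5.2); y <- c(2.0, 3.5, 4.1, 6.3)
  w <- t_test2(x, y, welch = TRUE)
  ref <- stats::t.test(x, y)
  expect_equal(unname(w$statistic), unname(ref$statistic))
  expect_equal(w$dof, unname(ref$parameter))
  expect_equal(w$p, ref$p.value)
  s <- t_test2(x, y, welch = FALSE)
  refs <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(unname(s$statistic), unname(refs$statistic))
  expect_equal(s$p, refs$p.value)
  expect_equal(unname(t_test2(y, x)$statistic), -unname(w$statistic))
  expect_equal(t_test2(c(1, 1, 2), c(1, 1, 2))$p, 1)
  expect_error(t_test2(c(1, 1), c(2, 2)), "variance")
})

test_that("Spearman rho is Pearson on mid-ranks; exact p matches the
           reference enumeration", {
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2.7, 1.8, 2.8, 1.9, 3.1, 4.1)
  r <- spearman_cor(x, y)
  expect_equal(unname(r$statistic), 0.6571429, tolerance = 1e-6)
  expect_equal(r$p, 0.175, tolerance = 1e-10)  # cor.test exact reference
  expect_equal(unname(r$statistic),
               stats::cor(rank(x), rank(y)))
  expect_equal(unname(spearman_cor(1:5, c(2, 4, 6, 8, 10))$statistic), 1)
  expect_equal(unname(spearman_cor(1:5, -(1:5))$statistic), -1)
  # mid-ranks under ties still equal Pearson on ranks
  xt <- c(1, 2, 2, 3, 4, 5); yt <- c(2, 2, 3, 3, 5, 7)
  expect_equal(unname(spearman_cor(xt, yt)$statistic),
               stats::cor(rank(xt), rank(yt)))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("two-way ANOVA matches the balanced closed-form decomposition", {
  set.seed(44)
  a <- gl(2, 12); b <- rep(gl(2, 6), 2)
  y <- rnorm(24, mean = 2 * (a == 2) + 3 * (b == 2) +
               1.5 * (a == 2 & b == 2))
  res <- two_way_anova(y, a, b)
  # independent route: balanced textbook formulas
  n <- 6; grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- n * 2 * sum((ma - grand)^2)
  ss_b <- n * 2 * sum((mb - grand)^2)
  ss_ab <- n * sum((sweep(sweep(mab, 1, ma), 2, mb) + grand)^2)
  ss_err <- sum((y - mab[cbind(a, b)])^2)
  expect_equal(res$A$ss, ss_a, tolerance = 1e-10)
  expect_equal(res$B$ss, ss_b, tolerance = 1e-10)
  expect_equal(res$AB$ss, ss_ab, tolerance = 1e-10)
  expect_equal(unname(res$A$statistic), (ss_a / 1) / (ss_err / 20),
               tolerance = 1e-10)
  # additive cell means, no noise: zero interaction SS
  y0 <- 1 * (a == 2) + 2 * (b == 2) + rep(0, 24)
  res0 <- two_way_anova(y0, a, b)
  expect_equal(res0$AB$ss, 0, tolerance = 1e-12)
})

test_that("two-way ANOVA Type-II sums match car::Anova on unbalanced
           data", {
  skip_if_not_installed("car")
  set.seed(45)
  a <- factor(c(rep("x", 9), rep("y", 14)))
  b <- factor(sample(c("u", "v"), 23, replace = TRUE,
                     prob = c(0.4, 0.6)))
  while (any(table(a, b) < 2))
    b <- factor(sample(c("u", "v"), 23, replace = TRUE))
  y <- rnorm(23, mean = (a == "y") * 1.2 + (b == "v") * 0.7)
  res <- two_way_anova(y, a, b)
  ref <- car::Anova(stats::lm(y ~ a * b), type = 2)
  expect_equal(res$A$ss, ref["a", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$B$ss, ref["b", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$AB$ss, ref["a:b", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$A$p, ref["a", "Pr(>F)"], tolerance = 1e-10)
})

test_that("mixed ANOVA reproduces the frozen split-plot table and the
           aov(Error()) decomposition", {
  y <- c(3, 4, 5, 6, 4, 5, 7, 8, 2, 3, 4, 5,
         6, 5, 4, 3, 8, 7, 6, 6, 5, 5, 4, 2)
  g <- rep(c("ctl", "trt"), each = 12)
  s <- rep(paste0("s", 1:6), each = 4)
  w <- rep(paste0("w", 1:4), 6)
  res <- mixed_anova(y, g, w, s)
  # frozen reference from the classical split-plot analysis of this table
  expect_equal(unname(res$between$statistic), 0.1397, tolerance = 1e-2)
  expect_equal(res$between$p, 0.728, tolerance = 1e-2)
  expect_equal(unname(res$within$statistic), 0.846, tolerance = 1e-2)
  expect_equal(unname(res$interaction$statistic), 57.462, tolerance = 1e-3)
  expect_equal(res$interaction$p, 2.17e-07, tolerance = 1e-2)
  # live aov cross-check to 1e-10
  fit <- summary(stats::aov(y ~ g * w + Error(factor(s))))
  btab <- fit[["Error: factor(s)"]][[1]]
  wtab <- fit[["Error: Within"]][[1]]
  expect_equal(unname(res$between$statistic), btab["g", "F value"],
               tolerance = 1e-10)
  expect_equal(unname(res$within$statistic), wtab["w", "F value"],
               tolerance = 1e-10)
  expect_equal(unname(res$interaction$statistic), wtab["g:w", "F value"],
               tolerance = 1e-10)
  expect_equal(res$interaction$p, wtab["g:w", "Pr(>F)"],
               tolerance = 1e-10)
})

test_that("mixed ANOVA degenerate cases and the log transform", {
  # identical profiles in both groups: between F = 0
  y <- rep(c(1, 2, 3), 4)
  g <- rep(c("a", "b"), each = 6)
  s <- rep(paste0("s", 1:4), each = 3)
  w <- rep(paste0("w", 1:3), 4)
  res <- mixed_anova(y, g, w, s)
  expect_equal(unname(res$between$statistic), 0)
  # profiles constant across radii: within SS = 0
  y2 <- rep(c(2, 2, 2, 5, 5, 5, 3, 3, 3, 4, 4, 4))
  res2 <- mixed_anova(y2, g, w, s)
  expect_equal(res2$within$ss, 0, tolerance = 1e-12)
  # log10(y + 1) transform applied when flagged
  y3 <- c(10, 5, 0, 12, 6, 1, 3, 2, 0, 4, 2, 1)
  res3a <- mixed_anova(y3, g, w, s, log_transform = TRUE)
  res3b <- mixed_anova(log10(y3 + 1), g, w, s)
  expect_equal(unname(res3a$between$statistic),
               unname(res3b$between$statistic))
  expect_error(mixed_anova(y[-1], g[-1], w[-1], s[-1]), "one observation")
})

test_that("Grubbs screen matches the closed-form critical value", {
  expect_equal(grubbs_critical(3), 1.154305, tolerance = 1e-6)
  r <- grubbs_outlier(c(1, 2, 3))
  expect_length(r$outliers, 0)
  expect_equal(r$G, 1)
  x <- c(rnorm(10), 100)
  expect_equal(grubbs_outlier(x)$outliers, 11L)
  # only the most deviant extreme is tested (and flagged) per pass
  xs <- c(-3, seq(-1, 1, length.out = 18), 8)
  r1 <- grubbs_outlier(xs, iterate = FALSE)
  expect_equal(r1$outliers, 20L)
  expect_length(r1$outliers, 1)
  expect_error(grubbs_outlier(rep(2, 5)), "constant")
})

test_that("exact and approximate branches agree near the crossover size", {
  set.seed(46)
  dmax_mw <- 0
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- mann_whitney_u(x, y, exact = TRUE)$p
    pa <- mann_whitney_u(x, y, exact = FALSE)$p
    dmax_mw <- max(dmax_mw, abs(pe - pa))
  }
  expect_lt(dmax_mw, 0.02)
  dmax_sp <- 0
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(8)
    pe <- spearman_cor(x, y, exact = TRUE)$p
    pa <- spearman_cor(x, y, exact = FALSE)$p
    dmax_sp <- max(dmax_sp, abs(pe - pa))
  }
  expect_lt(dmax_sp, 0.02)
})
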