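# Nonparametric tests, multiplicity rules, cluster comparison.

test_that("Kruskal-Wallis reproduces the hand-computed H and its invariances", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # identical groups
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$statistic, 0)
  # invariance under strictly monotone transforms
  g <- list(rnorm(10), rnorm(12) + 1, rnorm(8) - 1)
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, function(x) exp(3 * x)))$statistic)
  expect_warning(kw_na <- kruskal_wallis(list(c(2, 2), c(2, 2, 2))),
                 "identical")
  expect_true(is.na(kw_na$statistic))
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "empty")
})

test_that("Dunn adjustment reproduces the printed post-hoc p-values", {
  expect_equal(dunn_p_adjust(2.36, m = 3), 0.055, tolerance = 0.01)
  expect_gt(dunn_p_adjust(-0.243, m = 3), 0.999)
  # identical groups give z = 0, adjusted p = 1
  d <- dunn_posthoc(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(d$z, 0)
  expect_equal(d$p_adj, 1)
  expect_equal(d$p_label, ">0.999")
  # z statistics agree with direct midrank computation on untied data
  g <- list(c(1, 5, 9), c(2, 6, 10), c(3, 7, 11, 14))
  dd <- dunn_posthoc(g)
  N <- 10
  rbar <- tapply(rank(unlist(g)), rep(1:3, lengths(g)), mean)
  z12 <- (rbar[1] - rbar[2]) / sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
  expect_equal(dd$z[1], unname(z12))
})

test_that("Dunn tie correction matches the Kruskal-Wallis tie handling", {
  g <- list(c(1, 1, 2, 3), c(2, 2, 3, 4), c(4, 4, 5, 5))
  dd <- dunn_posthoc(g)
  vals <- unlist(g)
  N <- length(vals)
  tie_tab <- table(vals)
  vb <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(rank(vals), rep(1:3, each = 4), mean)
  expect_equal(dd$z[1],
               unname((rbar[1] - rbar[2]) / sqrt(vb * (1 / 4 + 1 / 4))))
})

test_that("Spearman correlation uses midranks and the t approximation", {
  s <- spearman_corr(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_equal(s$statistic, cor(1:8, c(2, 1, 4, 3, 6, 5, 8, 7),
                                method = "spearman"))
  s1 <- spearman_corr(1:10, (1:10)^3)
  expect_equal(s1$statistic, 1)
  expect_equal(s1$p, 0)
  # p agrees with cor.test's asymptotic t route on tied data
  set.seed(6)
  x <- sample(1:5, 30, replace = TRUE)
  y <- x + sample(0:2, 30, replace = TRUE)
  ours <- spearman_corr(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(ours$statistic, unname(ct$estimate))
  expect_equal(ours$p, ct$p.value, tolerance = 1e-10)
  # Bonferroni-adjusted alpha for a family of three correlations
  expect_equal(spearman_corr(1:10, 10:1, n_tests = 3)$alpha_star,
               0.05 / 3)
  expect_warning(sz <- spearman_corr(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(sz$statistic))
})

test_that("chi-square test of independence covers the closed-form cases", {
  expect_equal(chi_square_independence(rbind(c(10, 20), c(20, 40)))$statistic, 0)
  suppressWarnings({
    r <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  })
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1L)
  r2 <- chi_square_independence(matrix(c(10, 12, 9, 11, 10, 8), nrow = 2,
                                       byrow = TRUE))
  expect_equal(r2$df, 2L)
  expect_error(chi_square_independence(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("cluster comparison applies the seven-score Bonferroni family", {
  coh <- generate_cohort(cohort_spec(seed = 61L))
  fit <- gsa(coh$trajectories, k = 3)
  panel <- score_panel(coh$trajectories)
  cmp <- suppressWarnings(compare_clusters(fit$labels, panel))
  expect_equal(cmp$alpha_star, 0.05 / 7, tolerance = 1e-12)
  expect_equal(round(cmp$alpha_star, 3), 0.007)
  # z-normalized panel: cohort mean 0, SD 1 per variable
  num_vars <- colnames(cmp$panel_z)
  for (v in num_vars) {
    z <- scale(panel[[v]])
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  }
  # the planted high-aggression cluster tops the interactive dyad mean
  high_cl <- names(which.max(table(fit$labels[coh$truth$true_type == "both_high"])))
  expect_equal(rownames(cmp$panel_z)[which.max(cmp$panel_z[, "mean_inter"])],
               high_cl)
  # post-hoc tables exist only for significant variables
  expect_true(all(names(cmp$posthoc) %in%
                    cmp$tests$variable[cmp$tests$significant]))
  expect_false(is.null(cmp$gender))
  expect_equal(cmp$gender$df, 2L)
})
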