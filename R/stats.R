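# Nonparametric tests and multiplicity handling: Kruskal-Wallis, Dunn
# post-hoc with tie correction, Spearman correlation, chi-square.

#' Kruskal-Wallis test across groups
#'
#' Wrapper around [stats::kruskal.test()] (midranks, tie correction)
#' returning a compact result record. When every value in the pooled
#' sample is identical the tie correction degenerates and the statistic
#' is undefined; this is flagged rather than reported as zero.
#'
#' @param groups List of numeric vectors, one per group.
#' @param name Label for the comparison.
#' @return List of class `test_result`: `name`, `statistic` (H), `df`,
#'   `p`, `group_sizes`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic  # 7.2
#' @export
kruskal_wallis <- function(groups, name = "kruskal_wallis") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    warning("all values identical: H undefined", call. = FALSE)
    return(structure(list(name = name, statistic = NA_real_,
                          df = length(groups) - 1L, p = NA_real_,
                          group_sizes = lengths(groups)),
                     class = "test_result"))
  }
  kt <- stats::kruskal.test(values, g)
  structure(list(name = name, statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value,
                 group_sizes = lengths(groups)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$name,
              x$statistic, paste(x$df, collapse = ","), x$p))
  if (!is.null(x$alpha_star))
    cat(sprintf("  Bonferroni-adjusted alpha: %.4g\n", x$alpha_star))
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on mean midranks of the pooled sample with the
#' tie-corrected pooled variance,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 -
#' \sum(t^3 - t)/(12(N-1)))(1/n_i + 1/n_j)}},
#' two-sided p-values Bonferroni-multiplied by `m` and capped at 1.
#' Adjusted values above 0.999 are labelled `">0.999"`.
#'
#' @param groups List of numeric vectors (the Kruskal-Wallis groups).
#' @param m Number of comparisons for the Bonferroni adjustment;
#'   defaults to the number of pairs.
#' @return Data frame with `group1`, `group2`, `z`, `p`, `p_adj`,
#'   `p_label`.
#' @export
dunn_posthoc <- function(groups, m = choose(length(groups), 2)) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  gnames <- if (!is.null(names(groups))) names(groups) else
    as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    data.frame(group1 = gnames[i], group2 = gnames[j], z = unname(z),
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out$p_label <- ifelse(out$p_adj > 0.999, ">0.999",
                        formatC(out$p_adj, digits = 3, format = "f"))
  out
}

#' Bonferroni-adjusted p from a Dunn z statistic
#'
#' @param z Dunn z statistic.
#' @param m Number of comparisons.
#' @return Adjusted two-sided p-value, capped at 1.
#' @examples
#' dunn_p_adjust(2.36, m = 3)   # 0.055
#' @export
dunn_p_adjust <- function(z, m) pmin(1, m * 2 * stats::pnorm(-abs(z)))

#' Spearman rank correlation with t-approximation p-value
#'
#' rho from midranks; two-sided p from
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 df. When the
#' correlation is part of a Bonferroni family, the adjusted alpha
#' `alpha / n_tests` is reported alongside.
#'
#' @param x,y Paired numeric vectors (complete observations).
#' @param n_tests Size of the test family.
#' @param alpha Family-wise alpha.
#' @param name Label.
#' @return List of class `test_result` with `statistic` (rho), `df`
#'   (n - 2), `p`, `alpha_star`, `n`.
#' @export
spearman_corr <- function(x, y, n_tests = 1, alpha = 0.05,
                          name = "spearman") {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(structure(list(name = name, statistic = NA_real_, df = n - 2L,
                          p = NA_real_, alpha_star = alpha / n_tests, n = n),
                     class = "test_result"))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p_approx(rho, n)
  structure(list(name = name, statistic = rho, df = n - 2L, p = p,
                 alpha_star = alpha / n_tests, n = n),
            class = "test_result")
}

#' Two-sided p-value for a Spearman rho via the t approximation
#'
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} referred to a t distribution
#' on n - 2 df; the approximation used for reporting rank correlations
#' at moderate n.
#'
#' @param rho Spearman correlation.
#' @param n Number of paired observations.
#' @return Two-sided p-value.
#' @examples
#' spearman_p_approx(0.36, 56)   # ~0.006
#' @export
spearman_p_approx <- function(rho, n) {
  stopifnot(n > 2, abs(rho) <= 1)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

#' Pearson chi-square test of independence
#'
#' [stats::chisq.test()] without continuity correction on a two-way
#' count table; warns when any expected count falls below 5.
#'
#' @param tab Two-way contingency table or matrix of counts.
#' @param name Label.
#' @return List of class `test_result` with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(tab, name = "chi_square") {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected counts below 5: chi-square approximation inaccurate",
            call. = FALSE)
  structure(list(name = name, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "test_result")
}
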