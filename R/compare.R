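# Cluster characterisation: Kruskal-Wallis across clusters with
# Bonferroni control, Dunn post-hocs, z-normalized radar panels.

#' Compare GSA clusters across dyad-level variables
#'
#' For every variable in the score panel a Kruskal-Wallis test across
#' the clusters is run; the significance threshold for the seven iTAP
#' scores is Bonferroni-adjusted to `alpha / 7` (0.007 at alpha 0.05).
#' Dunn's pairwise tests are run on variables falling below the
#' adjusted threshold. For radar-plot export every variable is
#' z-normalized over the cohort (mean 0, SD 1) and averaged within
#' cluster. The gender composition of the clusters is tested with a
#' chi-square test of independence when a `gender` column is present.
#'
#' @param labels Named integer cluster labels (e.g. from [gsa()]),
#'   names matching `panel$dyad_id`.
#' @param panel Data frame with one row per dyad: `dyad_id`, optional
#'   `gender`, and numeric score columns (see [score_panel()]).
#' @param itap_vars Which columns form the iTAP score family sharing
#'   the Bonferroni correction; defaults to the seven [score_panel()]
#'   scores present in `panel`.
#' @param alpha Family-wise alpha.
#' @return List of class `cluster_comparison`: `tests` (data frame),
#'   `posthoc` (named list of Dunn tables), `panel_z` (cluster x
#'   variable matrix of z-normalized means), `gender` (chi-square
#'   result or `NULL`), `alpha_star`, `cluster_sizes`.
#' @export
compare_clusters <- function(labels, panel, itap_vars = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(panel), "dyad_id" %in% names(panel))
  if (is.null(names(labels))) stop("`labels` must be named by dyad id",
                                   call. = FALSE)
  panel <- panel[match(names(labels), panel$dyad_id), , drop = FALSE]
  if (anyNA(panel$dyad_id))
    stop("labels and panel dyad ids do not match", call. = FALSE)
  default_itap <- c("mean_inter", "diff_inter", "mean_fake", "diff_fake",
                    "mean_zero", "diff_zero", "mean_prepost")
  if (is.null(itap_vars)) itap_vars <- intersect(default_itap, names(panel))
  num_vars <- names(panel)[vapply(panel, is.numeric, TRUE)]
  cl <- factor(labels)
  sizes <- table(cl)
  if (any(sizes < 2L))
    warning("cluster of size < 2: comparisons unstable", call. = FALSE)
  alpha_star <- alpha / max(1L, length(itap_vars))

  tests <- do.call(rbind, lapply(num_vars, function(v) {
    grp <- split(panel[[v]], cl)
    kw <- kruskal_wallis(grp, name = v)
    thr <- if (v %in% itap_vars) alpha_star else alpha
    data.frame(variable = v, H = kw$statistic, df = kw$df, p = kw$p,
               threshold = thr,
               significant = !is.na(kw$p) & kw$p < thr,
               stringsAsFactors = FALSE)
  }))

  posthoc <- list()
  for (v in tests$variable[tests$significant]) {
    posthoc[[v]] <- dunn_posthoc(split(panel[[v]], cl))
  }

  zmat <- sapply(num_vars, function(v) {
    z <- as.numeric(scale(panel[[v]]))
    tapply(z, cl, mean)
  })
  zmat <- matrix(zmat, nrow = nlevels(cl),
                 dimnames = list(levels(cl), num_vars))

  gender_test <- NULL
  if ("gender" %in% names(panel))
    gender_test <- chi_square_independence(table(panel$gender, cl),
                                           name = "gender_by_cluster")

  structure(list(tests = tests, posthoc = posthoc, panel_z = zmat,
                 gender = gender_test, alpha_star = alpha_star,
                 cluster_sizes = as.integer(sizes)),
            class = "cluster_comparison")
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat(sprintf("Cluster comparison: %d clusters (sizes %s), alpha* = %.4g\n",
              length(x$cluster_sizes),
              paste(x$cluster_sizes, collapse = "/"), x$alpha_star))
  t <- x$tests
  t$H <- round(t$H, 2); t$p <- signif(t$p, 3)
  print(t[, c("variable", "H", "df", "p", "significant")], row.names = FALSE)
  if (!is.null(x$gender))
    cat(sprintf("gender x cluster: chi2 = %.2f, df = %d, p = %.3f\n",
                x$gender$statistic, x$gender$df, x$gender$p))
  invisible(x)
}
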