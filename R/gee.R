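# Generalized estimating equations for the manipulation check:
# Gaussian family, identity link, exchangeable working correlation,
# robust (sandwich) covariance, clustered on dyad.

#' Gaussian GEE with exchangeable working correlation
#'
#' Fits a marginal linear model to correlated repeated measures by
#' generalized estimating equations: iterated generalized least squares
#' with a moment estimate of the exchangeable within-cluster
#' correlation, and the robust sandwich covariance of the coefficients.
#' With `corstr = "independence"` the point estimates coincide with
#' ordinary least squares while the covariance remains cluster-robust.
#'
#' @param formula Model formula.
#' @param data Data frame in long format.
#' @param id Name of the cluster identifier column.
#' @param corstr Working correlation structure.
#' @param bias_correction Small-sample treatment of the sandwich:
#'   `"mancl-derouen"` (default) inflates each cluster's residual
#'   contribution by the inverse of its leverage, counteracting the
#'   downward bias of the plain sandwich when the number of clusters is
#'   small; `"none"` gives the classic robust covariance.
#' @param tol,max_iter Convergence control for the coefficient
#'   iteration.
#' @return An object of class `gee_fit` with `coefficients`, `vcov`
#'   (robust), `vcov_naive`, `alpha` (working correlation), `phi`
#'   (scale), `assign`/`term_labels` for term-wise Wald tests, and
#'   `n_clusters`.
#' @export
gee_gaussian <- function(formula, data, id,
                         corstr = c("exchangeable", "independence"),
                         bias_correction = c("mancl-derouen", "none"),
                         tol = 1e-8, max_iter = 50) {
  corstr <- match.arg(corstr)
  bias_correction <- match.arg(bias_correction)
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  cl <- factor(data[[id]][as.integer(rownames(mf))])
  if (anyNA(cl)) stop("missing cluster ids", call. = FALSE)
  idx <- split(seq_along(y), cl)
  N <- length(y); p <- ncol(X)

  beta <- stats::lm.fit(X, y)$coefficients
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in idx) {
        ri <- r[ix]
        ni <- length(ri)
        if (ni > 1L) {
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha <- (num / phi) / (npairs - p)
      alpha <- min(max(alpha, -0.99), 0.99)
    }
    B <- matrix(0, p, p)
    u <- numeric(p)
    for (ix in idx) {
      Xi <- X[ix, , drop = FALSE]
      ni <- length(ix)
      Ri_inv <- if (corstr == "exchangeable" && ni > 1L) {
        # closed-form inverse of (1-a)I + aJ
        a <- alpha
        (diag(ni) - matrix(a / (1 + (ni - 1) * a), ni, ni)) / (1 - a)
      } else diag(ni)
      B <- B + crossprod(Xi, Ri_inv %*% Xi)
      u <- u + crossprod(Xi, Ri_inv %*% y[ix])
    }
    beta_new <- solve(B, u)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }

  r <- y - X %*% beta
  phi <- sum(r^2) / (N - p)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in idx) {
    Xi <- X[ix, , drop = FALSE]
    ni <- length(ix)
    Ri_inv <- if (corstr == "exchangeable" && ni > 1L) {
      a <- alpha
      (diag(ni) - matrix(a / (1 + (ni - 1) * a), ni, ni)) / (1 - a)
    } else diag(ni)
    XtR <- crossprod(Xi, Ri_inv)
    B <- B + XtR %*% Xi
  }
  B_inv <- solve(B)
  for (ix in idx) {
    Xi <- X[ix, , drop = FALSE]
    ni <- length(ix)
    Ri_inv <- if (corstr == "exchangeable" && ni > 1L) {
      a <- alpha
      (diag(ni) - matrix(a / (1 + (ni - 1) * a), ni, ni)) / (1 - a)
    } else diag(ni)
    ei <- r[ix]
    if (bias_correction == "mancl-derouen")
      ei <- solve(diag(ni) - Xi %*% B_inv %*% crossprod(Xi, Ri_inv), ei)
    s <- crossprod(Xi, Ri_inv %*% ei)
    M <- M + tcrossprod(s)
  }
  vcov_robust <- B_inv %*% M %*% B_inv
  beta <- drop(beta)
  names(beta) <- colnames(X)
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vcov_robust,
                 vcov_naive = phi * B_inv, alpha = alpha, phi = phi,
                 assign = attr(X, "assign"),
                 term_labels = attr(stats::terms(mf), "term.labels"),
                 corstr = corstr, bias_correction = bias_correction,
                 formula = formula,
                 n_clusters = length(idx), n_obs = N, n_params = p,
                 X = X, residuals = drop(r), cluster = cl),
            class = "gee_fit")
}

#' Term-wise Wald tests for a GEE fit
#'
#' Wald statistic per model term on the robust covariance. With few
#' clusters the chi-square reference for a multi-df Wald statistic is
#' anti-conservative, so by default the statistic is referred to an F
#' distribution via Hotelling's T-squared on nu = K - p effective
#' degrees of freedom (K clusters, p coefficients):
#' \eqn{F = W (\nu - q + 1)/(\nu q)} on \eqn{(q, \nu - q + 1)} df for a
#' q-df term. `ref = "chisq"` gives the classic asymptotic reference.
#'
#' @param fit A [gee_gaussian()] fit.
#' @param ref Reference distribution for p-values.
#' @return Data frame with one row per model term: Wald `chisq`
#'   statistic, `df`, `p`.
#' @export
gee_wald <- function(fit, ref = c("hotelling-f", "chisq")) {
  stopifnot(inherits(fit, "gee_fit"))
  ref <- match.arg(ref)
  nu <- fit$n_clusters - fit$n_params
  rows <- lapply(seq_along(fit$term_labels), function(t) {
    sel <- which(fit$assign == t)
    b <- fit$coefficients[sel]
    V <- fit$vcov[sel, sel, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    q <- length(sel)
    p <- if (ref == "chisq" || nu - q + 1 <= 0) {
      stats::pchisq(stat, q, lower.tail = FALSE)
    } else {
      stats::pf(stat * (nu - q + 1) / (nu * q), q, nu - q + 1,
                lower.tail = FALSE)
    }
    data.frame(term = fit$term_labels[t], chisq = stat, df = q, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Gaussian GEE (%s), %d obs in %d clusters, alpha = %.3f\n",
              x$corstr, x$n_obs, x$n_clusters, x$alpha))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' Manipulation-check GEE on dyad block scores
#'
#' Fits a GEE to a dyad-by-block panel (5 rows per dyad, one per task
#' block) with block, gender and their interaction as predictors, dyad
#' as the cluster unit, Gaussian identity link and exchangeable working
#' correlation -- the model validating that provocation changed dyadic
#' aggression. Reports Wald chi-square tests with the design df: block
#' 4, gender 1, interaction 4.
#'
#' @param panel Data frame from [dyad_block_panel()]: columns
#'   `dyad_id`, `gender`, `block` plus the dependent variables.
#' @param dv `"dyad_mean"` or `"dyad_diff"`.
#' @param corstr Working correlation structure.
#' @return List of class `gee_result`: the `fit` and the `wald` table.
#' @export
gee_block_gender <- function(panel, dv = c("dyad_mean", "dyad_diff"),
                             corstr = "exchangeable") {
  dv <- match.arg(dv)
  need <- c("dyad_id", "gender", "block", dv)
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "), call. = FALSE)
  counts <- table(panel$dyad_id)
  nblk <- length(unique(panel$block))
  bad <- names(counts)[counts != nblk]
  if (length(bad))
    stop("unbalanced panel for dyad(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  panel$block <- factor(panel$block, levels = c("B1", "B2", "FAKE", "B3", "B4"))
  panel$gender <- factor(panel$gender)
  if (nlevels(panel$gender) < 2L) {
    warning("single-gender cohort: gender terms dropped from the model",
            call. = FALSE)
    f <- stats::as.formula(paste(dv, "~ block"))
  } else {
    f <- stats::as.formula(paste(dv, "~ block * gender"))
  }
  fit <- gee_gaussian(f, panel, id = "dyad_id", corstr = corstr)
  structure(list(fit = fit, wald = gee_wald(fit), dv = dv),
            class = "gee_result")
}

#' @export
print.gee_result <- function(x, ...) {
  cat(sprintf("Manipulation check GEE, dv = %s\n", x$dv))
  w <- x$wald
  w$chisq <- round(w$chisq, 2)
  w$p <- signif(w$p, 3)
  print(w, row.names = FALSE)
  invisible(x)
}

#' Post-hoc block contrasts from a manipulation-check GEE
#'
#' Model-based pairwise contrasts of the marginal block means: for each
#' of the 10 block pairs the design rows are averaged within block
#' (marginalising over the observed gender mix), the contrast is tested
#' with a Wald z using the robust covariance, and two-sided p-values
#' are Bonferroni-adjusted for the 10 pairs.
#'
#' @param result A [gee_block_gender()] result.
#' @param m Number of comparisons for the Bonferroni adjustment.
#' @return Data frame with `block1`, `block2`, `estimate`, `se`, `z`,
#'   `p`, `p_adj`.
#' @export
posthoc_block_contrasts <- function(result, m = 10) {
  stopifnot(inherits(result, "gee_result"))
  fit <- result$fit
  X <- fit$X
  blocks <- c("B1", "B2", "FAKE", "B3", "B4")
  # identify each observation's block from its dummy columns (B1 = reference)
  obs_block <- rep(blocks[1], nrow(X))
  for (b in blocks[-1]) obs_block[X[, paste0("block", b)] == 1] <- b
  xbar <- sapply(blocks, function(b)
    colMeans(X[obs_block == b, , drop = FALSE]))
  pairs <- utils::combn(blocks, 2)
  rows <- apply(pairs, 2, function(pr) {
    L <- xbar[, pr[1]] - xbar[, pr[2]]
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    z <- if (se > 0) est / se else 0
    data.frame(block1 = pr[1], block2 = pr[2], estimate = est, se = se,
               z = z, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out
}
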