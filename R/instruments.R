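# Questionnaire subscale scoring and internal consistency.

#' Score a questionnaire subscale
#'
#' Sum score per respondent, taking item polarity into account
#' (reverse-keyed responses are mapped `x -> min + max - x` on the
#' declared response scale) and using mean imputation: a respondent's
#' missing items are replaced by the mean of their non-missing
#' (post-reversal) items on the same subscale. Respondents with no
#' usable item are flagged `NA`.
#'
#' @param items Numeric matrix or data frame, respondents in rows and
#'   items in columns.
#' @param reversed Logical per item, `TRUE` for reverse-keyed items.
#' @param bounds Length-2 numeric, the response scale's `c(min, max)`.
#' @return Data frame with `score` (sum over items) and `n_imputed` per
#'   respondent.
#' @examples
#' score_subscale(rbind(c(4, 4, NA)), reversed = c(FALSE, FALSE, FALSE),
#'                bounds = c(1, 5))  # imputes 4, sum 12
#' @export
score_subscale <- function(items, reversed = rep(FALSE, ncol(items)),
                           bounds) {
  items <- as.matrix(items)
  stopifnot(length(reversed) == ncol(items), length(bounds) == 2L)
  out_of_scale <- !is.na(items) & (items < bounds[1] | items > bounds[2])
  if (any(out_of_scale))
    stop("item responses outside the declared scale bounds", call. = FALSE)
  items[, reversed] <- bounds[1] + bounds[2] - items[, reversed]
  n_miss <- rowSums(is.na(items))
  all_missing <- n_miss == ncol(items)
  if (any(all_missing))
    warning(sprintf("%d respondent(s) with all items missing: score undefined",
                    sum(all_missing)), call. = FALSE)
  row_mean <- rowMeans(items, na.rm = TRUE)
  imputed <- items
  for (j in seq_len(ncol(items))) {
    miss <- is.na(imputed[, j])
    imputed[miss, j] <- row_mean[miss]
  }
  score <- rowSums(imputed)
  score[all_missing] <- NA_real_
  data.frame(score = score, n_imputed = n_miss, row.names = NULL)
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items,
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_{\mathrm{total}}^2)},
#' with sample variances (denominator n-1) and listwise deletion of
#' incomplete respondents.
#'
#' @param items Numeric matrix or data frame, respondents in rows.
#' @param reversed Optional logical per item; reverse-keyed items are
#'   mapped onto the scale direction of the others before computing
#'   alpha, so alpha is invariant to reversing an item and flipping its
#'   flag.
#' @param bounds Response scale `c(min, max)`, required when `reversed`
#'   has any `TRUE`.
#' @return Alpha, or `NA` with a warning when the total-score variance
#'   is zero.
#' @export
cronbach_alpha <- function(items, reversed = NULL, bounds = NULL) {
  items <- as.matrix(items)
  if (!is.null(reversed) && any(reversed)) {
    if (is.null(bounds)) stop("`bounds` required with reversed items",
                              call. = FALSE)
    items[, reversed] <- bounds[1] + bounds[2] - items[, reversed]
  }
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2L || nrow(items) < 3L)
    stop("need >= 2 items and >= 3 complete respondents", call. = FALSE)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) {
    warning("zero variance of item sums: alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  item_vars <- apply(items, 2, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}
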