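# Derived aggression scores: block means, dyad mean/difference scores,
# zero-aggression counts, pre-post differences, outcome-conditioned means.

member_selections <- function(traj, member) {
  stopifnot(inherits(traj, "dyad_trajectory"), member %in% c("a", "b"))
  traj$trials[[paste0("sel_", member)]]
}

mean_or_flag <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    warning("block with all-missing selections: mean undefined", call. = FALSE)
    return(NaN)
  }
  mean(x)
}

#' Per-block mean aggression scores for one member
#'
#' Mean monetary selection per block, treating the five scripted fake
#' trials as a block of their own (five block means in total), plus the
#' mean over the 60 interactive trials. Missing selections
#' (non-responses) are excluded from the means; a block whose selections
#' are all missing yields `NaN` with a warning.
#'
#' @param traj A [dyad_trajectory()].
#' @param member `"a"` or `"b"`.
#' @return List with `block_means` (named numeric, B1/B2/FAKE/B3/B4) and
#'   `interactive_mean`.
#' @export
block_mean_scores <- function(traj, member) {
  sel <- member_selections(traj, member)
  blk <- traj$trials$block_id
  order_blocks <- c("B1", "B2", "FAKE", "B3", "B4")
  bm <- vapply(order_blocks, function(b) mean_or_flag(sel[blk == b]), numeric(1))
  list(block_means = bm,
       interactive_mean = mean_or_flag(sel[!traj$trials$is_fake]))
}

#' Dyad-level block scores
#'
#' For every block the dyad mean, `(m_a + m_b)/2`, and the dyad
#' difference, `|m_a - m_b|`, of the two members' block means. Members
#' are treated as indistinguishable, hence the absolute difference.
#'
#' @param traj A [dyad_trajectory()].
#' @return Data frame with columns `block`, `dyad_mean`, `dyad_diff`.
#' @export
dyad_block_scores <- function(traj) {
  ma <- block_mean_scores(traj, "a")$block_means
  mb <- block_mean_scores(traj, "b")$block_means
  data.frame(block = names(ma),
             dyad_mean = (ma + mb) / 2,
             dyad_diff = abs(ma - mb),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Zero-aggression counts and pre-post difference
#'
#' `zero_interactive` counts the interactive trials (60) on which the
#' member selected 0 cents, `zero_fake` the same over the five fake
#' trials. `pre_post_diff` is the mean selection over the 30 trials
#' before the fake block minus the mean over the 30 trials after it, so
#' positive values mean the member de-escalated relative to the opening
#' blocks.
#'
#' @inheritParams block_mean_scores
#' @return List with `zero_interactive`, `zero_fake`, `pre_post_diff`.
#' @export
derived_scores <- function(traj, member) {
  sel <- member_selections(traj, member)
  blk <- traj$trials$block_id
  pre <- sel[blk %in% c("B1", "B2")]
  post <- sel[blk %in% c("B3", "B4")]
  list(zero_interactive = sum(sel[!traj$trials$is_fake] == 0, na.rm = TRUE),
       zero_fake = sum(sel[traj$trials$is_fake] == 0, na.rm = TRUE),
       pre_post_diff = mean_or_flag(pre) - mean_or_flag(post))
}

#' Outcome-conditioned mean aggression
#'
#' Mean selection on trials whose *preceding* trial ended in a win, loss
#' or tie for this member, over all 65 trials (interactive and fake).
#' The first trial has no preceding outcome and is excluded, so the
#' three group sizes sum to 64.
#'
#' @inheritParams block_mean_scores
#' @return Named numeric of length 3 (`WIN`, `LOSS`, `TIE`); groups with
#'   no trials yield `NaN` with a warning.
#' @export
outcome_conditioned_means <- function(traj, member) {
  sel <- member_selections(traj, member)
  out <- traj$trials[[paste0("outcome_", member)]]
  nt <- length(sel)
  prev_out <- out[seq_len(nt - 1L)]
  cur_sel <- sel[-1L]
  vapply(c(WIN = "WIN", LOSS = "LOSS", TIE = "TIE"),
         function(o) mean_or_flag(cur_sel[prev_out == o]), numeric(1))
}

#' Individual score panel for one member
#'
#' Convenience wrapper collecting [block_mean_scores()],
#' [derived_scores()] and [outcome_conditioned_means()] into one row.
#'
#' @inheritParams block_mean_scores
#' @return One-row data frame.
#' @export
individual_scores <- function(traj, member) {
  bm <- block_mean_scores(traj, member)
  ds <- derived_scores(traj, member)
  om <- outcome_conditioned_means(traj, member)
  data.frame(dyad_id = traj$dyad_id, member = member,
             t(bm$block_means), interactive_mean = bm$interactive_mean,
             zero_interactive = ds$zero_interactive, zero_fake = ds$zero_fake,
             pre_post_diff = ds$pre_post_diff,
             mean_after_win = om[["WIN"]], mean_after_loss = om[["LOSS"]],
             mean_after_tie = om[["TIE"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dyad-level score panel for a cohort
#'
#' The seven iTAP scores used to characterise clusters, one row per
#' dyad: dyad mean and absolute difference of the interactive-trial
#' mean, of the fake-trial mean and of the zero-aggression count, plus
#' the dyad mean of the pre-post aggression difference.
#'
#' @param trajectories List of [dyad_trajectory()].
#' @return Data frame with columns `dyad_id`, `gender`, `mean_inter`,
#'   `diff_inter`, `mean_fake`, `diff_fake`, `mean_zero`, `diff_zero`,
#'   `mean_prepost`.
#' @export
score_panel <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    a <- block_mean_scores(tr, "a"); b <- block_mean_scores(tr, "b")
    da <- derived_scores(tr, "a"); db <- derived_scores(tr, "b")
    fa <- a$block_means[["FAKE"]]; fb <- b$block_means[["FAKE"]]
    za <- da$zero_interactive; zb <- db$zero_interactive
    data.frame(
      dyad_id = tr$dyad_id, gender = tr$gender,
      mean_inter = (a$interactive_mean + b$interactive_mean) / 2,
      diff_inter = abs(a$interactive_mean - b$interactive_mean),
      mean_fake = (fa + fb) / 2, diff_fake = abs(fa - fb),
      mean_zero = (za + zb) / 2, diff_zero = abs(za - zb),
      mean_prepost = (da$pre_post_diff + db$pre_post_diff) / 2,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Long-format dyad block scores for a cohort
#'
#' One row per dyad and block with the dyad mean and difference
#' aggression scores, gender attached -- the input panel for the
#' manipulation-check GEE models.
#'
#' @param trajectories List of [dyad_trajectory()].
#' @return Data frame with columns `dyad_id`, `gender`, `block`,
#'   `dyad_mean`, `dyad_diff`.
#' @export
dyad_block_panel <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    sc <- dyad_block_scores(tr)
    cbind(data.frame(dyad_id = tr$dyad_id, gender = tr$gender,
                     stringsAsFactors = FALSE), sc)
  })
  do.call(rbind, rows)
}
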