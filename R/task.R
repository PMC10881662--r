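# Task rules: punishment scale, block layout, outcome schedule, settlement.

#' iTAP task configuration
#'
#' Describes the structure of the interactive Taylor Aggression Paradigm:
#' the 10-level monetary punishment scale (0--90 cents in steps of 10),
#' four interactive blocks of 15 trials, and a scripted "fake" block of
#' five trials (displayed opponent selections 30-50-50-60-70 cents)
#' inserted between the second and third interactive block. The winner of
#' a trial gains a fixed 50 cents; the loser forfeits the amount the
#' winner pre-selected; failing to respond costs a fixed 100 cents and
#' the trial.
#'
#' @param levels Ordered punishment scale in cents.
#' @param n_interactive_blocks Number of interactive blocks.
#' @param trials_per_block Trials per interactive block.
#' @param fake_levels Scripted provocation levels shown during the fake
#'   block, in cents.
#' @param win_gain Fixed gain of the trial winner, in cents.
#' @param nonresponse_penalty Fixed deduction for failing to select a
#'   punishment, in cents.
#' @param fake_outcomes Outcome labels for the five fake trials. Five
#'   trials cannot split evenly into win/loss/tie, so a default pattern
#'   is used; any length-5 vector over `WIN_A`/`WIN_B`/`TIE` is accepted.
#' @return An object of class `itap_config`.
#' @examples
#' cfg <- itap_config()
#' cfg$fake_levels
#' @export
itap_config <- function(levels = seq(0L, 90L, by = 10L),
                        n_interactive_blocks = 4L,
                        trials_per_block = 15L,
                        fake_levels = c(30L, 50L, 50L, 60L, 70L),
                        win_gain = 50L,
                        nonresponse_penalty = 100L,
                        fake_outcomes = c("WIN_A", "WIN_B", "TIE", "WIN_A", "WIN_B")) {
  levels <- as.integer(levels)
  if (length(levels) != 10L || any(diff(levels) != diff(levels)[1L]))
    stop("`levels` must be 10 equally spaced values", call. = FALSE)
  if (trials_per_block %% 3L != 0L)
    stop("`trials_per_block` must be divisible by 3 (equal win/loss/tie counts)",
         call. = FALSE)
  if (length(fake_outcomes) != length(fake_levels))
    stop("`fake_outcomes` must match the fake block length", call. = FALSE)
  if (!all(fake_outcomes %in% c("WIN_A", "WIN_B", "TIE")))
    stop("`fake_outcomes` must be WIN_A, WIN_B or TIE", call. = FALSE)
  cfg <- list(
    levels = levels,
    n_interactive_blocks = as.integer(n_interactive_blocks),
    trials_per_block = as.integer(trials_per_block),
    fake_levels = as.integer(fake_levels),
    win_gain = as.integer(win_gain),
    nonresponse_penalty = as.integer(nonresponse_penalty),
    fake_outcomes = fake_outcomes
  )
  class(cfg) <- "itap_config"
  cfg
}

#' @export
print.itap_config <- function(x, ...) {
  cat("iTAP task configuration\n")
  cat("  punishment scale:", paste(x$levels, collapse = " "), "cents\n")
  cat("  blocks:", x$n_interactive_blocks, "interactive x",
      x$trials_per_block, "trials +", length(x$fake_levels), "fake trials\n")
  cat("  fake script:", paste(x$fake_levels, collapse = "-"), "cents\n")
  invisible(x)
}

n_trials <- function(cfg) {
  cfg$n_interactive_blocks * cfg$trials_per_block + length(cfg$fake_levels)
}

#' Block labels for every trial
#'
#' Trials 1--15 are `B1`, 16--30 `B2`, 31--35 `FAKE`, 36--50 `B3` and
#' 51--65 `B4` under the default configuration.
#'
#' @param cfg An [itap_config()].
#' @return Character vector, one label per trial.
#' @export
block_labels <- function(cfg = itap_config()) {
  tpb <- cfg$trials_per_block
  nf <- length(cfg$fake_levels)
  c(rep("B1", tpb), rep("B2", tpb), rep("FAKE", nf), rep("B3", tpb), rep("B4", tpb))
}

#' Deterministic outcome schedule
#'
#' The rock-paper-scissors outcome of every trial was preprogrammed:
#' within each interactive block of 15 trials, wins for member A, wins
#' for member B and ties occur in equal proportion (5/5/5) in a fixed
#' order identical across dyads. The fake block takes its outcomes from
#' the configured pattern.
#'
#' @param cfg An [itap_config()].
#' @return Character vector over `WIN_A`, `WIN_B`, `TIE`, one element per
#'   trial (65 by default).
#' @examples
#' table(build_outcome_schedule()[1:15])
#' @export
build_outcome_schedule <- function(cfg = itap_config()) {
  per_block <- rep(c("WIN_A", "WIN_B", "TIE"), cfg$trials_per_block / 3L)
  labs <- block_labels(cfg)
  out <- character(length(labs))
  out[labs == "FAKE"] <- cfg$fake_outcomes
  for (b in c("B1", "B2", "B3", "B4")[seq_len(cfg$n_interactive_blocks)])
    out[labs == b] <- per_block
  out
}

check_on_scale <- function(sel, cfg, who, trial = NA) {
  bad <- !is.na(sel) & !(sel %in% cfg$levels)
  if (any(bad))
    stop(sprintf("off-scale selection %s for member %s (trial %s)",
                 paste(sel[bad], collapse = ","), who,
                 paste(trial[bad], collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

#' Settle one trial
#'
#' Applies the payoff rules: the winner of the trial gains `win_gain`
#' cents and the loser forfeits the amount the *winner* selected; ties
#' transfer nothing. A member who failed to respond (selection `NA`)
#' loses the trial regardless of the scheduled outcome and is deducted
#' the fixed non-response penalty while the opponent receives the
#' winner's gain; if both fail, both are penalised and the trial is
#' recorded as a tie.
#'
#' @param sel_a,sel_b Punishment selections in cents, or `NA` for a
#'   non-response.
#' @param scheduled Scheduled outcome, one of `WIN_A`, `WIN_B`, `TIE`.
#' @param cfg An [itap_config()].
#' @return List with `outcome_a`, `outcome_b` (`WIN`/`LOSS`/`TIE`) and
#'   `payoff_a`, `payoff_b` in signed cents.
#' @examples
#' settle_trial(40, 70, "WIN_A")   # A wins +50, B loses 40
#' @export
settle_trial <- function(sel_a, sel_b, scheduled, cfg = itap_config()) {
  stopifnot(scheduled %in% c("WIN_A", "WIN_B", "TIE"))
  check_on_scale(sel_a, cfg, "a")
  check_on_scale(sel_b, cfg, "b")
  miss_a <- is.na(sel_a)
  miss_b <- is.na(sel_b)
  if (miss_a && miss_b)
    return(list(outcome_a = "TIE", outcome_b = "TIE",
                payoff_a = -cfg$nonresponse_penalty,
                payoff_b = -cfg$nonresponse_penalty))
  if (miss_a)
    return(list(outcome_a = "LOSS", outcome_b = "WIN",
                payoff_a = -cfg$nonresponse_penalty, payoff_b = cfg$win_gain))
  if (miss_b)
    return(list(outcome_a = "WIN", outcome_b = "LOSS",
                payoff_a = cfg$win_gain, payoff_b = -cfg$nonresponse_penalty))
  switch(scheduled,
    TIE = list(outcome_a = "TIE", outcome_b = "TIE", payoff_a = 0L, payoff_b = 0L),
    WIN_A = list(outcome_a = "WIN", outcome_b = "LOSS",
                 payoff_a = cfg$win_gain, payoff_b = -sel_a),
    WIN_B = list(outcome_a = "LOSS", outcome_b = "WIN",
                 payoff_a = -sel_b, payoff_b = cfg$win_gain))
}

#' Assemble a dyad trajectory
#'
#' Builds the per-trial record of a full iTAP session for one dyad from
#' both members' selections: block labels, displayed punishments (the
#' sibling's true selection on interactive trials, the scripted level on
#' fake trials), scheduled outcomes and settled payoffs.
#'
#' @param dyad_id Identifier.
#' @param sel_a,sel_b Integer vectors of 65 selections (cents, `NA` =
#'   non-response).
#' @param gender `"male_pair"` or `"female_pair"`.
#' @param ages Numeric length-2, ages of members a and b in years.
#' @param cfg An [itap_config()].
#' @param schedule Outcome schedule; defaults to
#'   [build_outcome_schedule()].
#' @return An object of class `dyad_trajectory`: a list with `dyad_id`,
#'   `gender`, `ages` and a 65-row `trials` data frame.
#' @export
dyad_trajectory <- function(dyad_id, sel_a, sel_b,
                            gender = NA_character_, ages = c(NA_real_, NA_real_),
                            cfg = itap_config(),
                            schedule = build_outcome_schedule(cfg)) {
  nt <- n_trials(cfg)
  if (length(sel_a) != nt || length(sel_b) != nt)
    stop(sprintf("need %d selections per member", nt), call. = FALSE)
  check_on_scale(sel_a, cfg, "a", seq_len(nt))
  check_on_scale(sel_b, cfg, "b", seq_len(nt))
  labs <- block_labels(cfg)
  is_fake <- labs == "FAKE"
  disp_a <- ifelse(is_fake, NA_integer_, sel_b)
  disp_b <- ifelse(is_fake, NA_integer_, sel_a)
  disp_a[is_fake] <- cfg$fake_levels
  disp_b[is_fake] <- cfg$fake_levels
  settled <- lapply(seq_len(nt), function(t)
    settle_trial(sel_a[t], sel_b[t], schedule[t], cfg))
  trials <- data.frame(
    trial_index = seq_len(nt),
    block_id = labs,
    is_fake = is_fake,
    sel_a = as.integer(sel_a),
    sel_b = as.integer(sel_b),
    disp_a = as.integer(disp_a),
    disp_b = as.integer(disp_b),
    outcome_a = vapply(settled, `[[`, "", "outcome_a"),
    outcome_b = vapply(settled, `[[`, "", "outcome_b"),
    payoff_a = vapply(settled, function(s) as.integer(s$payoff_a), 0L),
    payoff_b = vapply(settled, function(s) as.integer(s$payoff_b), 0L),
    stringsAsFactors = FALSE
  )
  structure(list(dyad_id = as.character(dyad_id), gender = gender,
                 ages = as.numeric(ages), trials = trials, cfg = cfg),
            class = "dyad_trajectory")
}

#' @export
print.dyad_trajectory <- function(x, ...) {
  cat(sprintf("iTAP dyad trajectory '%s' (%s): %d trials, %d fake\n",
              x$dyad_id, ifelse(is.na(x$gender), "gender NA", x$gender),
              nrow(x$trials), sum(x$trials$is_fake)))
  invisible(x)
}
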