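# Reciprocity-based generator of synthetic iTAP dyads.

#' Behavioural parameters of a simulated player
#'
#' The generator follows a linear reciprocity ("tit-for-tat") rule. At
#' trial 1 a member selects their baseline plus noise; afterwards the
#' selection is a convex combination of the (de-escalating) baseline and
#' the punishment last displayed by the opponent, plus a loss-reactivity
#' bump and Gaussian noise, clipped to \[0, 90\] and rounded to the
#' nearest multiple of 10:
#' \deqn{s(t+1) = q\big((1-\rho)(b - \delta \max(0, t-35)) + \rho d(t)
#'   + \gamma 1[\mathrm{loss}(t)] + \epsilon\big)}
#' De-escalation is indexed to trial 35, the end of the scripted
#' provocation block, so the baseline decays only during the real
#' interaction that follows it.
#'
#' @param b Baseline selection (cents, 0--90).
#' @param rho Reciprocity weight in \[0, 1\].
#' @param gamma Loss reactivity: cents added after losing a trial.
#' @param delta De-escalation rate in cents per trial after the fake
#'   block ends.
#' @param sigma Pre-quantisation noise standard deviation (cents).
#' @param p_nonresponse Probability of failing to respond on a trial.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(b, rho = 0, gamma = 0, delta = 0, sigma = 0,
                         p_nonresponse = 0) {
  if (b < 0 || b > 90) stop("baseline `b` must lie in [0, 90]", call. = FALSE)
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]", call. = FALSE)
  if (gamma < 0 || delta < 0 || sigma < 0 || p_nonresponse < 0 || p_nonresponse > 1)
    stop("`gamma`, `delta`, `sigma` must be >= 0; `p_nonresponse` in [0, 1]",
         call. = FALSE)
  structure(list(b = b, rho = rho, gamma = gamma, delta = delta,
                 sigma = sigma, p_nonresponse = p_nonresponse),
            class = "agent_params")
}

# clip to the scale range then round to the nearest level (half away from 0)
quantize_level <- function(x, cfg) {
  step <- diff(cfg$levels)[1L]
  x <- pmin(max(cfg$levels), pmax(min(cfg$levels), x))
  as.integer(floor(x / step + 0.5) * step)
}

#' Simulate one dyad's iTAP session
#'
#' Plays both members forward through the 65-trial session under the
#' reciprocity rule of [agent_params()]. On fake trials each member sees
#' the scripted provocation (30-50-50-60-70 cents) instead of the
#' sibling's true selection, so the response to the script propagates
#' into the interaction that follows.
#'
#' @param params_a,params_b [agent_params()] for the two members.
#' @param cfg An [itap_config()].
#' @param seed Integer seed; the trajectory is reproducible given the
#'   seed.
#' @param dyad_id,gender,ages Passed to [dyad_trajectory()].
#' @return A [dyad_trajectory()].
#' @examples
#' tr <- simulate_dyad(agent_params(b = 30), agent_params(b = 30), seed = 1)
#' all(tr$trials$sel_a == 30)  # no noise, no reciprocity: constant baseline
#' @export
simulate_dyad <- function(params_a, params_b, cfg = itap_config(), seed,
                          dyad_id = "dyad", gender = NA_character_,
                          ages = c(NA_real_, NA_real_)) {
  stopifnot(inherits(params_a, "agent_params"), inherits(params_b, "agent_params"))
  if (!missing(seed)) set.seed(as.integer(seed))
  nt <- n_trials(cfg)
  schedule <- build_outcome_schedule(cfg)
  labs <- block_labels(cfg)
  fake_end <- max(which(labs == "FAKE"))
  sel <- matrix(NA_integer_, nrow = nt, ncol = 2)
  disp <- matrix(NA_integer_, nrow = nt, ncol = 2)
  outc <- matrix(NA_character_, nrow = nt, ncol = 2)
  pars <- list(params_a, params_b)

  draw <- function(p, mean_part) {
    if (stats::runif(1) < p$p_nonresponse) return(NA_integer_)
    quantize_level(mean_part + stats::rnorm(1, 0, p$sigma), cfg)
  }

  for (t in seq_len(nt)) {
    for (i in 1:2) {
      p <- pars[[i]]
      if (t == 1L) {
        mean_part <- p$b
      } else {
        base <- p$b - p$delta * max(0, (t - 1L) - fake_end)
        mean_part <- (1 - p$rho) * base + p$rho * disp[t - 1L, i] +
          p$gamma * as.numeric(identical(outc[t - 1L, i], "LOSS"))
        # a non-response leaves nothing displayed; fall back to baseline pull
        if (is.na(disp[t - 1L, i]))
          mean_part <- base + p$gamma * as.numeric(identical(outc[t - 1L, i], "LOSS"))
      }
      sel[t, i] <- draw(p, mean_part)
    }
    if (labs[t] == "FAKE") {
      fk <- cfg$fake_levels[sum(labs[seq_len(t)] == "FAKE")]
      disp[t, ] <- c(fk, fk)
    } else {
      disp[t, ] <- c(sel[t, 2], sel[t, 1])
    }
    s <- settle_trial(sel[t, 1], sel[t, 2], schedule[t], cfg)
    outc[t, ] <- c(s$outcome_a, s$outcome_b)
  }
  dyad_trajectory(dyad_id, sel[, 1], sel[, 2], gender = gender, ages = ages,
                  cfg = cfg, schedule = schedule)
}

#' Default dyad-type parameter templates
#'
#' Three planted dyad types mirroring the subgroups the analysis is
#' designed to recover: both members low-aggressive, both high, and a
#' mixed pair with one high and one low baseline. Baselines 10/75 and
#' (70, 20); all types share moderate reciprocity, a 5-cent loss bump,
#' a 0.5 cents/trial final de-escalation and 5-cent noise.
#'
#' @return Named list of lists with elements `a` and `b`
#'   ([agent_params()] each).
#' @export
dyad_type_templates <- function() {
  list(
    both_low = list(a = agent_params(b = 10, rho = 0.3, gamma = 5, delta = 0.5, sigma = 5),
                    b = agent_params(b = 10, rho = 0.3, gamma = 5, delta = 0.5, sigma = 5)),
    both_high = list(a = agent_params(b = 75, rho = 0.4, gamma = 5, delta = 0.5, sigma = 5),
                     b = agent_params(b = 75, rho = 0.4, gamma = 5, delta = 0.5, sigma = 5)),
    mixed = list(a = agent_params(b = 70, rho = 0.3, gamma = 5, delta = 0.5, sigma = 5),
                 b = agent_params(b = 20, rho = 0.3, gamma = 5, delta = 0.5, sigma = 5))
  )
}

#' Cohort specification
#'
#' @param n_per_type Named integer vector of dyad counts; names must
#'   match `templates`. The default 10/10/8 gives the study-sized cohort
#'   of 28 dyads.
#' @param templates Parameter templates per type; see
#'   [dyad_type_templates()].
#' @param n_male_pairs How many of the dyads are brother pairs (the rest
#'   are sister pairs); by default the study's 13/28 proportion scaled
#'   to the cohort size.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_type = c(both_low = 10L, both_high = 10L, mixed = 8L),
                        templates = dyad_type_templates(),
                        n_male_pairs = NULL,
                        seed = 20240208L) {
  if (!all(names(n_per_type) %in% names(templates)))
    stop("every type in `n_per_type` needs a template", call. = FALSE)
  if (any(n_per_type < 2L))
    stop("at least 2 dyads per requested type", call. = FALSE)
  if (is.null(n_male_pairs))
    n_male_pairs <- round(13 / 28 * sum(n_per_type))
  structure(list(n_per_type = n_per_type, templates = templates,
                 n_male_pairs = as.integer(n_male_pairs),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Simulates `sum(n_per_type)` dyads with planted type labels. Gender is
#' assigned by a seeded permutation of `n_male_pairs` brother pairs over
#' the cohort; ages are drawn from the study's demographic profile
#' (mean 23.4, SD 3.4 years, truncated to 18--35, sibling gap centred on
#' 2.3 years). All randomness derives from `spec$seed`, so two calls
#' with the same spec are identical.
#'
#' @param spec A [cohort_spec()].
#' @param cfg An [itap_config()].
#' @return List with `trajectories` (list of [dyad_trajectory()]) and
#'   `truth` (data frame: `dyad_id`, `true_type`, `gender`, `age_a`,
#'   `age_b`).
#' @export
generate_cohort <- function(spec = cohort_spec(), cfg = itap_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  types <- rep(names(spec$n_per_type), spec$n_per_type)
  n <- length(types)
  dyad_seeds <- sample.int(.Machine$integer.max - 1L, n)
  genders <- rep("female_pair", n)
  genders[sample.int(n, min(spec$n_male_pairs, n))] <- "male_pair"
  rtrunc_age <- function() {
    repeat {
      a <- stats::rnorm(1, 23.39, 3.42)
      if (a >= 18 && a <= 35) return(round(a, 1))
    }
  }
  trajectories <- vector("list", n)
  truth <- data.frame(dyad_id = sprintf("D%02d", seq_len(n)),
                      true_type = types, gender = genders,
                      age_a = NA_real_, age_b = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    age_a <- rtrunc_age()
    age_b <- min(35, max(18, round(age_a + sample(c(-1, 1), 1) *
                                     min(5, abs(stats::rnorm(1, 2.3, 1.41))), 1)))
    truth$age_a[i] <- age_a
    truth$age_b[i] <- age_b
    tmpl <- spec$templates[[types[i]]]
    trajectories[[i]] <- simulate_dyad(tmpl$a, tmpl$b, cfg = cfg,
                                       seed = dyad_seeds[i],
                                       dyad_id = truth$dyad_id[i],
                                       gender = genders[i],
                                       ages = c(age_a, age_b))
  }
  list(trajectories = trajectories, truth = truth)
}
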