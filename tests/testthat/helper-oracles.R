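# Independent oracles and fixture builders shared across test files.

# Exhaustive recursive search over all edit scripts (substitute / delete /
# insert) -- deliberately naive and independent of the dynamic programme.
brute_om <- function(c1, c2, indel = 1) {
  n <- nrow(c1); m <- nrow(c2)
  if (n == 0L && m == 0L) return(0)
  best <- Inf
  if (n > 0L && m > 0L) {
    sub <- abs(c1[1, 1] - c2[1, 1]) + abs(c1[1, 2] - c2[1, 2])
    best <- min(best, sub + brute_om(c1[-1, , drop = FALSE],
                                     c2[-1, , drop = FALSE], indel))
  }
  if (n > 0L)
    best <- min(best, indel + brute_om(c1[-1, , drop = FALSE], c2, indel))
  if (m > 0L)
    best <- min(best, indel + brute_om(c1, c2[-1, , drop = FALSE], indel))
  best
}

# random cell sequence over a sub-grid, distinguishable mode
random_seq <- function(len, id, max_level = 9L) {
  cell_sequence(cbind(sample(0:max_level, len, replace = TRUE),
                      sample(0:max_level, len, replace = TRUE)),
                id = id, mode = "distinguishable")
}

# a cohort with no block, gender or type structure: iid noise around a
# common baseline
null_cohort_spec <- function(seed, n = 28L, b = 45, sigma = 10) {
  tmpl <- list(null = list(a = agent_params(b = b, sigma = sigma),
                           b = agent_params(b = b, sigma = sigma)))
  cohort_spec(n_per_type = stats::setNames(n, "null"), templates = tmpl,
              seed = seed)
}

# trajectory with hand-picked selections for both members
fixture_trajectory <- function(sel_a, sel_b, id = "fix") {
  dyad_trajectory(id, sel_a, sel_b, gender = "female_pair", ages = c(25, 23))
}
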