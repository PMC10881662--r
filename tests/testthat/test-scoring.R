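# Derived aggression scores and questionnaire scoring.

test_that("block means follow the five-block partition", {
  tr <- fixture_trajectory(rep(30L, 65), rep(30L, 65))
  bm <- block_mean_scores(tr, "a")
  expect_equal(unname(bm$block_means), rep(30, 5))
  expect_equal(bm$interactive_mean, 30)
  expect_length(bm$block_means, 5L)

  sel <- c(rep(0L, 30), rep(90L, 35))  # 0 on B1-B2, 90 from FAKE on
  tr2 <- fixture_trajectory(sel, rep(50L, 65))
  bm2 <- block_mean_scores(tr2, "a")
  expect_equal(unname(bm2$block_means), c(0, 0, 90, 90, 90))
  expect_equal(bm2$interactive_mean, 45)
})

test_that("interactive mean equals the weighted mean of interactive block means", {
  tr <- simulate_dyad(agent_params(b = 40, rho = 0.5, sigma = 20),
                      agent_params(b = 60, rho = 0.3, sigma = 20), seed = 21)
  bm <- block_mean_scores(tr, "b")
  expect_equal(bm$interactive_mean,
               mean(bm$block_means[c("B1", "B2", "B3", "B4")]))
})

test_that("dyad scores are symmetric in member relabelling", {
  tr <- fixture_trajectory(rep(20L, 65), rep(40L, 65))
  sc <- dyad_block_scores(tr)
  expect_equal(sc$dyad_mean, rep(30, 5))
  expect_equal(sc$dyad_diff, rep(20, 5))
  swapped <- fixture_trajectory(rep(40L, 65), rep(20L, 65))
  expect_equal(dyad_block_scores(swapped)[, c("dyad_mean", "dyad_diff")],
               sc[, c("dyad_mean", "dyad_diff")])
  same <- fixture_trajectory(rep(40L, 65), rep(40L, 65))
  expect_equal(dyad_block_scores(same)$dyad_diff, rep(0, 5))
})

test_that("zero counts and pre-post difference use the right trial windows", {
  sel <- c(rep(20L, 30), rep(50L, 35))
  ds <- derived_scores(fixture_trajectory(sel, rep(10L, 65)), "a")
  expect_equal(ds$pre_post_diff, -30)

  ds0 <- derived_scores(fixture_trajectory(rep(0L, 65), rep(10L, 65)), "a")
  expect_equal(ds0$zero_interactive, 60L)
  expect_equal(ds0$zero_fake, 5L)

  sel_b1 <- c(rep(0L, 15), rep(10L, 50))
  expect_equal(derived_scores(fixture_trajectory(sel_b1, rep(10L, 65)), "a")$zero_interactive,
               15L)
})

test_that("outcome-conditioned means partition trials 2..65 by preceding outcome", {
  tr <- fixture_trajectory(rep(50L, 65), rep(50L, 65))
  om <- outcome_conditioned_means(tr, "a")
  expect_equal(unname(om), rep(50, 3))

  # selections track the previous trial's own outcome: +10 after a loss
  sched <- build_outcome_schedule()
  out_a <- c("WIN_A" = "WIN", "WIN_B" = "LOSS", "TIE" = "TIE")[sched]
  sel <- c(40L, ifelse(out_a[-65] == "LOSS", 50L, 40L))
  tr2 <- fixture_trajectory(sel, rep(30L, 65))
  om2 <- outcome_conditioned_means(tr2, "a")
  expect_equal(om2[["LOSS"]] - om2[["WIN"]], 10)

  # group sizes partition the 64 usable trials
  counts <- table(tr$trials$outcome_a[1:64])
  expect_equal(sum(counts), 64L)
})

test_that("subscale scoring reverses, imputes and bounds correctly", {
  # reversed item: 2 on a 1-5 scale contributes 4
  s <- score_subscale(matrix(c(2, 3), nrow = 1), reversed = c(TRUE, FALSE),
                      bounds = c(1, 5))
  expect_equal(s$score, 4 + 3)
  # mean imputation
  s2 <- score_subscale(matrix(c(4, 4, NA), nrow = 1),
                       reversed = rep(FALSE, 3), bounds = c(1, 5))
  expect_equal(s2$score, 12)
  expect_equal(s2$n_imputed, 1L)
  # plain sum without missing or reversal
  s3 <- score_subscale(rbind(c(1, 2, 3), c(5, 5, 5)),
                       reversed = rep(FALSE, 3), bounds = c(1, 5))
  expect_equal(s3$score, c(6, 15))
  expect_error(score_subscale(matrix(c(0, 3), nrow = 1),
                              reversed = c(FALSE, FALSE), bounds = c(1, 5)),
               "bounds")
  expect_warning(score_subscale(matrix(c(NA, NA), nrow = 1),
                                reversed = c(FALSE, FALSE), bounds = c(1, 5)),
                 "all items missing")
})

test_that("Cronbach's alpha matches the closed form and its invariances", {
  # duplicated identical items are perfectly consistent
  x <- matrix(rnorm(30), ncol = 2)
  x[, 2] <- x[, 1]
  expect_equal(cronbach_alpha(x), 1)
  # constructed 2-item matrix with variances 1 and covariance 0.5
  m <- cbind(c(1, 2, 3), c(1, 3, 2))
  expect_equal(cov(m)[1, 2], 0.5)
  expect_equal(cronbach_alpha(m), 2 * (1 - 2 / 3))
  # reversing an item and flipping its polarity flag leaves alpha unchanged
  set.seed(4)
  items <- matrix(sample(1:5, 60, replace = TRUE), ncol = 4)
  rev_items <- items
  rev_items[, 2] <- 1 + 5 - rev_items[, 2]
  expect_equal(cronbach_alpha(items),
               cronbach_alpha(rev_items,
                              reversed = c(FALSE, TRUE, FALSE, FALSE),
                              bounds = c(1, 5)))
  expect_warning(cronbach_alpha(matrix(c(1, 2, 1, 2, 1, 2), ncol = 2,
                                       byrow = TRUE)), "undefined")
})

test_that("score panel is invariant to member relabelling", {
  tr <- simulate_dyad(agent_params(b = 30, rho = 0.3, sigma = 10),
                      agent_params(b = 70, rho = 0.3, sigma = 10), seed = 5,
                      dyad_id = "D1")
  swapped <- tr
  swapped$trials[, c("sel_a", "sel_b")] <- swapped$trials[, c("sel_b", "sel_a")]
  swapped$trials[, c("outcome_a", "outcome_b")] <-
    swapped$trials[, c("outcome_b", "outcome_a")]
  p1 <- score_panel(list(tr))
  p2 <- score_panel(list(swapped))
  num <- vapply(p1, is.numeric, TRUE)
  expect_equal(p1[, num], p2[, num])
})
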