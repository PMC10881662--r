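# Grid encoding, Manhattan cost model, optimal matching, Ward clustering.

test_that("indistinguishable encoding mirrors at the diagonal and drops fakes", {
  sel_a <- rep(30L, 65); sel_b <- rep(70L, 65)
  s1 <- encode_indistinguishable(fixture_trajectory(sel_a, sel_b))
  s2 <- encode_indistinguishable(fixture_trajectory(sel_b, sel_a))
  expect_identical(s1$cells, s2$cells)
  expect_equal(unname(s1$cells[1, ]), c(3L, 7L))
  expect_equal(length(s1), 60L)
  s0 <- encode_indistinguishable(fixture_trajectory(rep(0L, 65), rep(0L, 65)))
  expect_equal(unname(s0$cells[1, ]), c(0L, 0L))
})

test_that("distinguishable encoding pins the script on the second axis", {
  cfg <- itap_config()
  s <- encode_distinguishable(c(30L, 50L, 50L, 60L, 70L), cfg, id = "p1")
  expect_equal(unname(s$cells), cbind(c(3L, 5L, 5L, 6L, 7L), c(3L, 5L, 5L, 6L, 7L)),
               ignore_attr = TRUE)
  sz <- encode_distinguishable(rep(0L, 5), cfg, id = "p2")
  expect_equal(unname(sz$cells[, 1]), rep(0L, 5))
  expect_equal(unname(sz$cells[, 2]), c(3L, 5L, 5L, 6L, 7L))
  # feasible alphabet: 4 distinct scripted rows x 10 participant levels
  expect_equal(length(unique(cfg$fake_levels)) * 10L, 40L)
  expect_error(encode_distinguishable(c(30L, 50L), cfg), "exactly 5")
})

test_that("cost matrix is a Manhattan metric over the active alphabet", {
  cm <- build_cost_matrix("distinguishable")
  expect_equal(nrow(cm$alphabet), 100L)
  expect_equal(cm$substitution["35", "45"], 1)
  expect_equal(cm$substitution["00", "99"], 18)
  expect_equal(max(cm$substitution), 18)
  expect_true(all(diag(cm$substitution) == 0))
  expect_true(isSymmetric(cm$substitution))
  cmc <- build_cost_matrix("indistinguishable")
  expect_equal(nrow(cmc$alphabet), 55L)
})

test_that("canonical Manhattan cost equals the minimum over diagonal reflections", {
  cells <- build_cost_matrix("indistinguishable")$alphabet
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(nrow(cells))) {
      direct <- abs(cells[i, 1] - cells[j, 1]) + abs(cells[i, 2] - cells[j, 2])
      reflect <- abs(cells[i, 1] - cells[j, 2]) + abs(cells[i, 2] - cells[j, 1])
      expect_identical(unname(direct), unname(min(direct, reflect)))
    }
  }
})

test_that("optimal matching agrees with exhaustive edit-script enumeration", {
  set.seed(31)
  cost <- build_cost_matrix("distinguishable")
  for (rep in 1:60) {
    s1 <- random_seq(sample(0:4, 1), "s1", max_level = 2L)
    s2 <- random_seq(sample(0:4, 1), "s2", max_level = 2L)
    expect_equal(om_distance(s1, s2, cost), brute_om(s1$cells, s2$cells))
  }
  # non-unit indel cost as well
  cost2 <- build_cost_matrix("distinguishable", indel = 2.5)
  for (rep in 1:20) {
    s1 <- random_seq(sample(0:3, 1), "s1", max_level = 2L)
    s2 <- random_seq(sample(0:3, 1), "s2", max_level = 2L)
    expect_equal(om_distance(s1, s2, cost2),
                 brute_om(s1$cells, s2$cells, indel = 2.5))
  }
})

test_that("om_distance degenerate cases and the indel-2 cap", {
  cost <- build_cost_matrix("distinguishable")
  s <- random_seq(5, "s")
  expect_equal(om_distance(s, s, cost), 0)
  empty <- cell_sequence(matrix(integer(0), ncol = 2), "e", "distinguishable")
  expect_equal(om_distance(s, empty, cost), 5)
  expect_equal(om_distance(empty, s, cost), 5)
  # adjacent-cell substitution beats delete+insert
  a <- cell_sequence(rbind(c(1, 1), c(2, 2), c(3, 3)), "a", "distinguishable")
  b <- cell_sequence(rbind(c(1, 1), c(2, 3), c(3, 3)), "b", "distinguishable")
  expect_equal(om_distance(a, b, cost), 1)
  # with indel 1 the effective per-position cost never exceeds 2
  set.seed(8)
  for (rep in 1:30) {
    s1 <- random_seq(10, "s1"); s2 <- random_seq(10, "s2")
    aligned_cap <- sum(pmin(rowSums(abs(s1$cells - s2$cells)), 2))
    expect_lte(om_distance(s1, s2, cost), aligned_cap)
  }
  smode <- cell_sequence(rbind(c(0, 1)), "m", "indistinguishable")
  expect_error(om_distance(s, smode), "mode mismatch")
})

test_that("dissimilarity matrices are symmetric, zero-diagonal and equivariant", {
  set.seed(12)
  seqs <- lapply(1:6, function(i) random_seq(8, paste0("s", i)))
  d <- pairwise_dissimilarity(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(d >= 0))
  perm <- c(3, 1, 6, 2, 5, 4)
  d2 <- pairwise_dissimilarity(seqs[perm])
  expect_equal(d2, d[perm, perm])
})

test_that("triangle inequality holds on random sequence triples", {
  set.seed(13)
  cost <- build_cost_matrix("distinguishable")
  for (rep in 1:200) {
    lens <- sample(3:8, 3, replace = TRUE)
    s <- lapply(1:3, function(i) random_seq(lens[i], paste0("t", i)))
    d12 <- om_distance(s[[1]], s[[2]], cost)
    d13 <- om_distance(s[[1]], s[[3]], cost)
    d23 <- om_distance(s[[2]], s[[3]], cost)
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("Ward clustering separates planted structure and handles edge cuts", {
  # two groups with zero within-group distance
  g1 <- cell_sequence(rbind(c(1, 1), c(1, 1)), "a1", "distinguishable")
  g2 <- cell_sequence(rbind(c(1, 1), c(1, 1)), "a2", "distinguishable")
  g3 <- cell_sequence(rbind(c(8, 8), c(8, 8)), "b1", "distinguishable")
  g4 <- cell_sequence(rbind(c(8, 8), c(8, 8)), "b2", "distinguishable")
  fit <- gsa(list(g1, g2, g3, g4), k = 2, min_size = 1)
  expect_equal(unname(fit$labels[c("a1", "a2")]), rep(1L, 2))
  expect_equal(unname(fit$labels[c("b1", "b2")]), rep(2L, 2))
  # k = n puts every sequence in its own cluster
  fitn <- gsa(list(g1, g2, g3, g4), k = 4, min_size = 1)
  expect_equal(length(unique(fitn$labels)), 4L)
  expect_error(gsa(list(g1, g2), k = 5, min_size = 1), "out of range")
})

test_that("sibling-role swaps leave the indistinguishable pipeline unchanged", {
  coh <- generate_cohort(cohort_spec(n_per_type = c(both_low = 3L, both_high = 3L,
                                                    mixed = 3L), seed = 55L))
  trajs <- coh$trajectories
  swapped <- lapply(trajs, function(tr) {
    tr$trials[, c("sel_a", "sel_b")] <- tr$trials[, c("sel_b", "sel_a")]
    tr
  })
  f1 <- gsa(trajs, k = 3)
  f2 <- gsa(swapped, k = 3)
  expect_equal(f1$dissimilarity, f2$dissimilarity)
  expect_equal(f1$labels, f2$labels)
})

test_that("select_k finds planted group counts and respects min_size", {
  coh <- generate_cohort(cohort_spec(seed = 41L))
  fit <- gsa(coh$trajectories, k = 3)
  expect_equal(fit$k_recommended, 3L)
  # homogeneous cohort: no dominant gap
  coh1 <- generate_cohort(null_cohort_spec(seed = 42L, n = 12L))
  fit1 <- gsa(coh1$trajectories, k = 2)
  expect_equal(fit1$k_recommended, 1L)
  # min_size above n/2 rules out k > 2
  expect_lte(select_k(fit$tree, min_size = 15), 2L)
})

test_that("letter labels enumerate the alphabet in order", {
  cm <- build_cost_matrix("indistinguishable")
  lab <- cell_letter_labels(cm)
  expect_equal(length(lab), 55L)
  expect_equal(lab[1:3], c("a", "b", "c"))
  expect_equal(anyDuplicated(lab), 0L)
})
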