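# Grid Sequence Analysis: state-space-grid encoding, optimal-matching
# dissimilarities under a Manhattan cost model, Ward clustering.

#' Cell sequence on the state-space grid
#'
#' A trajectory through the 10x10 grid whose cells are joint punishment
#' combinations, stored as an n x 2 integer matrix of level indices
#' (level index = cents / 10). In `"indistinguishable"` mode the two
#' dyad members are interchangeable: cells mirrored at the diagonal are
#' identified, and every cell is stored in canonical sorted form
#' `u <= v`. In `"distinguishable"` mode the first coordinate is the
#' real player and the second the scripted fake opponent.
#'
#' @param cells Integer matrix with two columns of level indices in
#'   0--9.
#' @param id Sequence identifier (dyad or participant).
#' @param mode `"indistinguishable"` or `"distinguishable"`.
#' @return An object of class `cell_sequence`.
#' @export
cell_sequence <- function(cells, id, mode = c("indistinguishable", "distinguishable")) {
  mode <- match.arg(mode)
  cells <- matrix(as.integer(cells), ncol = 2,
                  dimnames = list(NULL, c("u", "v")))
  if (any(is.na(cells)) || any(cells < 0L) || any(cells > 9L))
    stop("cell indices must lie in 0..9", call. = FALSE)
  if (mode == "indistinguishable" && any(cells[, 1] > cells[, 2]))
    stop("indistinguishable cells must be canonical (u <= v)", call. = FALSE)
  structure(list(id = as.character(id), mode = mode, cells = cells),
            class = "cell_sequence")
}

#' @export
print.cell_sequence <- function(x, ...) {
  cat(sprintf("cell_sequence '%s' (%s), length %d\n",
              x$id, x$mode, nrow(x$cells)))
  invisible(x)
}

#' @export
length.cell_sequence <- function(x) nrow(x$cells)

#' Encode a dyad's interactive trials (indistinguishable)
#'
#' Maps the 60 interactive trials to canonical grid cells: the two
#' members' selections are sorted so that `(30, 70)` and `(70, 30)`
#' land in the same cell `(3, 7)` -- the grid is mirrored at its
#' diagonal because members are treated as interchangeable. Fake trials
#' are excluded. Trials with a missing selection are dropped from the
#' sequence with a message (optimal matching tolerates unequal
#' lengths).
#'
#' @param traj A [dyad_trajectory()].
#' @return A [cell_sequence()] in indistinguishable mode, length 60 for
#'   a complete trajectory.
#' @export
encode_indistinguishable <- function(traj) {
  stopifnot(inherits(traj, "dyad_trajectory"))
  tr <- traj$trials[!traj$trials$is_fake, ]
  keep <- !is.na(tr$sel_a) & !is.na(tr$sel_b)
  if (!all(keep))
    message(sprintf("dyad %s: dropped %d trial(s) with missing selections",
                    traj$dyad_id, sum(!keep)))
  tr <- tr[keep, ]
  step <- diff(traj$cfg$levels)[1L]
  u <- pmin(tr$sel_a, tr$sel_b) %/% step
  v <- pmax(tr$sel_a, tr$sel_b) %/% step
  cell_sequence(cbind(u, v), traj$dyad_id, "indistinguishable")
}

#' Encode one participant's fake trials (distinguishable)
#'
#' Maps a member's five responses during the scripted provocation block
#' to cells (participant level, scripted level): the real player on the
#' first axis, the fake opponent on the second. Under the default
#' script (30-50-50-60-70 cents) the second coordinates are fixed at
#' (3, 5, 5, 6, 7), so only four grid rows are feasible.
#'
#' @param selections Five fake-trial selections in cents, or a
#'   [dyad_trajectory()] together with `member`.
#' @param cfg An [itap_config()].
#' @param id Sequence identifier.
#' @param member When `selections` is a trajectory, which member
#'   (`"a"`/`"b"`) to encode.
#' @return A [cell_sequence()] in distinguishable mode, length 5.
#' @export
encode_distinguishable <- function(selections, cfg = itap_config(),
                                   id = "participant", member = NULL) {
  if (inherits(selections, "dyad_trajectory")) {
    traj <- selections
    stopifnot(member %in% c("a", "b"))
    cfg <- traj$cfg
    id <- paste0(traj$dyad_id, "_", member)
    selections <- traj$trials[[paste0("sel_", member)]][traj$trials$is_fake]
  }
  if (length(selections) != length(cfg$fake_levels))
    stop(sprintf("need exactly %d fake-trial selections",
                 length(cfg$fake_levels)), call. = FALSE)
  if (any(is.na(selections)))
    stop("missing fake-trial selections cannot be encoded", call. = FALSE)
  check_on_scale(selections, cfg, "fake")
  step <- diff(cfg$levels)[1L]
  cell_sequence(cbind(selections %/% step, cfg$fake_levels %/% step),
                id, "distinguishable")
}

canonical_cells <- function(mode) {
  g <- expand.grid(u = 0:9, v = 0:9)
  if (mode == "indistinguishable") g <- g[g$u <= g$v, ]
  as.matrix(g[order(g$u, g$v), ])
}

#' Manhattan cost model for optimal matching
#'
#' Substitution between cells `(u1, v1)` and `(u2, v2)` costs their
#' Manhattan distance `|u1 - u2| + |v1 - v2|`, giving low costs to
#' neighbouring cells and stepwise increasing costs with grid distance;
#' insertion/deletion costs `indel` (1 by default). The full
#' substitution matrix over the active alphabet (100 cells, or the 55
#' canonical cells in indistinguishable mode, where sorted coordinates
#' realise the minimum over diagonal reflections) is cached on the
#' object.
#'
#' @param mode `"indistinguishable"` or `"distinguishable"`.
#' @param indel Insertion/deletion cost.
#' @return An object of class `om_cost` with elements `mode`, `indel`,
#'   `alphabet` (cell matrix) and `substitution` (cost matrix).
#' @export
build_cost_matrix <- function(mode = c("indistinguishable", "distinguishable"),
                              indel = 1) {
  mode <- match.arg(mode)
  stopifnot(indel >= 0)
  cells <- canonical_cells(mode)
  sub <- outer(seq_len(nrow(cells)), seq_len(nrow(cells)),
               function(i, j) abs(cells[i, 1] - cells[j, 1]) +
                 abs(cells[i, 2] - cells[j, 2]))
  lab <- paste0(cells[, 1], cells[, 2])
  dimnames(sub) <- list(lab, lab)
  structure(list(mode = mode, indel = indel, alphabet = cells,
                 substitution = sub),
            class = "om_cost")
}

#' Optimal-matching distance between two cell sequences
#'
#' Minimal total cost of transforming one sequence into the other by
#' substitutions (Manhattan cell cost), insertions and deletions
#' (`indel` each), computed by dynamic programming.
#'
#' @param s1,s2 [cell_sequence()] objects in the same mode.
#' @param cost An [build_cost_matrix()] model matching that mode.
#' @return Non-negative dissimilarity.
#' @export
om_distance <- function(s1, s2, cost = build_cost_matrix(s1$mode)) {
  stopifnot(inherits(s1, "cell_sequence"), inherits(s2, "cell_sequence"),
            inherits(cost, "om_cost"))
  if (s1$mode != s2$mode || s1$mode != cost$mode)
    stop("sequence/cost mode mismatch", call. = FALSE)
  om_dist_cpp(s1$cells, s2$cells, cost$indel)
}

#' Pairwise optimal-matching dissimilarity matrix
#'
#' @param sequences List of [cell_sequence()] in a common mode.
#' @param cost An [build_cost_matrix()] model.
#' @return Symmetric numeric matrix with zero diagonal, sequence ids as
#'   dimnames.
#' @export
pairwise_dissimilarity <- function(sequences,
                                   cost = build_cost_matrix(sequences[[1]]$mode)) {
  stopifnot(length(sequences) >= 2L)
  n <- length(sequences)
  ids <- vapply(sequences, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- om_distance(sequences[[i]], sequences[[j]], cost)
  }
  d
}

#' Grid Sequence Analysis of an iTAP cohort
#'
#' The package's central fit. Encodes each dyad's session as a
#' trajectory through the 10x10 state-space grid, computes all pairwise
#' optimal-matching dissimilarities under the Manhattan cost model, and
#' builds a Ward linkage tree on the dissimilarity matrix. In
#' `"interactive"` mode the 60 real trials of each dyad are encoded
#' with members treated as interchangeable (one sequence per dyad); in
#' `"fake"` mode each participant's five responses to the scripted
#' provocation are encoded individually against the script (two
#' sequences per dyad).
#'
#' @param x List of [dyad_trajectory()] objects, or a list of
#'   [cell_sequence()] objects in a common mode.
#' @param mode `"interactive"` (indistinguishable encoding) or `"fake"`
#'   (distinguishable encoding); ignored when `x` is already a list of
#'   sequences.
#' @param indel Insertion/deletion cost (default 1, the study's
#'   setting).
#' @param method Ward variant: `"ward.D"` (default) on raw
#'   dissimilarities or `"ward.D2"` on squared ones.
#' @param k Number of clusters to cut; `NULL` to use the
#'   [select_k()] recommendation.
#' @param min_size Minimum cluster size passed to [select_k()].
#' @return An object of class `gsa` with elements `sequences`, `cost`,
#'   `dissimilarity`, `tree` (an [stats::hclust] object), `method`,
#'   `k`, `labels` (named integer cluster labels) and `k_recommended`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_type = c(both_low = 3, both_high = 3),
#'                                    seed = 7))
#' fit <- gsa(coh$trajectories, k = 2)
#' table(fit$labels, coh$truth$true_type)
#' @export
gsa <- function(x, mode = c("interactive", "fake"), indel = 1,
                method = c("ward.D", "ward.D2"), k = NULL, min_size = 3) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (length(x) && inherits(x[[1]], "dyad_trajectory")) {
    sequences <- if (mode == "interactive") {
      lapply(x, encode_indistinguishable)
    } else {
      unlist(lapply(x, function(tr) list(
        encode_distinguishable(tr, member = "a"),
        encode_distinguishable(tr, member = "b"))), recursive = FALSE)
    }
  } else if (length(x) && inherits(x[[1]], "cell_sequence")) {
    sequences <- x
  } else stop("`x` must be a list of dyad trajectories or cell sequences",
              call. = FALSE)
  cost <- build_cost_matrix(sequences[[1]]$mode, indel = indel)
  d <- pairwise_dissimilarity(sequences, cost)
  tree <- stats::hclust(stats::as.dist(d), method = method)
  k_rec <- select_k(tree, min_size = min_size)
  if (is.null(k)) k <- k_rec
  if (k < 1L || k > nrow(d)) stop("`k` out of range", call. = FALSE)
  labels <- stats::cutree(tree, k = k)
  structure(list(sequences = sequences, cost = cost, dissimilarity = d,
                 tree = tree, method = method, k = as.integer(k),
                 labels = labels, k_recommended = k_rec),
            class = "gsa")
}

#' Cut a GSA tree into k clusters
#'
#' @param object A [gsa()] fit.
#' @param k Number of clusters; defaults to the fit's `k`.
#' @return Named integer vector of cluster labels.
#' @export
clusters <- function(object, k = object$k) {
  stopifnot(inherits(object, "gsa"))
  stats::cutree(object$tree, k = k)
}

#' Recommend a cut level from a linkage tree
#'
#' Inspects the dendrogram branch lengths: for each candidate `k` whose
#' clusters all contain at least `min_size` members, the ratio of the
#' merge height that destroys the k-cluster solution to the height that
#' created it is computed; the `k` with the largest ratio is
#' recommended, or 1 when no ratio exceeds `threshold` (a homogeneous
#' cohort). Advisory only -- `k` stays user-settable in [gsa()].
#'
#' @param tree An [stats::hclust] object (or a [gsa()] fit).
#' @param min_size Minimum admissible cluster size.
#' @param k_max Largest `k` considered.
#' @param threshold Minimal height ratio regarded as a real gap.
#' @return Recommended number of clusters.
#' @export
select_k <- function(tree, min_size = 3, k_max = 8, threshold = 2) {
  if (inherits(tree, "gsa")) tree <- tree$tree
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (n < 3L) return(1L)
  h <- sort(tree$height)
  best_k <- 1L
  best_ratio <- -Inf
  for (k in 2:min(k_max, n - 1L)) {
    sizes <- tabulate(stats::cutree(tree, k = k))
    if (any(sizes < min_size)) next
    destroy <- h[n - k + 1L]   # merge that collapses k into k-1 clusters
    create <- h[n - k]         # last merge inside the k-cluster solution
    ratio <- if (create > 0) destroy / create else if (destroy > 0) Inf else NaN
    if (!is.nan(ratio) && ratio > best_ratio) {
      best_ratio <- ratio
      best_k <- k
    }
  }
  if (is.infinite(best_ratio) || (is.finite(best_ratio) && best_ratio >= threshold))
    best_k else 1L
}

#' @export
print.gsa <- function(x, ...) {
  cat(sprintf("Grid sequence analysis (%s mode): %d sequences, Ward (%s)\n",
              x$sequences[[1]]$mode, length(x$sequences), x$method))
  cat(sprintf("  indel %.2f, k = %d (recommended %d); cluster sizes: %s\n",
              x$cost$indel, x$k, x$k_recommended,
              paste(tabulate(x$labels), collapse = "/")))
  invisible(x)
}

#' @export
summary.gsa <- function(object, ...) {
  d <- object$dissimilarity
  out <- list(
    n = length(object$sequences),
    mode = object$sequences[[1]]$mode,
    method = object$method,
    k = object$k,
    k_recommended = object$k_recommended,
    sizes = tabulate(object$labels),
    dissimilarity_range = range(d[upper.tri(d)]),
    merge_heights = object$tree$height
  )
  class(out) <- "summary.gsa"
  out
}

#' @export
print.summary.gsa <- function(x, ...) {
  cat(sprintf("GSA: %d %s sequences, Ward (%s)\n", x$n, x$mode, x$method))
  cat(sprintf("  dissimilarity range: %.1f .. %.1f\n",
              x$dissimilarity_range[1], x$dissimilarity_range[2]))
  cat(sprintf("  k = %d (recommended %d), sizes %s\n", x$k, x$k_recommended,
              paste(x$sizes, collapse = "/")))
  cat("  top merge heights:",
      paste(round(utils::tail(sort(x$merge_heights), 4), 1), collapse = " "), "\n")
  invisible(x)
}

#' Plot a GSA dendrogram
#'
#' @param x A [gsa()] fit.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.gsa <- function(x, ...) {
  plot(x$tree, xlab = "", sub = sprintf("Ward (%s) on OM dissimilarities",
                                        x$method), ...)
  if (x$k > 1L) stats::rect.hclust(x$tree, k = x$k, border = "grey40")
  invisible(x)
}

#' Letter labels for grid cells
#'
#' Presentation helper reproducing an `a, b, c, ..., z, aa, ab, ...`
#' labelling of the active alphabet in row-major order. Cell identity in
#' the package is always the coordinate pair; labels are cosmetic.
#'
#' @param cost An [build_cost_matrix()] model.
#' @return Character vector of labels aligned with `cost$alphabet` rows.
#' @export
cell_letter_labels <- function(cost) {
  n <- nrow(cost$alphabet)
  single <- letters
  if (n <= 26L) return(single[seq_len(n)])
  extra <- as.vector(t(outer(letters, letters, paste0)))
  c(single, extra)[seq_len(n)]
}
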