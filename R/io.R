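# Readers and writers for the long-format trials CSV and the GSA
# artifacts. MISSING selections are encoded as empty fields.

trials_header <- c("dyad_id", "trial_index", "block_id", "is_fake",
                   "sel_a", "sel_b", "disp_a", "disp_b",
                   "outcome_a", "outcome_b", "payoff_a", "payoff_b")

#' Write trajectories to a long-format trials CSV
#'
#' One row per dyad and trial with the fixed header
#' `dyad_id,trial_index,block_id,is_fake,sel_a,sel_b,disp_a,disp_b,`
#' `outcome_a,outcome_b,payoff_a,payoff_b`; missing selections are
#' written as empty fields.
#'
#' @param trajectories List of [dyad_trajectory()].
#' @param path Output CSV path.
#' @export
write_trials <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr)
    cbind(data.frame(dyad_id = tr$dyad_id, stringsAsFactors = FALSE),
          tr$trials))
  df <- do.call(rbind, rows)[, trials_header]
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read trajectories from a trials CSV
#'
#' Parses and validates the long-format schema written by
#' [write_trials()]: required columns, exactly one row per
#' (dyad, trial index) with a complete 1..65 index, on-scale
#' selections, and the displayed-punishment invariants (the sibling's
#' true selection on interactive trials, the scripted level on fake
#' trials). Violations fail hard with row-level diagnostics.
#'
#' @param path Trials CSV path.
#' @param cfg An [itap_config()].
#' @param dyads_path Optional sidecar CSV (`dyad_id`, `true_type`,
#'   `gender`, `age_a`, `age_b`) supplying demographics.
#' @return List of [dyad_trajectory()] objects.
#' @export
read_trials <- function(path, cfg = itap_config(), dyads_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trials_header, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  sidecar <- NULL
  if (!is.null(dyads_path)) sidecar <- utils::read.csv(dyads_path,
                                                       stringsAsFactors = FALSE)
  nt <- n_trials(cfg)
  labs <- block_labels(cfg)
  fake_idx <- which(labs == "FAKE")
  out <- list()
  for (id in unique(df$dyad_id)) {
    d <- df[df$dyad_id == id, ]
    if (anyDuplicated(d$trial_index))
      stop(sprintf("dyad %s: duplicate trial_index %s", id,
                   paste(unique(d$trial_index[duplicated(d$trial_index)]),
                         collapse = ",")), call. = FALSE)
    miss <- setdiff(seq_len(nt), d$trial_index)
    if (length(miss))
      stop(sprintf("dyad %s: missing trial_index %s", id,
                   paste(miss, collapse = ",")), call. = FALSE)
    d <- d[order(d$trial_index), ]
    check_on_scale(d$sel_a, cfg, "a", d$trial_index)
    check_on_scale(d$sel_b, cfg, "b", d$trial_index)
    inter <- !d$is_fake
    bad_a <- inter & !is.na(d$sel_b) & (is.na(d$disp_a) | d$disp_a != d$sel_b)
    bad_b <- inter & !is.na(d$sel_a) & (is.na(d$disp_b) | d$disp_b != d$sel_a)
    if (any(bad_a | bad_b))
      stop(sprintf("dyad %s: displayed punishment != partner selection on interactive trial(s) %s",
                   id, paste(d$trial_index[bad_a | bad_b], collapse = ",")),
           call. = FALSE)
    if (any(d$disp_a[fake_idx] != cfg$fake_levels) ||
        any(d$disp_b[fake_idx] != cfg$fake_levels))
      stop(sprintf("dyad %s: fake-trial display does not match the script", id),
           call. = FALSE)
    gender <- NA_character_; ages <- c(NA_real_, NA_real_)
    if (!is.null(sidecar) && id %in% sidecar$dyad_id) {
      s <- sidecar[sidecar$dyad_id == id, ][1, ]
      if ("gender" %in% names(s)) gender <- s$gender
      if (all(c("age_a", "age_b") %in% names(s)))
        ages <- c(s$age_a, s$age_b)
    }
    trials <- d[, setdiff(trials_header, "dyad_id")]
    rownames(trials) <- NULL
    out[[id]] <- structure(list(dyad_id = id, gender = gender, ages = ages,
                                trials = trials, cfg = cfg),
                           class = "dyad_trajectory")
  }
  unname(out)
}

#' Write a dissimilarity matrix
#'
#' Square CSV with ids as header and first column.
#' @param d Symmetric matrix from [pairwise_dissimilarity()].
#' @param path Output path.
#' @export
write_dissimilarity <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a dissimilarity matrix written by [write_dissimilarity()]
#' @param path CSV path.
#' @return Symmetric numeric matrix with id dimnames.
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Export a linkage tree as a merge table
#'
#' One row per agglomeration step: `step`, `left`, `right` (negative =
#' singleton id index, positive = earlier step) and the merge `height`.
#' @param tree An [stats::hclust] object or [gsa()] fit.
#' @param path Output path.
#' @export
write_linkage <- function(tree, path) {
  if (inherits(tree, "gsa")) tree <- tree$tree
  df <- data.frame(step = seq_len(nrow(tree$merge)),
                   left = tree$merge[, 1], right = tree$merge[, 2],
                   height = tree$height)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cluster labels
#' @param labels Named integer labels.
#' @param path Output path.
#' @export
write_clusters <- function(labels, path) {
  utils::write.csv(data.frame(id = names(labels), label = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cluster labels written by [write_clusters()]
#' @param path CSV path.
#' @return Named integer vector.
#' @export
read_clusters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$label), df$id)
}
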