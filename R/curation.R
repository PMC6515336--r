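# Training-set curation: merge labeled sources with tier precedence and
# conflict removal, balance classes by Kennard-Stone selection over the
# negatives, and refine labels with the cross-validated voting filter.

#' Merge tier-1 and tier-2 sources with precedence and conflict removal
#'
#' Tier-1 records (authoritative sources) are kept verbatim, first occurrence
#' per structure key winning among same-label duplicates; conflicting labels
#' within tier 1 are an error. Tier-2 records whose key already appears in
#' tier 1 are discarded as duplicates; tier-2 keys carrying both labels are
#' removed entirely (status `rejected_conflict`); the remainder is unioned.
#'
#' @param tier1,tier2 standardized compound record data.frames (every active
#'   record needs a `canonical_key` and a positive/negative label).
#' @return list of class `curated_dataset`: `records` (merged; conflicted
#'   tier-2 rows carry status `rejected_conflict`), `provenance` (counts per
#'   tier), `merge_report` (duplicate/conflict accounting).
#' @export
merge_sources <- function(tier1, tier2) {
  tier1 <- validate_records(tier1); tier2 <- validate_records(tier2)
  a1 <- active_records(tier1); a2 <- active_records(tier2)
  for (nm in list(a1, a2)) {
    if (any(is.na(nm$canonical_key)))
      stop("all active records must be standardized (canonical_key set)")
    if (any(!nm$label %in% c("positive", "negative")))
      stop("records entering merging must be labeled positive/negative")
  }
  # tier 1: conflicting labels are fatal; same-label duplicates keep first
  lab_by_key <- split(a1$label, a1$canonical_key)
  conflict1 <- names(lab_by_key)[vapply(lab_by_key,
                                        function(l) length(unique(l)) > 1,
                                        logical(1))]
  if (length(conflict1)) {
    stop("conflicting labels within tier 1 for key(s): ",
         paste(conflict1, collapse = ", "))
  }
  keep1 <- a1[!duplicated(a1$canonical_key), , drop = FALSE]

  # tier 2: drop keys present in tier 1; remove keys with conflicting labels
  in1 <- a2$canonical_key %in% keep1$canonical_key
  a2r <- a2[!in1, , drop = FALSE]
  lab2 <- split(a2r$label, a2r$canonical_key)
  conflict2 <- names(lab2)[vapply(lab2, function(l) length(unique(l)) > 1,
                                  logical(1))]
  is_conf <- a2r$canonical_key %in% conflict2
  a2r$status[is_conf] <- "rejected_conflict"
  a2r$reason[is_conf] <- "conflicting labels across tier-2 sources"
  keep2 <- a2r[!is_conf, , drop = FALSE]
  keep2 <- keep2[!duplicated(keep2$canonical_key), , drop = FALSE]

  records <- rbind(keep1, keep2, a2r[is_conf, , drop = FALSE])
  structure(list(
    records = records,
    provenance = c(tier1 = nrow(keep1), tier2 = nrow(keep2)),
    merge_report = list(
      tier1_in = nrow(a1), tier1_kept = nrow(keep1),
      tier1_duplicates = nrow(a1) - nrow(keep1),
      tier2_in = nrow(a2),
      tier2_overridden_by_tier1 = sum(in1),
      tier2_conflicts_removed = sum(is_conf),
      tier2_kept = nrow(keep2)
    )
  ), class = "curated_dataset")
}

#' Kennard-Stone representative subset selection
#'
#' The classic deterministic max-min algorithm in z-scored Euclidean
#' descriptor space: seed with the pair at maximum distance, then repeatedly
#' add the candidate whose minimum distance to the already-selected set is
#' largest. Ties (equal distances) resolve to the lowest row index; the
#' seed-pair tie rule picks the lexicographically smallest index pair.
#'
#' @param matrix numeric matrix with rownames (compound ids); features are
#'   z-scored internally before distances (zero-variance columns ignored).
#' @param k number of points to select, `2 <= k <= n`.
#' @return character vector of the selected rownames, in selection order.
#' @export
kennard_stone_select <- function(matrix, k) {
  x <- as.matrix(matrix)
  n <- nrow(x)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n (k=", k, ", n=", n, ")")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sds <- apply(x, 2, stats::sd)
  use <- sds > 0
  z <- if (any(use)) scale(x[, use, drop = FALSE]) else
    matrix(0, n, 1)  # all rows identical: distances all zero, tie rule decides
  d <- as.matrix(stats::dist(z))
  # seed: maximum-distance pair, smallest (i, j) on ties
  up <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[up]
  best <- up[order(-dv, up[, 1], up[, 2])[1], ]
  selected <- c(best[1], best[2])
  mind <- pmin(d[, selected[1]], d[, selected[2]])
  while (length(selected) < k) {
    mind[selected] <- -Inf
    nxt <- which.max(mind)  # which.max takes the first (lowest index) on ties
    selected <- c(selected, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  ids[selected]
}

#' Balance classes by Kennard-Stone selection over the negatives
#'
#' All positives are kept; the negatives are reduced to `target_neg`
#' structurally representative compounds via [kennard_stone_select()] on the
#' negative-only descriptor rows. The excluded negatives are returned as a
#' reverse-validation hold-out pool, disjoint from the modeling set.
#'
#' @param records compound record data.frame (active, labeled).
#' @param matrix descriptor matrix whose rownames cover the active records.
#' @param target_neg number of negatives to retain.
#' @return list of class `curated_dataset`: `records` (balanced modeling
#'   set), `holdout_negatives` (excluded records), `selected_negative_ids`.
#'   If `target_neg >=` current negative count the call warns and keeps
#'   everything.
#' @export
balance_dataset <- function(records, matrix, target_neg) {
  records <- validate_records(records)
  act <- active_records(records)
  neg <- act[act$label == "negative", , drop = FALSE]
  if (target_neg >= nrow(neg)) {
    warning("target_neg (", target_neg, ") >= current negatives (",
            nrow(neg), "); nothing to balance")
    return(structure(list(records = records,
                          holdout_negatives = records[0, ],
                          selected_negative_ids = neg$compound_id),
                     class = "curated_dataset"))
  }
  miss <- setdiff(neg$compound_id, rownames(matrix))
  if (length(miss)) stop("descriptor rows missing for: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  sel <- kennard_stone_select(matrix[neg$compound_id, , drop = FALSE],
                              k = target_neg)
  keep <- act$label == "positive" |
    (act$label == "negative" & act$compound_id %in% sel)
  modeling <- act[keep, , drop = FALSE]
  holdout <- act[!keep, , drop = FALSE]
  structure(list(
    records = modeling,
    holdout_negatives = holdout,
    selected_negative_ids = sel
  ), class = "curated_dataset")
}

#' Cross-validated voting filter for probable mislabels
#'
#' Each of the eight classifiers is evaluated by stratified k-fold
#' cross-validation on the balanced set; a compound scores 1 per classifier
#' whose out-of-fold prediction matches its label, giving a vote score in
#' `[0, 8]`. Compounds scoring below `min_score` are flagged
#' `rejected_vote` and leave the modeling set.
#'
#' @param records active, labeled compound record data.frame.
#' @param matrix descriptor matrix (rownames = compound ids).
#' @param min_score minimum retained score (default 2: scores < 2 removed).
#' @param folds CV folds (default 10).
#' @param seed master seed shared by all eight classifiers' folds.
#' @param control learner settings, see [modeling_control()].
#' @return list of class `curated_dataset`: `records` (statuses updated),
#'   `vote_scores` (named integer vector), `removed_ids`, `cv` (the
#'   underlying `dili_cv`).
#' @export
vote_filter <- function(records, matrix, min_score = 2, folds = 10, seed = 1,
                        control = modeling_control()) {
  records <- validate_records(records)
  act <- active_records(records)
  stopifnot(all(act$label %in% c("positive", "negative")))
  x <- matrix[act$compound_id, , drop = FALSE]
  cv <- cross_validate(x, act$label, k = folds, seed = seed, control = control)
  pred_class <- cv$per_classifier_prob >= 0.5
  truth_pos <- cv$labels == "positive"
  correct <- pred_class == truth_pos  # recycles down columns
  scores <- as.integer(rowSums(correct))
  names(scores) <- rownames(x)
  removed <- names(scores)[scores < min_score]
  records$status[records$compound_id %in% removed] <- "rejected_vote"
  records$reason[records$compound_id %in% removed] <-
    sprintf("vote score %d < %d",
            scores[match(records$compound_id[records$compound_id %in% removed],
                         names(scores))], min_score)
  structure(list(
    records = records,
    vote_scores = scores,
    removed_ids = removed,
    cv = cv
  ), class = "curated_dataset")
}
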