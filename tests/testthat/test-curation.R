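make_rec <- function(ids, keys, labels, tier) {
  rec <- compound_records(ids, keys, labels, source_tier = tier)
  rec$canonical_key <- keys
  rec
}

test_that("merging keeps tier-1 labels over tier-2 and removes tier-2 conflicts", {
  t1 <- make_rec(c("a1", "a2"), c("K1", "K2"), c("positive", "negative"), "tier1")
  t2 <- make_rec(c("b1", "b2", "b3", "b4"),
                 c("K1", "K3", "K3", "K4"),
                 c("negative", "positive", "negative", "positive"), "tier2")
  m <- merge_sources(t1, t2)
  act <- active_records(m$records)
  # K1 resolved by tier-1 precedence: positive
  expect_equal(act$label[act$canonical_key == "K1"], "positive")
  expect_equal(sum(act$canonical_key == "K1"), 1)
  # K3 carries both labels within tier 2: removed entirely
  expect_false("K3" %in% act$canonical_key)
  expect_equal(sum(m$records$status == "rejected_conflict"), 2)
  # K4 unioned
  expect_true("K4" %in% act$canonical_key)
  expect_equal(unname(m$provenance), c(2, 1))
})

test_that("disjoint tiers union with additive counts", {
  t1 <- make_rec(c("a1", "a2"), c("K1", "K2"), c("positive", "negative"), "tier1")
  t2 <- make_rec(c("b1", "b2"), c("K3", "K4"), c("positive", "negative"), "tier2")
  m <- merge_sources(t1, t2)
  expect_equal(nrow(active_records(m$records)), 4)
})

test_that("conflicting labels within tier 1 fail loudly with the keys named", {
  t1 <- make_rec(c("a1", "a2"), c("K1", "K1"), c("positive", "negative"), "tier1")
  t2 <- make_rec("b1", "K9", "positive", "tier2")
  expect_error(merge_sources(t1, t2), "conflicting labels within tier 1.*K1")
})

test_that("Kennard-Stone picks the extreme pair on a 1-D line", {
  m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "x"))
  expect_setequal(kennard_stone_select(m, 2), c("a", "c"))
  expect_setequal(kennard_stone_select(m, 3), c("a", "b", "c"))
  expect_error(kennard_stone_select(m, 1), "k must satisfy")
  expect_error(kennard_stone_select(m, 4), "k must satisfy")
})

test_that("Kennard-Stone equals the exhaustive max-min oracle on all instances n <= 12", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:12, 1)
    p <- sample(1:4, 1)
    k <- sample(2:n, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("r%02d", 1:n), paste0("f", 1:p)))
    expect_equal(kennard_stone_select(x, k), ks_oracle(x, k),
                 info = sprintf("seed=%d n=%d p=%d k=%d", seed, n, p, k))
  }
})

test_that("Kennard-Stone selection is equivariant under row permutation", {
  set.seed(99)
  x <- matrix(rnorm(10 * 3), 10, 3,
              dimnames = list(sprintf("r%02d", 1:10), paste0("f", 1:3)))
  sel <- kennard_stone_select(x, 5)
  perm <- sample(10)
  sel_p <- kennard_stone_select(x[perm, ], 5)
  # continuous data: ties have probability zero, so the selection is
  # identical regardless of row order, up to the documented rule that the
  # two seed points are reported in row order
  expect_setequal(sel_p[1:2], sel[1:2])
  expect_equal(sel_p[-(1:2)], sel[-(1:2)])
})

test_that("duplicate rows (zero distances) are handled by the index tie rule", {
  x <- matrix(c(0, 0, 5, 5, 9), ncol = 1,
              dimnames = list(paste0("r", 1:5), "x"))
  sel <- kennard_stone_select(x, 4)
  expect_equal(length(sel), 4)
  expect_true(all(c("r1", "r5") %in% sel))
})

test_that("balancing keeps all positives, KS-selects negatives, and pools the rest", {
  set.seed(21)
  n_pos <- 10; n_neg <- 30
  mat <- rbind(matrix(rnorm(n_pos * 3, 2), n_pos, 3),
               matrix(rnorm(n_neg * 3), n_neg, 3))
  rownames(mat) <- sprintf("c%02d", 1:(n_pos + n_neg))
  colnames(mat) <- paste0("f", 1:3)
  labels <- c(rep("positive", n_pos), rep("negative", n_neg))
  rec <- matrix_records(mat, labels)
  bal <- balance_dataset(rec, mat, target_neg = 10)
  kept <- active_records(bal$records)
  expect_equal(sum(kept$label == "positive"), 10)
  expect_equal(sum(kept$label == "negative"), 10)
  expect_equal(nrow(bal$holdout_negatives), 20)
  # definitional: the retained negatives are exactly the KS selection
  neg_ids <- rec$compound_id[rec$label == "negative"]
  expect_setequal(bal$selected_negative_ids,
                  kennard_stone_select(mat[neg_ids, ], 10))
  # the hold-out pool and the modeling set are disjoint
  expect_length(intersect(bal$holdout_negatives$compound_id,
                          kept$compound_id), 0)
  expect_warning(balance_dataset(rec, mat, target_neg = 40), "nothing to balance")
})

test_that("vote filter removes exactly the compounds scoring below the threshold", {
  blobs <- make_blobs(n = 120, p = 4, delta = 4, seed = 5)
  rec <- matrix_records(blobs$x, blobs$y)
  vf <- vote_filter(rec, blobs$x, min_score = 2, folds = 10, seed = 3,
                    control = modeling_control("fast"))
  expect_true(all(vf$vote_scores >= 0 & vf$vote_scores <= 8))
  expect_setequal(vf$removed_ids, names(vf$vote_scores)[vf$vote_scores < 2])
  # strongly separated classes: every learner is near-perfect, nothing removed
  expect_length(vf$removed_ids, 0)
  # monotone in min_score: a stricter threshold removes a superset
  vf5 <- vote_filter(rec, blobs$x, min_score = 5, folds = 10, seed = 3,
                     control = modeling_control("fast"))
  expect_true(all(vf$removed_ids %in% vf5$removed_ids))
})

test_that("planted label noise earns lower vote scores than clean compounds", {
  dat <- generate_synthetic_dataset(synthetic_spec(
    n = 300, n_features = 12, signal = 2, label_noise = 0.05, seed = 11))
  rec <- matrix_records(dat$matrix, dat$labels)
  vf <- vote_filter(rec, dat$matrix, min_score = 2, folds = 10, seed = 7,
                    control = modeling_control("fast"))
  flipped <- names(vf$vote_scores) %in% dat$truth$flipped_ids
  expect_gt(sum(flipped), 0)
  expect_lt(mean(vf$vote_scores[flipped]), mean(vf$vote_scores[!flipped]))
})
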