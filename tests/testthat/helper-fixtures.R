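# Shared fixtures and independent oracles used across the test files.

# two Gaussian blobs separated by `delta` SDs on every feature
make_blobs <- function(n = 100, p = 2, delta = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              paste0("f", seq_len(p))))
  y <- rep(c("positive", "negative"), length.out = n)
  x[y == "positive", ] <- x[y == "positive", ] + delta
  list(x = x, y = y)
}

# independent max-min (Kennard-Stone) oracle: plain loops, no shared code
# with the implementation beyond base R distance arithmetic
ks_oracle <- function(x, k) {
  x <- as.matrix(x)
  ids <- rownames(x)
  sds <- apply(x, 2, sd)
  z <- x[, sds > 0, drop = FALSE]
  if (ncol(z) == 0) z <- matrix(0, nrow(x), 1) else z <- scale(z)
  n <- nrow(z)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((z[i, ] - z[j, ])^2))
  }
  best <- c(NA, NA); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand_best <- NA; cand_d <- -Inf
    for (c in seq_len(n)) {
      if (c %in% sel) next
      mind <- min(d[c, sel])
      if (mind > cand_d) { cand_d <- mind; cand_best <- c }
    }
    sel <- c(sel, cand_best)
  }
  ids[sel]
}

# pairwise-counting AUC oracle (ties get half credit)
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == "positive"]; neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# labeled records wrapper for descriptor-matrix datasets
matrix_records <- function(mat, labels) {
  rec <- compound_records(rownames(mat), "*", labels)
  rec$canonical_key <- rec$compound_id
  rec
}
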