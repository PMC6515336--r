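# Unsupervised feature filters applied before modeling: near-constant
# columns (modal value frequency above a threshold) and pairwise Pearson
# redundancy (greedy scan in canonical column order, later column dropped).

#' Remove near-constant features
#'
#' A feature is removed iff the relative frequency of its most common value
#' is strictly greater than `threshold`; a column at exactly the threshold is
#' retained.
#'
#' @param matrix numeric matrix (rows = compounds, named columns = features).
#' @param threshold modal-frequency cutoff in `(0, 1]`, default 0.95.
#' @return list with `matrix` (filtered) and `report` containing
#'   `removed_near_constant` (names with their modal frequencies) and
#'   `retained`.
#' @export
remove_near_constant <- function(matrix, threshold = 0.95) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  modal_freq <- apply(matrix, 2, function(col) max(table(col)) / length(col))
  drop <- modal_freq > threshold
  list(
    matrix = matrix[, !drop, drop = FALSE],
    report = list(
      removed_near_constant = stats::setNames(modal_freq[drop],
                                              colnames(matrix)[drop]),
      retained = colnames(matrix)[!drop],
      threshold = threshold
    )
  )
}

#' Remove highly correlated features
#'
#' Deterministic greedy scan in the fixed column order: every unordered pair
#' with `|Pearson r| > cutoff` drops the later-ordered feature (the earlier
#' column in the canonical descriptor order is kept). Re-running on the
#' output is a no-op.
#'
#' @param matrix numeric matrix after the near-constant pass; zero-variance
#'   columns are an error (they must have been removed upstream).
#' @param cutoff absolute Pearson correlation cutoff, default 0.95 (strict
#'   inequality: `|r|` exactly at the cutoff is retained).
#' @return list with `matrix` and `report` containing `removed_correlated`
#'   (data.frame dropped / kept_partner / r) and `retained`.
#' @export
remove_correlated <- function(matrix, cutoff = 0.95) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1)
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(matrix)[sds == 0], collapse = ", "),
         " (run remove_near_constant() first)")
  }
  r <- stats::cor(matrix)
  p <- ncol(matrix)
  keep <- rep(TRUE, p)
  dropped <- kept_partner <- character(0)
  rvals <- numeric(0)
  for (i in seq_len(p - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):p) {
      if (!keep[j]) next
      if (abs(r[i, j]) > cutoff) {
        keep[j] <- FALSE
        dropped <- c(dropped, colnames(matrix)[j])
        kept_partner <- c(kept_partner, colnames(matrix)[i])
        rvals <- c(rvals, r[i, j])
      }
    }
  }
  list(
    matrix = matrix[, keep, drop = FALSE],
    report = list(
      removed_correlated = data.frame(
        dropped = dropped, kept_partner = kept_partner, r = rvals,
        stringsAsFactors = FALSE),
      retained = colnames(matrix)[keep],
      cutoff = cutoff
    )
  )
}

#' Run both feature filters
#'
#' @param matrix descriptor matrix.
#' @param near_constant_threshold,correlation_cutoff filter parameters
#'   (defaults 0.95 / 0.95).
#' @return list with `matrix` and a combined `report` whose `retained` and
#'   removed sets partition the input feature names.
#' @export
select_features <- function(matrix, near_constant_threshold = 0.95,
                            correlation_cutoff = 0.95) {
  s1 <- remove_near_constant(matrix, near_constant_threshold)
  s2 <- remove_correlated(s1$matrix, correlation_cutoff)
  report <- list(
    removed_near_constant = s1$report$removed_near_constant,
    removed_correlated = s2$report$removed_correlated,
    retained = s2$report$retained,
    input_features = colnames(matrix)
  )
  stopifnot(setequal(
    c(names(report$removed_near_constant),
      report$removed_correlated$dropped, report$retained),
    colnames(matrix)))
  list(matrix = s2$matrix, report = report)
}
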