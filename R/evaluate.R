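# Performance evaluation: confusion-matrix metrics (ACC, SE, SP, BACC),
# ROC/AUC, reconstruction of confusion counts from published SE/SP, and the
# Y-randomization (label-scrambling) chance-level test.

#' Metrics from confusion counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `BACC = (SE+SP)/2`. When a class is empty the affected metric is `NA` and
#' the others are still computed.
#'
#' @param TP,FN,TN,FP non-negative integer counts.
#' @return list of class `eval_metrics` with the four counts and `ACC`,
#'   `SE`, `SP`, `BACC`.
#' @export
metrics_from_confusion <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- sum(counts)
  se <- if (TP + FN >= 1) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP >= 1) TN / (TN + FP) else NA_real_
  structure(list(
    TP = TP, FN = FN, TN = TN, FP = FP,
    ACC = if (n >= 1) (TP + TN) / n else NA_real_,
    SE = se, SP = sp,
    BACC = (se + sp) / 2
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("confusion: TP=%d FN=%d TN=%d FP=%d\n", x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("ACC=%.*f  SE=%.*f  SP=%.*f  BACC=%.*f\n",
              digits, x$ACC, digits, x$SE, digits, x$SP, digits, x$BACC))
  invisible(x)
}

#' Metrics of predicted vs true labels
#'
#' @param truth,predicted label vectors (`"positive"`/`"negative"`).
#' @return `eval_metrics`.
#' @export
metrics_from_labels <- function(truth, predicted) {
  truth <- as_class_factor(truth); predicted <- as_class_factor(predicted)
  stopifnot(length(truth) == length(predicted))
  metrics_from_confusion(
    TP = sum(truth == "positive" & predicted == "positive"),
    FN = sum(truth == "positive" & predicted == "negative"),
    TN = sum(truth == "negative" & predicted == "negative"),
    FP = sum(truth == "negative" & predicted == "positive")
  )
}

#' Reconstruct confusion counts from published class sizes and SE/SP
#'
#' `TP = round(SE * n_pos)`, `TN = round(SP * n_neg)`, complements for
#' FN/FP. Used to recover the integer confusion matrix behind printed
#' comparison tables. Warns when the printed rate is not consistent with an
#' integer count.
#'
#' @param n_pos,n_neg class sizes.
#' @param se,sp printed sensitivity and specificity in `[0, 1]`.
#' @return list with `TP`, `FN`, `TN`, `FP` and the derived `eval_metrics`
#'   as `$metrics`.
#' @export
reconstruct_confusion <- function(n_pos, n_neg, se, sp) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1, n_pos >= 0, n_neg >= 0)
  TP <- round(se * n_pos); TN <- round(sp * n_neg)
  if (abs(TP - se * n_pos) > 0.5 + 1e-9 || abs(TN - sp * n_neg) > 0.5 + 1e-9) {
    warning("printed rates are inconsistent with integer counts")
  }
  res <- list(TP = TP, FN = n_pos - TP, TN = TN, FP = n_neg - TN)
  res$metrics <- metrics_from_confusion(res$TP, res$FN, res$TN, res$FP)
  res
}

#' ROC curve and AUC
#'
#' The AUC is computed two ways and must agree to 1e-9: (i) the rank (Mann-
#' Whitney) formulation, the fraction of (positive, negative) pairs where the
#' positive scores higher, ties counted 0.5; (ii) the trapezoidal area under
#' the threshold-sweep curve. The curve runs from (0,0) to (1,1) with
#' monotone FPR/TPR.
#'
#' @param labels binary labels (`"positive"`/`"negative"`), both present.
#' @param scores finite numeric scores, higher = more positive.
#' @return `roc_curve` object: `thresholds`, `FPR`, `TPR`, `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as_class_factor(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  pos <- scores[labels == "positive"]; neg <- scores[labels == "negative"]
  if (!length(pos) || !length(neg)) stop("both classes required for ROC analysis")
  # rank formulation via midranks (equivalent to pairwise counting w/ ties=0.5)
  r <- rank(scores, ties.method = "average")
  auc_rank <- (sum(r[labels == "positive"]) -
                 length(pos) * (length(pos) + 1) / 2) /
    (as.numeric(length(pos)) * length(neg))
  # threshold sweep
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  auc_sweep <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (abs(auc_rank - auc_sweep) > 1e-9) {
    stop("internal AUC cross-check failed: ", auc_rank, " vs ", auc_sweep)
  }
  structure(list(thresholds = thr, FPR = fpr, TPR = tpr, auc = auc_rank),
            class = "roc_curve")
}

#' Metrics of a cross-validation result
#'
#' Pooled out-of-fold metrics: confusion counts over all compounds plus the
#' AUC of the ensemble probabilities.
#'
#' @param cv `dili_cv` from [cross_validate()].
#' @return `eval_metrics` with an extra `AUC` element.
#' @export
cv_metrics <- function(cv) {
  stopifnot(inherits(cv, "dili_cv"))
  m <- metrics_from_labels(cv$labels, cv$predicted_label)
  m$AUC <- roc_auc(cv$labels, cv$ensemble_prob)$auc
  m
}

#' Per-classifier out-of-fold metrics of a cross-validation result
#'
#' @param cv `dili_cv`.
#' @return data.frame with one row per classifier plus the ensemble row,
#'   columns SE, SP, ACC, BACC, AUC.
#' @export
cv_metrics_table <- function(cv) {
  stopifnot(inherits(cv, "dili_cv"))
  probs <- cbind(cv$per_classifier_prob, ensemble = cv$ensemble_prob)
  rows <- lapply(colnames(probs), function(cl) {
    pred <- ifelse(probs[, cl] >= 0.5, "positive", "negative")
    m <- metrics_from_labels(cv$labels, pred)
    data.frame(classifier = cl, SE = m$SE, SP = m$SP, ACC = m$ACC,
               BACC = m$BACC, AUC = roc_auc(cv$labels, probs[, cl])$auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Y-randomization (label-scrambling) test
#'
#' Permutes the labels (class counts preserved by construction), reruns the
#' full stratified k-fold cross-validated eight-classifier ensemble, and
#' records the pooled metrics of each run. A sound pipeline scores at chance
#' (ACC about 0.5 on balanced data) on every permuted run.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param runs number of permutation runs (default 100).
#' @param seed master seed; permutations and CV seeds are derived from it.
#' @param k CV folds.
#' @param control learner settings; the `"fast"` profile is the intended
#'   choice for 100-run experiments.
#' @return list of class `yrand_result`: `runs` data.frame (per-run ACC, SE,
#'   SP, BACC, AUC) and `summary` (mean and sd per metric).
#' @export
y_randomization <- function(x, y, runs = 100, seed = 1, k = 10,
                            control = modeling_control("fast")) {
  if (runs < 1) stop("runs must be >= 1")
  x <- as.matrix(x)
  y <- as_class_factor(y)
  res <- vector("list", runs)
  for (r in seq_len(runs)) {
    yperm <- with_seed(seed * 1000L + r, sample(y))
    stopifnot(identical(as.vector(table(yperm)), as.vector(table(y))))
    cv <- cross_validate(x, yperm, k = k, seed = seed * 1000L + r,
                         control = control)
    m <- cv_metrics(cv)
    res[[r]] <- data.frame(run = r, ACC = m$ACC, SE = m$SE, SP = m$SP,
                           BACC = m$BACC, AUC = m$AUC)
  }
  runs_df <- do.call(rbind, res)
  metrics <- c("ACC", "SE", "SP", "BACC", "AUC")
  structure(list(
    runs = runs_df,
    summary = data.frame(
      metric = metrics,
      mean = vapply(metrics, function(mm) mean(runs_df[[mm]]), numeric(1)),
      sd = vapply(metrics, function(mm) stats::sd(runs_df[[mm]]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  ), class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat("Y-randomization over", nrow(x$runs), "label permutations\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
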