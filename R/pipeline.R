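# End-to-end orchestration: standardize -> descriptors -> merge -> feature
# selection -> Kennard-Stone balancing -> voting filter -> cross-validated
# ensemble -> evaluation (+ optional Y-randomization), with a manifest that
# conserves record counts across stages.

#' Pipeline configuration
#'
#' Defaults equal the reference workflow settings: 0.95 near-constant and
#' correlation thresholds, vote threshold 2, 10-fold CV, 100 Y-randomization
#' runs. The master seed fans out to per-stage seeds as
#' `seed * 10 + offset` (1 = voting filter, 2 = cross-validation,
#' 3 = Y-randomization), so stages are reproducible independently.
#'
#' @param near_constant_threshold,correlation_cutoff feature-filter settings.
#' @param vote_min_score voting-filter threshold (scores below it removed).
#' @param cv_folds folds for both the voting filter and final evaluation.
#' @param yrand_runs Y-randomization runs when requested.
#' @param target_neg negatives retained at balancing; `NULL` balances to the
#'   positive count.
#' @param min_carbons,max_mw admission bounds for standardization.
#' @param seed master seed.
#' @param control [modeling_control()] settings for every learner stage.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(near_constant_threshold = 0.95,
                            correlation_cutoff = 0.95,
                            vote_min_score = 2,
                            cv_folds = 10,
                            yrand_runs = 100,
                            target_neg = NULL,
                            min_carbons = 4,
                            max_mw = 900,
                            seed = 1,
                            control = modeling_control()) {
  structure(list(
    near_constant_threshold = near_constant_threshold,
    correlation_cutoff = correlation_cutoff,
    vote_min_score = vote_min_score,
    cv_folds = cv_folds,
    yrand_runs = yrand_runs,
    target_neg = target_neg,
    min_carbons = min_carbons,
    max_mw = max_mw,
    seed = seed,
    control = control
  ), class = "pipeline_config")
}

#' Run the full modeling workflow
#'
#' Two entry modes. Records mode: a compound record table (tiers taken from
#' `source_tier`) is standardized, descriptors are computed, tiers are
#' merged with precedence. Matrix mode: a ready descriptor matrix plus
#' labels (e.g. from [generate_synthetic_dataset()]) skips the chemistry.
#' Both then share feature selection, optional Kennard-Stone balancing, the
#' voting filter, cross-validated ensemble evaluation and optional
#' Y-randomization. Every stage appends counts to the manifest;
#' records in = records out + records rejected holds at each stage.
#'
#' @param records compound record data.frame (records mode) or `NULL`.
#' @param descriptor_matrix,labels matrix mode inputs (rownames = ids).
#' @param config [pipeline_config()].
#' @param balance balance classes before the voting filter (default TRUE
#'   when negatives exceed the target).
#' @param y_randomize also run the Y-randomization test (slow).
#' @param out_dir optional directory; stage reports, metrics and the
#'   manifest are written there as JSON/CSV.
#' @return `dili_pipeline_result` list: `records`, `matrix` (retained
#'   features), `feature_report`, `vote`, `cv`, `metrics`, `metrics_table`,
#'   `yrand` (or NULL), `manifest`.
#' @export
run_pipeline <- function(records = NULL, descriptor_matrix = NULL,
                         labels = NULL, config = pipeline_config(),
                         balance = TRUE, y_randomize = FALSE,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(name, n_in, n_out, n_rejected) {
    stopifnot(n_in == n_out + n_rejected)
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out,
                                     n_rejected = n_rejected)
  }

  if (!is.null(records)) {
    records <- validate_records(records)
    n0 <- nrow(records)
    std <- standardize_dataset(records, min_carbons = config$min_carbons,
                               max_mw = config$max_mw)
    records <- std$records
    act <- active_records(records)
    log_stage("standardize", n0, nrow(act), n0 - nrow(act))

    desc <- compute_descriptors(act)
    failed <- attr(desc, "failed_ids")
    records$status[records$compound_id %in% failed] <- "rejected_structure"
    records$reason[records$compound_id %in% failed] <- "descriptor failure"
    act <- active_records(records)
    log_stage("descriptors", nrow(act) + length(failed), nrow(act),
              length(failed))

    t1 <- act[act$source_tier == "tier1", , drop = FALSE]
    t2 <- act[act$source_tier == "tier2", , drop = FALSE]
    merged <- merge_sources(t1, t2)
    mrecords <- active_records(merged$records)
    log_stage("merge", nrow(act), nrow(mrecords), nrow(act) - nrow(mrecords))
    labels <- stats::setNames(mrecords$label, mrecords$compound_id)
    descriptor_matrix <- desc[mrecords$compound_id, , drop = FALSE]
    records_out <- merged$records
  } else {
    if (is.null(descriptor_matrix) || is.null(labels)) {
      stop("provide either records or descriptor_matrix + labels")
    }
    descriptor_matrix <- as.matrix(descriptor_matrix)
    if (is.null(rownames(descriptor_matrix)))
      rownames(descriptor_matrix) <- sprintf("cmpd%04d",
                                             seq_len(nrow(descriptor_matrix)))
    labels <- stats::setNames(as.character(labels), rownames(descriptor_matrix))
    records_out <- compound_records(rownames(descriptor_matrix),
                                    smiles = rep("*", nrow(descriptor_matrix)),
                                    label = labels)
    records_out$canonical_key <- records_out$compound_id
    log_stage("input", nrow(descriptor_matrix), nrow(descriptor_matrix), 0)
  }

  sel <- select_features(descriptor_matrix,
                         near_constant_threshold = config$near_constant_threshold,
                         correlation_cutoff = config$correlation_cutoff)
  x <- sel$matrix
  log_stage("feature_select", nrow(x), nrow(x), 0)

  holdout <- NULL
  y <- labels[rownames(x)]
  n_pos <- sum(y == "positive"); n_neg <- sum(y == "negative")
  target <- config$target_neg
  if (is.null(target)) target <- n_pos
  if (balance && n_neg > target) {
    bal <- balance_dataset(records_out, x, target_neg = target)
    keep_ids <- active_records(bal$records)$compound_id
    holdout <- bal$holdout_negatives
    x <- x[keep_ids, , drop = FALSE]
    y <- y[keep_ids]
    log_stage("balance", length(labels[rownames(sel$matrix)]),
              nrow(x), nrow(holdout))
    records_out <- bal$records
  } else {
    log_stage("balance", nrow(x), nrow(x), 0)
  }

  vote <- vote_filter(records_out, x, min_score = config$vote_min_score,
                      folds = config$cv_folds, seed = config$seed * 10L + 1L,
                      control = config$control)
  records_out <- vote$records
  keep_ids <- intersect(rownames(x), active_records(records_out)$compound_id)
  log_stage("vote_filter", nrow(x), length(keep_ids),
            nrow(x) - length(keep_ids))
  x <- x[keep_ids, , drop = FALSE]
  y <- y[keep_ids]
  if (!length(keep_ids)) stop("voting filter emptied the modeling set; ",
                              "lower vote_min_score")

  cv <- cross_validate(x, y, k = config$cv_folds,
                       seed = config$seed * 10L + 2L, control = config$control)
  metrics <- cv_metrics(cv)
  mtable <- cv_metrics_table(cv)
  log_stage("cross_validate", nrow(x), nrow(x), 0)

  yrand <- NULL
  if (y_randomize) {
    yrand <- y_randomization(x, y, runs = config$yrand_runs,
                             seed = config$seed * 10L + 3L,
                             k = config$cv_folds,
                             control = modeling_control("fast"))
  }

  result <- structure(list(
    records = records_out,
    matrix = x,
    labels = y,
    feature_report = sel$report,
    holdout_negatives = holdout,
    vote = vote,
    cv = cv,
    metrics = metrics,
    metrics_table = mtable,
    yrand = yrand,
    manifest = manifest,
    config = config
  ), class = "dili_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  m <- result$metrics
  jsonlite::write_json(
    list(TP = m$TP, FN = m$FN, TN = m$TN, FP = m$FP, ACC = m$ACC, SE = m$SE,
         SP = m$SP, BACC = m$BACC, AUC = m$AUC),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$metrics_table,
                   file.path(out_dir, "metrics_by_classifier.csv"),
                   row.names = FALSE)
  votes <- data.frame(compound_id = names(result$vote$vote_scores),
                      score = as.integer(result$vote$vote_scores),
                      kept = !names(result$vote$vote_scores) %in%
                        result$vote$removed_ids)
  utils::write.csv(votes, file.path(out_dir, "vote_scores.csv"),
                   row.names = FALSE)
  roc <- roc_auc(result$cv$labels, result$cv$ensemble_prob)
  utils::write.csv(data.frame(threshold = roc$thresholds, FPR = roc$FPR,
                              TPR = roc$TPR),
                   file.path(out_dir, "roc_points.csv"), row.names = FALSE)
  if (!is.null(result$yrand)) {
    utils::write.csv(result$yrand$runs, file.path(out_dir, "yrand_runs.csv"),
                     row.names = FALSE)
  }
  write_dataset(result$records[, RECORD_COLUMNS],
                file.path(out_dir, "records.csv"))
  invisible(out_dir)
}

#' @export
print.dili_pipeline_result <- function(x, ...) {
  cat("DILI QSAR pipeline result\n")
  for (nm in names(x$manifest$stages)) {
    s <- x$manifest$stages[[nm]]
    cat(sprintf("  %-15s in=%4d out=%4d rejected=%3d\n", nm, s$n_in,
                s$n_out, s$n_rejected))
  }
  cat(sprintf("ensemble 10-fold CV: ACC=%.3f SE=%.3f SP=%.3f BACC=%.3f AUC=%.3f\n",
              x$metrics$ACC, x$metrics$SE, x$metrics$SP, x$metrics$BACC,
              x$metrics$AUC))
  invisible(x)
}
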