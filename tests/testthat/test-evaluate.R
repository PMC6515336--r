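test_that("metric identities hold to 1e-12 on 10^4 random confusion tables", {
  set.seed(1)
  for (i in 1:10000) {
    counts <- rmultinom(1, sample(20:400, 1), prob = runif(4, 0.05, 1))[, 1]
    if (counts[1] + counts[2] == 0 || counts[3] + counts[4] == 0) next
    m <- metrics_from_confusion(counts[1], counts[2], counts[3], counts[4])
    expect_equal(m$ACC, (m$TP + m$TN) / sum(counts), tolerance = 1e-12)
    expect_equal(m$SE, m$TP / (m$TP + m$FN), tolerance = 1e-12)
    expect_equal(m$SP, m$TN / (m$TN + m$FP), tolerance = 1e-12)
    expect_equal(m$BACC, (m$SE + m$SP) / 2, tolerance = 1e-12)
  }
})

test_that("published-style confusion tables give the printed metrics", {
  # 85-compound test set with 58 positives / 27 negatives
  m <- metrics_from_confusion(TP = 41, FN = 17, TN = 22, FP = 5)
  expect_equal(round(m$SE, 3), 0.707)
  expect_equal(round(m$SP, 3), 0.815)
  expect_equal(round(m$ACC, 3), 0.741)
  expect_equal(round(m$BACC, 3), 0.761)

  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(perfect$ACC, 1); expect_equal(perfect$BACC, 1)

  # SE == SP forces BACC to the common value
  m2 <- metrics_from_confusion(30, 10, 60, 20)
  expect_equal(m2$SE, m2$SP)
  expect_equal(m2$BACC, m2$SE)

  # empty class: the affected metric is NA, others still computed
  m3 <- metrics_from_confusion(0, 0, 8, 2)
  expect_true(is.na(m3$SE))
  expect_equal(m3$SP, 0.8)
})

test_that("confusion reconstruction from printed class sizes and rates", {
  r1 <- reconstruct_confusion(66, 17, 0.879, 0.647)
  expect_equal(r1$TP, 58); expect_equal(r1$TN, 11)
  r2 <- reconstruct_confusion(28, 39, 0.786, 0.590)
  expect_equal(r2$TP, 22); expect_equal(r2$TN, 23)
  expect_equal(r2$metrics$ACC, 45 / 67)
  r3 <- reconstruct_confusion(12, 9, 1, 1)
  expect_equal(unlist(r3[c("TP", "FN", "TN", "FP")]),
               c(TP = 12, FN = 0, TN = 9, FP = 0))
})

test_that("AUC equals the exhaustive pair-count oracle, ties included", {
  labels <- c("positive", "positive", "negative", "positive",
              "negative", "negative")
  scores <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)   # one cross-class tie
  r <- roc_auc(labels, scores)
  expect_equal(r$auc, auc_oracle(labels, scores))
  # curve geometry: starts at (0,0), ends at (1,1), monotone
  expect_equal(r$FPR[1], 0); expect_equal(r$TPR[1], 0)
  expect_equal(r$FPR[length(r$FPR)], 1)
  expect_equal(r$TPR[length(r$TPR)], 1)
  expect_true(all(diff(r$FPR) >= 0) && all(diff(r$TPR) >= 0))
})

test_that("AUC identities: separation, complement, and label swap", {
  set.seed(2)
  labels <- rep(c("positive", "negative"), each = 30)
  sep <- c(runif(30, 0.7, 1), runif(30, 0, 0.3))
  expect_equal(roc_auc(labels, sep)$auc, 1)

  scores <- rnorm(60)  # tie-free almost surely
  a <- roc_auc(labels, scores)$auc
  expect_equal(roc_auc(labels, -scores)$auc, 1 - a, tolerance = 1e-12)
  swapped <- ifelse(labels == "positive", "negative", "positive")
  expect_equal(roc_auc(swapped, scores)$auc, 1 - a, tolerance = 1e-12)
  expect_error(roc_auc(rep("positive", 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:5) {
    labels <- sample(rep(c("positive", "negative"), times = c(40, 35)))
    scores <- round(rnorm(75), 1)   # force ties
    ours <- roc_auc(labels, scores)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("negative", "positive"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("label swap exchanges SE and SP exactly", {
  set.seed(4)
  truth <- sample(rep(c("positive", "negative"), times = c(45, 55)))
  pred <- sample(rep(c("positive", "negative"), times = c(50, 50)))
  m <- metrics_from_labels(truth, pred)
  swap <- function(z) ifelse(z == "positive", "negative", "positive")
  ms <- metrics_from_labels(swap(truth), swap(pred))
  expect_equal(ms$SE, m$SP)
  expect_equal(ms$SP, m$SE)
  expect_equal(ms$ACC, m$ACC)
})

test_that("Y-randomization preserves class counts and is reproducible", {
  blobs <- make_blobs(n = 60, p = 3, delta = 2, seed = 5)
  yr1 <- y_randomization(blobs$x, blobs$y, runs = 3, seed = 6, k = 5,
                         control = modeling_control("fast"))
  yr2 <- y_randomization(blobs$x, blobs$y, runs = 3, seed = 6, k = 5,
                         control = modeling_control("fast"))
  expect_identical(yr1$runs, yr2$runs)
  expect_equal(nrow(yr1$runs), 3)
  # permuted-label performance sits near chance even though the original
  # data are strongly separable
  expect_lt(abs(mean(yr1$runs$ACC) - 0.5), 0.25)
  expect_error(y_randomization(blobs$x, blobs$y, runs = 0), "runs")
})
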