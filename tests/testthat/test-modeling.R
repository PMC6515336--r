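test_that("every learner separates well-separated blobs at resubstitution", {
  blobs <- make_blobs(n = 100, p = 2, delta = 3, seed = 1)
  em <- train_base_classifiers(blobs$x, blobs$y, seed = 7)
  expect_length(em$learners, 8)
  expect_named(em$learners, diliqsar:::CLASSIFIER_ROLES)
  all_pred <- predict(em, blobs$x, type = "all")
  acc <- apply(all_pred$per_classifier, 2, function(p)
    mean((p >= 0.5) == (blobs$y == "positive")))
  for (role in names(acc)) {
    expect_gte(acc[[role]], 0.95)
  }
  expect_true(all(all_pred$per_classifier >= 0 & all_pred$per_classifier <= 1))
})

test_that("training on a single class is fatal", {
  blobs <- make_blobs(n = 20, seed = 2)
  expect_error(train_base_classifiers(blobs$x, rep("positive", 20)),
               "single class")
})

test_that("ensemble averaging is the unweighted mean of exactly 8 probabilities", {
  expect_equal(ensemble_average(rep(0.7, 8)), 0.7)
  expect_equal(ensemble_average(c(1, 0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_error(ensemble_average(rep(0.5, 7)), "exactly 8")
  expect_error(ensemble_average(rep(1.5, 8)))
  # mean boundedness: ensemble prob within [min, max] of its inputs
  set.seed(3)
  for (i in 1:20) {
    p <- runif(8)
    m <- ensemble_average(p)
    expect_gte(m, min(p)); expect_lte(m, max(p))
  }
})

test_that("stratified folds have per-class sizes differing by at most one", {
  blobs <- make_blobs(n = 100, p = 2, delta = 1, seed = 4)
  cv <- cross_validate(blobs$x, blobs$y, k = 10, seed = 5,
                       control = modeling_control("fast"))
  tab <- table(cv$fold_assignment, cv$labels)
  expect_true(all(tab == 5))  # 50/50 classes over 10 folds
  expect_equal(sort(unique(cv$fold_assignment)), 1:10)
  expect_equal(unname(cv$ensemble_prob),
               unname(rowMeans(cv$per_classifier_prob)))
})

test_that("cross-validation is deterministic under a fixed seed", {
  blobs <- make_blobs(n = 80, p = 3, delta = 1, seed = 6)
  cv1 <- cross_validate(blobs$x, blobs$y, k = 5, seed = 11,
                        control = modeling_control("fast"))
  cv2 <- cross_validate(blobs$x, blobs$y, k = 5, seed = 11,
                        control = modeling_control("fast"))
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$per_classifier_prob, cv2$per_classifier_prob)
  cv3 <- cross_validate(blobs$x, blobs$y, k = 5, seed = 12,
                        control = modeling_control("fast"))
  expect_false(identical(cv1$per_classifier_prob, cv3$per_classifier_prob))
})

test_that("refitting the ensemble with the same seed reproduces predictions", {
  blobs <- make_blobs(n = 60, p = 3, delta = 2, seed = 8)
  em1 <- train_base_classifiers(blobs$x, blobs$y, seed = 9,
                                control = modeling_control("fast"))
  em2 <- train_base_classifiers(blobs$x, blobs$y, seed = 9,
                                control = modeling_control("fast"))
  expect_identical(predict(em1, blobs$x), predict(em2, blobs$x))
})

test_that("label-permuted data scores at chance within binomial error", {
  set.seed(13)
  blobs <- make_blobs(n = 200, p = 5, delta = 2, seed = 13)
  yperm <- sample(blobs$y)
  cv <- cross_validate(blobs$x, yperm, k = 10, seed = 14,
                       control = modeling_control("fast"))
  m <- cv_metrics(cv)
  expect_lt(abs(m$ACC - 0.5), 3 * sqrt(0.25 / 200) + 0.02)
})

test_that("n < k and missing-value inputs are fatal", {
  blobs <- make_blobs(n = 8, seed = 15)
  expect_error(cross_validate(blobs$x, blobs$y, k = 10), "n < k")
  xx <- blobs$x; xx[1, 1] <- NA
  expect_error(train_base_classifiers(xx, blobs$y), "missing values")
})
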