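# The eight base classifiers and the probability-averaging (soft-voting)
# ensemble. The roster mirrors a WEKA 3.8 default bench: Gaussian naive
# Bayes, 1-nearest-neighbor, an entropic-instance-learner surrogate
# (distance-weighted neighbors, standing in for Kstar), AdaBoost.M1 on
# decision stumps (10 iterations), bagged trees (10 bootstrap replicates),
# a single CART tree (C4.5/J48 surrogate), a random forest, and a small
# fully-connected neural network (Dl4j surrogate). Every learner exposes a
# positive-class probability; the ensemble is their unweighted mean with a
# 0.5 decision threshold (ties classified positive).

CLASSIFIER_ROLES <- c("naive_bayes", "knn", "kstar_like", "adaboost",
                      "bagging", "decision_tree", "random_forest", "mlp_deep")

POSITIVE <- "positive"
CLASS_LEVELS <- c("negative", "positive")

# run expr under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

as_class_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  y <- as.character(y)
  bad <- setdiff(unique(y), CLASS_LEVELS)
  if (length(bad)) stop("labels must be 'positive'/'negative'; got: ",
                        paste(bad, collapse = ", "))
  factor(y, levels = CLASS_LEVELS)
}

#' Learner size settings for the classifier bench
#'
#' `"standard"` mirrors common library defaults where a counterpart exists
#' (10 boosting and bagging iterations, single-neighbor KNN, 100-tree
#' forest). `"fast"` shrinks the stochastic learners (30-tree forest,
#' smaller/shorter network) for large repeated-refit experiments such as
#' Y-randomization; decision rules are unchanged.
#'
#' @param profile `"standard"` or `"fast"`.
#' @param ... named overrides of individual settings.
#' @return named list of settings.
#' @export
modeling_control <- function(profile = c("standard", "fast"), ...) {
  profile <- match.arg(profile)
  ctrl <- list(
    knn_k = 1L,
    kstar_k = 25L,
    boost_iter = 10L,
    bag_iter = 10L,
    rf_ntree = if (profile == "fast") 30L else 100L,
    mlp_size = if (profile == "fast") 5L else 10L,
    mlp_decay = 0.01,
    mlp_maxit = if (profile == "fast") 40L else 150L,
    rpart_cp = 0.01,
    profile = profile
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(ctrl))
  if (length(unknown)) stop("unknown control setting(s): ",
                            paste(unknown, collapse = ", "))
  ctrl[names(dots)] <- dots
  ctrl
}

fit_one_classifier <- function(role, x, y, ctrl, seed) {
  xdf <- as.data.frame(x)
  fit <- with_seed(seed, switch(
    role,
    naive_bayes = e1071::naiveBayes(xdf, y),
    knn = list(train = x, y = y, k = ctrl$knn_k, seed = seed),
    kstar_like = list(train = x, y = y, k = ctrl$kstar_k),
    adaboost = fit_adaboost(xdf, y, ctrl),
    bagging = fit_bagging(xdf, y, ctrl),
    decision_tree = rpart::rpart(
      .y ~ ., data = cbind(xdf, .y = y), method = "class",
      control = rpart::rpart.control(cp = ctrl$rpart_cp, xval = 0)),
    random_forest = randomForest::randomForest(x, y, ntree = ctrl$rf_ntree),
    mlp_deep = fit_mlp(x, y, ctrl),
    stop("unknown classifier role: ", role)
  ))
  structure(list(role = role, fit = fit), class = "dili_learner")
}

predict_prob <- function(model, x) {
  xdf <- as.data.frame(x)
  fit <- model$fit
  p <- switch(
    model$role,
    naive_bayes = {
      pr <- stats::predict(fit, xdf, type = "raw")
      as.numeric(pr[, POSITIVE])
    },
    knn = {
      pred <- with_seed(fit$seed, class::knn(fit$train, x, fit$y,
                                             k = fit$k, prob = TRUE))
      vote <- attr(pred, "prob")
      ifelse(pred == POSITIVE, vote, 1 - vote)
    },
    kstar_like = predict_kstar(fit, x),
    adaboost = predict_adaboost(fit, xdf),
    bagging = predict_bagging(fit, xdf),
    decision_tree = as.numeric(stats::predict(fit, xdf)[, POSITIVE]),
    random_forest = as.numeric(stats::predict(fit, x, type = "prob")[, POSITIVE]),
    mlp_deep = predict_mlp(fit, x),
    stop("unknown classifier role: ", model$role)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

# -- AdaBoost.M1 on depth-1 CART stumps ------------------------------------

fit_adaboost <- function(xdf, y, ctrl) {
  n <- nrow(xdf)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(ctrl$boost_iter)) {
    stump <- rpart::rpart(
      .y ~ ., data = cbind(xdf, .y = y), weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, xval = 0,
                                     minsplit = 2, minbucket = 1))
    pred <- stats::predict(stump, xdf, type = "class")
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    eps <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    miss <- pred != y
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    if (err == 0) break
  }
  if (!length(stumps)) {  # first stump no better than chance: keep it anyway
    stump <- rpart::rpart(
      .y ~ ., data = cbind(xdf, .y = y), method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, xval = 0,
                                     minsplit = 2, minbucket = 1))
    stumps <- list(stump); alphas <- 1
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, xdf) {
  votes <- matrix(0, nrow(xdf), length(fit$stumps))
  for (t in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[t]], xdf, type = "class")
    votes[, t] <- as.numeric(pred == POSITIVE)
  }
  as.numeric(votes %*% fit$alphas / sum(fit$alphas))
}

# -- bagged CART trees ------------------------------------------------------

fit_bagging <- function(xdf, y, ctrl) {
  n <- nrow(xdf)
  trees <- vector("list", ctrl$bag_iter)
  for (t in seq_len(ctrl$bag_iter)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- rpart::rpart(
      .y ~ ., data = cbind(xdf[idx, , drop = FALSE], .y = y[idx]),
      method = "class",
      control = rpart::rpart.control(cp = ctrl$rpart_cp, xval = 0))
  }
  list(trees = trees)
}

predict_bagging <- function(fit, xdf) {
  probs <- vapply(fit$trees,
                  function(tr) as.numeric(stats::predict(tr, xdf)[, POSITIVE]),
                  numeric(nrow(xdf)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(xdf))
  rowMeans(probs)
}

# -- distance-weighted neighbor learner (Kstar surrogate) -------------------

predict_kstar <- function(fit, x) {
  x <- as.matrix(x); train <- as.matrix(fit$train)
  k <- min(fit$k, nrow(train))
  ypos <- fit$y == POSITIVE
  # squared Euclidean cross-distances, vectorized
  d2 <- outer(rowSums(x^2), rowSums(train^2), "+") - 2 * x %*% t(train)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  apply_rows <- function(i) {
    ord <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
    dk <- d[i, ord]
    h <- mean(dk) + 1e-8
    w <- exp(-dk / h)
    sum(w * ypos[ord]) / sum(w)
  }
  vapply(seq_len(nrow(x)), apply_rows, numeric(1))
}

# -- small fully-connected network (Dl4j surrogate) -------------------------

fit_mlp <- function(x, y, ctrl) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  net <- nnet::nnet(xs, nnet::class.ind(y), size = ctrl$mlp_size,
                    decay = ctrl$mlp_decay, maxit = ctrl$mlp_maxit,
                    softmax = TRUE, trace = FALSE,
                    MaxNWts = 100000)
  list(net = net, center = ctr, scale = scl)
}

predict_mlp <- function(fit, x) {
  xs <- scale(as.matrix(x), center = fit$center, scale = fit$scale)
  pr <- stats::predict(fit$net, xs)
  as.numeric(pr[, POSITIVE])
}

# -- ensemble ---------------------------------------------------------------

#' Train the eight-classifier bench
#'
#' @param x numeric feature matrix (rows = compounds, named columns).
#' @param y labels (`"positive"`/`"negative"`), both classes required.
#' @param control learner settings from [modeling_control()].
#' @param seed master seed; each stochastic learner gets a sub-seed derived
#'   from it, so refitting with the same seed reproduces predictions exactly.
#' @return `dili_ensemble` object: 8 fitted learners, the feature list, the
#'   unweighted-mean averaging rule and the 0.5 decision threshold.
#' @export
train_base_classifiers <- function(x, y, control = modeling_control(),
                                   seed = 1) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  if (nlevels(droplevels(y)) < 2) stop("training data contain a single class")
  if (anyNA(x)) stop("feature matrix contains missing values")
  learners <- vector("list", length(CLASSIFIER_ROLES))
  names(learners) <- CLASSIFIER_ROLES
  for (i in seq_along(CLASSIFIER_ROLES)) {
    learners[[i]] <- fit_one_classifier(CLASSIFIER_ROLES[i], x, y, control,
                                        seed = seed * 8L + i)
  }
  structure(list(
    learners = learners,
    feature_names = colnames(x),
    threshold = 0.5,
    control = control,
    seed = seed
  ), class = "dili_ensemble")
}

#' Average the eight per-classifier probabilities
#'
#' The ensemble rule: the unweighted arithmetic mean of exactly eight
#' positive-class probabilities.
#'
#' @param probs numeric vector of length 8, values in `[0, 1]`.
#' @return the mean, in `[0, 1]`.
#' @export
ensemble_average <- function(probs) {
  if (length(probs) != 8 || anyNA(probs)) {
    stop("ensemble_average() needs exactly 8 non-missing probabilities")
  }
  stopifnot(all(probs >= 0 & probs <= 1))
  mean(probs)
}

#' Predict with a fitted ensemble
#'
#' @param object `dili_ensemble`.
#' @param newdata feature matrix containing at least the training features.
#' @param type `"prob"` (ensemble positive-class probability), `"class"`
#'   (threshold 0.5, ties positive) or `"all"` (per-classifier matrix plus
#'   both).
#' @param ... unused.
#' @export
predict.dili_ensemble <- function(object, newdata,
                                  type = c("prob", "class", "all"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  per <- vapply(object$learners, predict_prob, numeric(nrow(newdata)),
                x = newdata)
  if (is.null(dim(per))) per <- matrix(per, nrow = nrow(newdata),
                                       dimnames = list(NULL, CLASSIFIER_ROLES))
  prob <- rowMeans(per)
  cls <- factor(ifelse(prob >= object$threshold, POSITIVE, "negative"),
                levels = CLASS_LEVELS)
  switch(type,
         prob = prob,
         class = cls,
         all = list(per_classifier = per, prob = prob, class = cls))
}

# stratified fold assignment: within each class, sizes differ by at most 1
stratified_folds <- function(y, k, seed) {
  y <- as_class_factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the eight-classifier ensemble
#'
#' Folds are stratified by class (per-class sizes differ by at most one) and
#' shared by all eight classifiers, so their out-of-fold probabilities are
#' directly comparable. The ensemble probability of each compound is the
#' arithmetic mean of its eight out-of-fold probabilities; labels follow the
#' 0.5 threshold with ties classified positive.
#'
#' @param x feature matrix with rownames (compound ids).
#' @param y labels aligned with `x`.
#' @param k number of folds (default 10); `n >= k` required.
#' @param seed master seed controlling fold assignment and every stochastic
#'   learner.
#' @param control learner settings, see [modeling_control()].
#' @return `dili_cv` object: `fold_assignment`, `per_classifier_prob`
#'   (n x 8), `ensemble_prob`, `predicted_label`, `labels`.
#' @export
cross_validate <- function(x, y, k = 10, seed = 1,
                           control = modeling_control()) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  n <- nrow(x)
  if (n < k) stop("n < k: ", n, " rows for ", k, " folds")
  if (min(table(y)) < k) stop("each class needs at least k members for stratified ",
                              k, "-fold CV")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  fold <- stratified_folds(y, k, seed)
  per <- matrix(NA_real_, n, length(CLASSIFIER_ROLES),
                dimnames = list(ids, CLASSIFIER_ROLES))
  for (f in seq_len(k)) {
    te <- fold == f
    xtr <- x[!te, , drop = FALSE]; ytr <- droplevels(y[!te])
    if (nlevels(ytr) < 2) stop("training fold ", f, " lost a class")
    ytr <- factor(as.character(ytr), levels = CLASS_LEVELS)
    for (i in seq_along(CLASSIFIER_ROLES)) {
      m <- fit_one_classifier(CLASSIFIER_ROLES[i], xtr, ytr, control,
                              seed = (seed * 100L + f) * 8L + i)
      per[te, i] <- predict_prob(m, x[te, , drop = FALSE])
    }
  }
  prob <- rowMeans(per)
  predicted <- factor(ifelse(prob >= 0.5, POSITIVE, "negative"),
                      levels = CLASS_LEVELS)
  structure(list(
    fold_assignment = stats::setNames(fold, ids),
    per_classifier_prob = per,
    ensemble_prob = stats::setNames(prob, ids),
    predicted_label = stats::setNames(predicted, ids),
    labels = stats::setNames(y, ids),
    k = k, seed = seed, control = control
  ), class = "dili_cv")
}
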