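# Eight classifier configurations behind a uniform train/predict contract,
# plus the stratified k-fold cross-validation harness. SVMs, random forest,
# the decision tree and gradient boosting delegate to established solvers
# (e1071, ranger, rpart, xgboost) pinned to the benchmark hyperparameters;
# QDA and AdaBoost (with its logit round weight) are implemented natively.

GW_KINDS <- c("SVM_LINEAR", "SVM_POLY", "SVM_RBF", "RANDOM_FOREST",
              "DECISION_TREE", "QDA", "ADABOOST", "XGBOOST",
              "CENTROID", "MAJORITY")

gw_default_hyper <- function(kind) {
  switch(kind,
    SVM_LINEAR = list(C = 10),
    SVM_POLY = list(degree = 3, C = 1),
    SVM_RBF = list(C = 0.5, gamma = 0.1),
    RANDOM_FOREST = list(n_estimators = 100L, max_depth = 5L, max_features = 10L),
    DECISION_TREE = list(max_depth = 10L, min_samples = 1L),
    QDA = list(regularization = 0.5),
    ADABOOST = list(n_estimators = 100L, learning_rate = 0.1),
    XGBOOST = list(n_estimators = 100L, learning_rate = 0.01),
    CENTROID = list(),
    MAJORITY = list())
}

#' Build a classifier specification
#'
#' The eight benchmark configurations with their fixed hyperparameters:
#' linear SVM (C = 10), cubic polynomial SVM, RBF SVM (C = 0.5,
#' gamma = 0.1), random forest (100 trees, depth 5, 10 candidate features
#' per split), decision tree (depth 10, minimum 1 sample per leaf), QDA
#' (covariance shrinkage 0.5 toward its diagonal), AdaBoost (100 stumps,
#' learning rate 0.1) and XGBoost (100 rounds, learning rate 0.01).
#' `"CENTROID"` (nearest class centroid) and `"MAJORITY"` (training
#' majority class) are cheap baselines used as fitness surrogates.
#'
#' @param kind one of `r paste(GW_KINDS, collapse = ", ")`.
#' @param ... hyperparameter overrides (must name known fields).
#' @param seed RNG seed used by stochastic backends.
#' @return a `gw_clf_spec`.
#' @export
classifier_spec <- function(kind, ..., seed = 1L) {
  kind <- match.arg(kind, GW_KINDS)
  hyper <- gw_default_hyper(kind)
  dots <- list(...)
  bad <- setdiff(names(dots), names(hyper))
  if (length(bad))
    stop("unknown hyperparameters for ", kind, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  hyper[names(dots)] <- dots
  structure(list(kind = kind, hyper = hyper, seed = as.integer(seed)),
            class = "gw_clf_spec")
}

#' Stratified k-fold scheme
#'
#' Samples are shuffled within class under the seed and dealt round-robin
#' to `k` folds, so per-fold class counts are within one of exact
#' proportionality; folds are disjoint and cover all samples.
#'
#' @param labels factor (or vector) of class labels.
#' @param k number of folds (default 10); every class must have >= k
#'   members.
#' @param seed RNG seed.
#' @return a `gw_folds`: list with `k`, `test_indices` (list of integer
#'   vectors), `seed`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  counts <- table(labels)
  # k = n is leave-one-out (singleton folds); otherwise every class must
  # be large enough to appear in each fold
  if (k != length(labels) && any(counts < k))
    stop("class '", names(counts)[which.min(counts)], "' has only ",
         min(counts), " members; choose k <= ", min(counts), call. = FALSE)
  set.seed(seed)
  fold_of <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    # rotate the starting fold per class so small folds even out
    fold_of[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  structure(list(k = k,
                 test_indices = lapply(seq_len(k), function(f) which(fold_of == f)),
                 seed = seed),
            class = "gw_folds")
}

## ------------------------------------------------------------------ QDA

#' Fit regularized quadratic discriminant analysis
#'
#' Per class k: prior `P(y = k)`, mean `mu_k` and MLE covariance `Sigma_k`
#' shrunk toward its diagonal, `Sigma_k <- (1 - rho) Sigma_k +
#' rho diag(Sigma_k)`, which keeps the matrix positive-definite whenever
#' every feature varies within the class. Zero within-class variances are
#' floored at a small fraction of the overall variance.
#'
#' @param x samples x d matrix.
#' @param y factor of class labels (>= 2 classes present).
#' @param rho shrinkage weight in `[0, 1]` (default 0.5).
#' @return a `gw_qda`: `classes`, `priors`, `means`, `cov` (list),
#'   `cov_inv`, `log_det`.
#' @export
qda_fit <- function(x, y, rho = 0.5) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need both classes present", call. = FALSE)
  if (ncol(x) == 0) stop("need at least one feature", call. = FALSE)
  classes <- levels(y)
  vfloor <- 1e-8 * mean(apply(x, 2, stats::var)) + 1e-12
  fits <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    xc <- sweep(xi, 2, mu)
    S <- crossprod(xc) / nrow(xi)
    S <- (1 - rho) * S + rho * diag(pmax(diag(S), 0), ncol(x))
    diag(S) <- pmax(diag(S), vfloor)
    ch <- chol(S)
    list(prior = nrow(xi) / nrow(x), mu = mu, cov = S,
         cov_inv = chol2inv(ch), log_det = 2 * sum(log(diag(ch))))
  })
  structure(list(classes = classes,
                 priors = vapply(fits, `[[`, numeric(1), "prior"),
                 means = lapply(fits, `[[`, "mu"),
                 cov = lapply(fits, `[[`, "cov"),
                 cov_inv = lapply(fits, `[[`, "cov_inv"),
                 log_det = vapply(fits, `[[`, numeric(1), "log_det")),
            class = "gw_qda")
}

#' Quadratic discriminant scores
#'
#' `g_k(x) = ln P(y = k) - 0.5 ln|Sigma_k| -
#' 0.5 (x - mu_k)' Sigma_k^{-1} (x - mu_k)`; the predicted class is the
#' argmax over k.
#'
#' @param params a [qda_fit()] model.
#' @param x a feature vector or samples x d matrix.
#' @return matrix of scores (rows = samples, columns = classes).
#' @export
qda_discriminant <- function(params, x) {
  stopifnot(inherits(params, "gw_qda"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(params$means[[1]]))
    stop("feature dimension mismatch", call. = FALSE)
  scores <- vapply(seq_along(params$classes), function(k) {
    xc <- sweep(x, 2, params$means[[k]])
    maha <- rowSums((xc %*% params$cov_inv[[k]]) * xc)
    log(params$priors[k]) - 0.5 * params$log_det[k] - 0.5 * maha
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, params$classes))
  scores
}

## ------------------------------------------------------------- AdaBoost

#' AdaBoost round weight
#'
#' `alpha_t = learning_rate * ln((1 - eps_t) / eps_t)`. A weighted error
#' outside (0, 1) is clamped to `[1e-10, 1 - 1e-10]` with a warning.
#'
#' @param eps_t weighted training error of the round's weak learner.
#' @param learning_rate shrinkage factor.
#' @export
adaboost_round_weight <- function(eps_t, learning_rate) {
  if (eps_t <= 0 || eps_t >= 1) {
    warning("weighted error clamped into (0, 1)")
    eps_t <- min(max(eps_t, 1e-10), 1 - 1e-10)
  }
  learning_rate * log((1 - eps_t) / eps_t)
}

adaboost_fit <- function(x, y, n_estimators, learning_rate) {
  df <- data.frame(x)
  ysign <- ifelse(y == levels(y)[2], 1, -1)
  n <- length(ysign)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  for (t in seq_len(n_estimators)) {
    df$.y <- factor(ysign, levels = c(-1, 1))
    stump <- rpart::rpart(.y ~ ., data = df, weights = w,
                          control = rpart::rpart.control(
                            maxdepth = 1, cp = -1, minsplit = 2,
                            minbucket = 1, xval = 0))
    pred <- as.numeric(as.character(stats::predict(stump, df, type = "class")))
    eps <- sum(w * (pred != ysign))
    if (eps >= 0.5) break                       # no better than chance; stop
    eps_c <- max(eps, 1e-10)
    a <- learning_rate * log((1 - eps_c) / eps_c)
    w <- w * exp(-a * ysign * pred)
    w <- w / sum(w)
    used <- used + 1L
    stumps[[used]] <- stump
    alphas[used] <- a
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
       levels = levels(y))
}

adaboost_predict <- function(model, x) {
  df <- data.frame(x)
  if (!length(model$stumps))
    return(factor(rep(model$levels[2], nrow(df)), levels = model$levels))
  score <- rep(0, nrow(df))
  for (t in seq_along(model$stumps)) {
    pred <- as.numeric(as.character(
      stats::predict(model$stumps[[t]], df, type = "class")))
    score <- score + model$alphas[t] * pred
  }
  factor(model$levels[(score >= 0) + 1L], levels = model$levels)
}

## ---------------------------------------------------------- train/predict

#' Train a classifier per its specification
#'
#' @param spec a [classifier_spec()].
#' @param x samples x d matrix (d >= 1).
#' @param y factor of class labels with both classes present.
#' @return a `gw_model` usable with [predict()][predict.gw_model].
#' @export
train_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "gw_clf_spec"))
  x <- as.matrix(x)
  y <- factor(y, levels = levels(as.factor(y)))
  if (ncol(x) == 0) stop("need at least one feature", call. = FALSE)
  if (nlevels(droplevels(y)) < 2 && !spec$kind %in% c("MAJORITY"))
    stop("training labels contain a single class", call. = FALSE)
  h <- spec$hyper
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    SVM_LINEAR = e1071::svm(x, y, kernel = "linear", cost = h$C,
                            scale = FALSE),
    SVM_POLY = e1071::svm(x, y, kernel = "polynomial", degree = h$degree,
                          cost = h$C, scale = FALSE),
    SVM_RBF = e1071::svm(x, y, kernel = "radial", cost = h$C,
                         gamma = h$gamma, scale = FALSE),
    RANDOM_FOREST = {
      colnames(x) <- paste0("f", seq_len(ncol(x)))
      ranger::ranger(x = x, y = y, num.trees = h$n_estimators,
                     max.depth = h$max_depth,
                     mtry = min(h$max_features, ncol(x)),
                     seed = spec$seed, num.threads = 1)
    },
    DECISION_TREE = {
      df <- data.frame(x, .y = y)
      rpart::rpart(.y ~ ., data = df,
                   control = rpart::rpart.control(
                     maxdepth = h$max_depth, minbucket = h$min_samples,
                     minsplit = 2, cp = 0, xval = 0))
    },
    QDA = qda_fit(x, y, rho = h$regularization),
    ADABOOST = adaboost_fit(x, y, h$n_estimators, h$learning_rate),
    XGBOOST = {
      colnames(x) <- paste0("f", seq_len(ncol(x)))
      xgboost::xgboost(x, y, objective = "binary:logistic",
                       nrounds = h$n_estimators,
                       learning_rate = h$learning_rate,
                       nthreads = 1, seed = spec$seed, verbosity = 0)
    },
    CENTROID = lapply(split(seq_along(y), y), function(i)
      colMeans(x[i, , drop = FALSE])),
    MAJORITY = names(which.max(table(y))))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 d = ncol(x), n = nrow(x)),
            class = "gw_model")
}

#' Predict class labels from a trained model
#'
#' @param object a `gw_model`.
#' @param newdata samples x d matrix with the training dimension.
#' @param ... unused.
#' @return factor of predicted labels with the training levels.
#' @export
predict.gw_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$d)
    stop("feature dimension at predict (", ncol(x),
         ") differs from training (", object$d, ")", call. = FALSE)
  lv <- object$levels
  out <- switch(object$spec$kind,
    SVM_LINEAR = , SVM_POLY = , SVM_RBF =
      stats::predict(object$fit, x),
    RANDOM_FOREST = {
      colnames(x) <- paste0("f", seq_len(ncol(x)))
      stats::predict(object$fit, data = x, num.threads = 1)$predictions
    },
    DECISION_TREE = stats::predict(object$fit, data.frame(x), type = "class"),
    QDA = {
      sc <- qda_discriminant(object$fit, x)
      factor(object$fit$classes[max.col(sc, ties.method = "first")],
             levels = lv)
    },
    ADABOOST = adaboost_predict(object$fit, x),
    XGBOOST = {
      colnames(x) <- paste0("f", seq_len(ncol(x)))
      stats::predict(object$fit, x, type = "class")
    },
    CENTROID = {
      cents <- do.call(rbind, object$fit)
      d2 <- outer(rowSums(x^2), rowSums(cents^2), "+") - 2 * x %*% t(cents)
      factor(rownames(cents)[max.col(-d2, ties.method = "first")], levels = lv)
    },
    MAJORITY = factor(rep(object$fit, nrow(x)), levels = lv))
  factor(as.character(out), levels = lv)
}

#' Pooled cross-validated predictions
#'
#' Each sample's prediction comes from the model trained on all folds
#' except its own; pooled predictions cover every sample exactly once.
#'
#' @param spec a [classifier_spec()].
#' @param x samples x d matrix.
#' @param y factor of class labels.
#' @param folds a [stratified_folds()] scheme over `y`.
#' @return factor of length `nrow(x)`.
#' @export
cross_val_predict <- function(spec, x, y, folds) {
  stopifnot(inherits(folds, "gw_folds"))
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  covered <- sort(unlist(folds$test_indices))
  if (!identical(covered, seq_len(n)))
    stop("fold scheme does not cover the samples exactly once", call. = FALSE)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (test in folds$test_indices) {
    if (!length(test)) next
    model <- train_classifier(spec, x[-test, , drop = FALSE], y[-test])
    pred[test] <- predict(model, x[test, , drop = FALSE])
  }
  pred
}
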