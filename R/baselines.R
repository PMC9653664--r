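#' Specify a baseline ensemble learner
#'
#' The comparison rosters are fixed: classifiers RF (random forest),
#' BAGGING (bagged decision trees = a forest that considers all features
#' at every split), ADABOOST (SAMME boosting of shallow trees);
#' regressors RF, SVR (epsilon support vector regression, RBF kernel),
#' GB (gradient boosted trees), KR (kernel ridge, RBF), DTBOOST
#' (AdaBoost.R2 over decision trees), KN (k-nearest neighbours with
#' equally weighted neighbours).
#'
#' @param method one of RF, BAGGING, ADABOOST (classification) or RF, SVR,
#'   GB, KR, DTBOOST, KN (regression).
#' @param task "binary", "multiclass" or "regression".
#' @param seed integer seed for any stochastic learner.
#' @param ... hyperparameter overrides passed to the underlying learner
#'   (e.g. `ntree`, `n_estimators`, `k`, `lambda`, `sigma`).
#' @return list of class `estimator_spec` (the chosen method is stored in
#'   its `kind` field).
#' @export
estimator_spec <- function(method, task = c("binary", "multiclass",
                                            "regression"),
                           seed = 1L, ...) {
  task <- match.arg(task)
  kind <- toupper(method)
  allowed <- if (task == "regression") {
    c("RF", "SVR", "GB", "KR", "DTBOOST", "KN")
  } else {
    c("RF", "BAGGING", "ADABOOST")
  }
  if (!(kind %in% allowed)) {
    stop(sprintf("unknown estimator kind '%s' for task %s (allowed: %s)",
                 kind, task, paste(allowed, collapse = ", ")))
  }
  structure(list(kind = kind, task = task, seed = as.integer(seed),
                 hyper = list(...)),
            class = "estimator_spec")
}

.hy <- function(spec, name, default) {
  if (!is.null(spec$hyper[[name]])) spec$hyper[[name]] else default
}

#' Fit a baseline learner
#'
#' Dispatches to the established implementation for each roster entry
#' (randomForest, e1071, xgboost, caret) and to the in-package SAMME,
#' AdaBoost.R2 and kernel-ridge fits. The result is used through
#' [predict_baseline()], which returns hard labels/values, and for
#' classifiers class probabilities (the ensemble vote fraction).
#'
#' @param spec an [estimator_spec()].
#' @param x complete numeric feature matrix or data.frame.
#' @param y targets: 0/1, 0/1/2 factor-able labels, or numeric values.
#' @return list of class `baseline_fit`.
#' @export
fit_baseline <- function(spec, x, y) {
  stopifnot(inherits(spec, "estimator_spec"))
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y must have matching rows")
  set.seed(spec$seed)
  classification <- spec$task != "regression"
  fit <- if (classification) {
    yf <- factor(y, levels = sort(unique(c(y, if (spec$task == "binary")
      c(0, 1) else 0:2))))
    switch(spec$kind,
      RF = randomForest::randomForest(x, yf,
             ntree = .hy(spec, "ntree", 500L)),
      BAGGING = randomForest::randomForest(x, yf,
             ntree = .hy(spec, "ntree", 500L), mtry = ncol(x)),
      ADABOOST = .fit_samme(x, yf,
             n_estimators = .hy(spec, "n_estimators", 50L),
             maxdepth = .hy(spec, "maxdepth", 1L)))
  } else {
    switch(spec$kind,
      RF = randomForest::randomForest(x, y,
             ntree = .hy(spec, "ntree", 500L)),
      SVR = e1071::svm(x, y, type = "eps-regression", kernel = "radial",
             cost = .hy(spec, "cost", 1), epsilon = .hy(spec, "epsilon", 0.1)),
      GB = xgboost::xgb.train(
             params = list(objective = "reg:squarederror",
                           max_depth = .hy(spec, "max_depth", 3L),
                           eta = .hy(spec, "eta", 0.1), nthread = 1L),
             data = xgboost::xgb.DMatrix(data = x, label = y),
             nrounds = .hy(spec, "nrounds", 100L), verbose = 0),
      KR = .fit_krr(x, y, lambda = .hy(spec, "lambda", 1),
             sigma = .hy(spec, "sigma", NULL)),
      DTBOOST = .fit_adaboost_r2(x, y,
             n_estimators = .hy(spec, "n_estimators", 50L),
             maxdepth = .hy(spec, "maxdepth", 3L)),
      KN = caret::knnreg(x, y, k = .hy(spec, "k", 5L)))
  }
  structure(list(spec = spec, fit = fit,
                 levels = if (classification) levels(
                   factor(y, levels = sort(unique(c(y,
                     if (spec$task == "binary") c(0, 1) else 0:2)))))
                 else NULL),
            class = "baseline_fit")
}

#' Predict from a fitted baseline learner
#'
#' @param object a `baseline_fit`.
#' @param x feature matrix with the training columns.
#' @param type "response" (hard label / numeric value) or, for
#'   classifiers, "prob" (class-probability matrix, columns in class
#'   order).
#' @return vector of predictions, or a probability matrix.
#' @export
predict_baseline <- function(object, x, type = c("response", "prob")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  spec <- object$spec
  classification <- spec$task != "regression"
  if (!classification) {
    if (type == "prob") stop("probabilities are defined for classifiers only")
    p <- switch(spec$kind,
                KN = stats::predict(object$fit, as.data.frame(x)),
                KR = .predict_krr(object$fit, x),
                DTBOOST = .predict_adaboost_r2(object$fit, x),
                GB = stats::predict(object$fit, x),
                stats::predict(object$fit, x))
    return(as.numeric(p))
  }
  prob <- switch(spec$kind,
    RF = ,
    BAGGING = stats::predict(object$fit, x, type = "prob"),
    ADABOOST = .predict_samme(object$fit, x, type = "prob"))
  prob <- as.matrix(prob)
  if (type == "prob") return(prob)
  cls <- object$levels[max.col(prob, ties.method = "first")]
  as.numeric(cls)
}

#' Seven-way consensus prediction
#'
#' The final consensus regression value for each chemical is the
#' element-wise arithmetic mean of the seven member predictions
#' (HNN, RF, SVR, GB, KR, DTBOOST, KN).
#'
#' @param predictions list of exactly 7 numeric vectors of equal length.
#' @return numeric vector of per-chemical consensus values.
#' @export
consensus_predict <- function(predictions) {
  if (!is.list(predictions) || length(predictions) != 7L) {
    stop("consensus requires exactly 7 member prediction vectors")
  }
  n <- unique(vapply(predictions, length, integer(1)))
  if (length(n) != 1L) stop("member prediction vectors differ in length")
  rowMeans(do.call(cbind, predictions))
}

## ---- in-package learners (no installed implementation exists) ----------

# SAMME multiclass AdaBoost over shallow rpart trees.
.fit_samme <- function(x, y, n_estimators = 50L, maxdepth = 1L) {
  n <- nrow(x); K <- nlevels(y)
  df <- data.frame(.y = y, x, check.names = FALSE)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2,
                          xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w * miss) / sum(w)
    if (err >= 1 - 1 / K) break        # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break             # perfect learner: nothing left to boost
  }
  if (length(trees) == 0L) {  # first stump no better than chance: keep it
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2,
                          xval = 0))
    trees <- list(fit); alphas <- 1
  }
  list(trees = trees, alphas = alphas, levels = levels(y))
}

.predict_samme <- function(model, x, type = c("prob", "class")) {
  type <- match.arg(type)
  df <- as.data.frame(x)
  K <- length(model$levels)
  votes <- matrix(0, nrow(df), K, dimnames = list(NULL, model$levels))
  for (m in seq_along(model$trees)) {
    pred <- stats::predict(model$trees[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + model$alphas[m]
  }
  prob <- votes / pmax(rowSums(votes), .Machine$double.eps)
  if (type == "prob") prob else
    model$levels[max.col(prob, ties.method = "first")]
}

# AdaBoost.R2 (Drucker) regression boosting over rpart trees with the
# linear loss; final prediction is the weighted median of the members.
.fit_adaboost_r2 <- function(x, y, n_estimators = 50L, maxdepth = 3L) {
  n <- nrow(x)
  df <- data.frame(.y = y, x, check.names = FALSE)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    rows <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(.y ~ ., data = df[rows, , drop = FALSE],
                        method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0.001, xval = 0))
    pred <- stats::predict(fit, df)
    ae <- abs(pred - y)
    denom <- max(ae)
    if (denom <= 0) {
      trees[[length(trees) + 1L]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    lossv <- ae / denom
    lbar <- sum(w * lossv)
    if (lbar >= 0.5) break
    beta <- lbar / (1 - lbar)
    w <- w * beta^(1 - lossv)
    w <- w / sum(w)
    trees[[length(trees) + 1L]] <- fit
    betas <- c(betas, max(beta, 1e-10))
  }
  if (length(trees) == 0L) {  # first learner already too weak: keep it
    fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0.001, xval = 0))
    trees <- list(fit); betas <- 1
  }
  list(trees = trees, betas = betas)
}

.predict_adaboost_r2 <- function(model, x) {
  df <- as.data.frame(x)
  preds <- vapply(model$trees, function(t) stats::predict(t, df),
                  numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  lw <- log(1 / model$betas)
  apply(preds, 1, function(p) {
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1]]
  })
}

# Kernel ridge regression, RBF kernel, closed form
# alpha = (K + lambda I)^(-1) y.
.fit_krr <- function(x, y, lambda = 1, sigma = NULL) {
  if (is.null(sigma)) sigma <- 1 / ncol(x)  # rbfdot inverse-width default
  kern <- kernlab::rbfdot(sigma = sigma)
  Km <- kernlab::kernelMatrix(kern, x)
  alpha <- solve(Km + lambda * diag(nrow(x)), y)
  list(xtrain = x, alpha = alpha, kern = kern)
}

.predict_krr <- function(model, x) {
  Kx <- kernlab::kernelMatrix(model$kern, x, model$xtrain)
  as.numeric(Kx %*% model$alpha)
}
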