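#' Configuration for the machine-learning predictors
#'
#' The regression algorithms and their settings: k-nearest neighbors
#' (`k = 5`, Euclidean distances, uniform weights), RBF-kernel support
#' vector regression with the free parameter `theta = 1/(p * var(Z))`
#' computed from the training genotype matrix, random forest with 100 trees
#' grown to a maximum height of `p`, and AdaBoost with decision-tree base
#' regressors and the linear loss. The classification algorithms (RBF-kernel
#' SVC, random forest, one-hidden-layer MLP and Gaussian naive Bayes) run at
#' baseline defaults.
#'
#' @param algorithm One of `"knn"`, `"svm"`, `"rf"`, `"adaboost"`
#'   (regression) or `"svm"`, `"rf"`, `"mlp"`, `"gnb"` (classification).
#' @param task `"regression"` or `"classification"`.
#' @param k Neighbors for KNN.
#' @param n_trees Trees for the forest / boosting stages.
#' @param C Soft-margin constant for the SVMs.
#' @param epsilon Insensitive-tube width for SVR.
#' @param theta Optional fixed RBF free parameter; by default computed from
#'   the training matrix as `1/(p * var(Z))` with `var(Z)` the pooled
#'   variance over all entries.
#' @param seed Integer seed fixed into the model fits.
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(algorithm, task = c("regression", "classification"),
                      k = 5, n_trees = 100, C = 1, epsilon = 0.1,
                      theta = NULL, seed = 1) {
  task <- match.arg(task)
  valid <- if (task == "regression") c("knn", "svm", "rf", "adaboost")
           else c("svm", "rf", "mlp", "gnb")
  algorithm <- match.arg(algorithm, valid)
  structure(list(algorithm = algorithm, task = task, k = k,
                 n_trees = n_trees, C = C, epsilon = epsilon, theta = theta,
                 seed = seed),
            class = "ml_config")
}

#' The RBF free parameter theta = 1/(p * var(Z))
#'
#' `var(Z)` is the pooled variance over all entries of the training
#' genotype matrix and `p` the number of loci.
#'
#' @param Z Training genotype matrix.
#' @return Positive scalar.
#' @export
rbf_theta <- function(Z) {
  v <- stats::var(as.vector(as.matrix(Z)))
  if (v <= 0) stop("genotype matrix has zero variance; theta undefined")
  1 / (ncol(Z) * v)
}

#' Fit a configured machine-learning predictor
#'
#' @param config An [ml_config()].
#' @param Z Training genotype matrix (individuals x markers), imputed.
#' @param target Numeric trait values (regression) or interval labels
#'   (classification, at least two classes).
#' @return A `predictor_model`; use [predict()] on new genotype rows.
#' @export
fit_predictor <- function(config, Z, target) {
  stopifnot(inherits(config, "ml_config"))
  Z <- as.matrix(Z)
  if (nrow(Z) != length(target)) stop("target must align with Z rows")
  if (config$task == "classification" &&
      nlevels(factor(target)) < 2)
    stop("classification target has a single class")
  if (config$task == "regression" && config$algorithm == "knn" &&
      config$k > nrow(Z))
    stop("k exceeds the number of training individuals")
  set.seed(config$seed)
  theta <- config$theta
  if (is.null(theta) && config$algorithm == "svm") theta <- rbf_theta(Z)
  fit <- switch(
    paste(config$task, config$algorithm, sep = "."),
    regression.knn = list(Z = Z, y = as.numeric(target)),
    regression.svm = fit_svr_rbf(Z, target, theta = theta, C = config$C,
                                 epsilon = config$epsilon),
    regression.rf = fit_rf(Z, target, task = "regression",
                           n_trees = config$n_trees),
    regression.adaboost = fit_adaboost_r2(Z, target,
                                          n_trees = min(config$n_trees, 50)),
    classification.svm = fit_svc_rbf(Z, target, theta = theta,
                                     C = config$C),
    classification.rf = fit_rf(Z, target, task = "classification",
                               n_trees = config$n_trees),
    classification.mlp = fit_mlp(Z, target),
    classification.gnb = fit_gnb(Z, target),
    stop("unknown algorithm/task combination")
  )
  structure(list(config = config, fit = fit, theta = theta,
                 p = ncol(Z), training_ids = rownames(Z),
                 levels = if (config$task == "classification")
                   levels(factor(target))),
            class = "predictor_model")
}

#' @export
predict.predictor_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " markers; model trained on ",
         object$p)
  cfg <- object$config
  switch(
    paste(cfg$task, cfg$algorithm, sep = "."),
    regression.knn = as.numeric(FNN::knn.reg(
      train = object$fit$Z, test = newdata, y = object$fit$y,
      k = cfg$k)$pred),
    regression.svm = predict_svr_rbf(object$fit, newdata),
    regression.rf = predict_rf(object$fit, newdata),
    regression.adaboost = predict_adaboost_r2(object$fit, newdata),
    classification.svm = predict_svc_rbf(object$fit, newdata),
    classification.rf = predict_rf(object$fit, newdata),
    classification.mlp = predict_mlp(object$fit, newdata),
    classification.gnb = predict_gnb(object$fit, newdata)
  )
}

#' @exportS3Method print predictor_model
print.predictor_model <- function(x, ...) {
  cat("predictor_model:", x$config$algorithm, "(", x$config$task, "),",
      length(x$training_ids), "training individuals,", x$p, "markers\n")
  if (!is.null(x$theta)) cat("  RBF theta:", signif(x$theta, 5), "\n")
  invisible(x)
}
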