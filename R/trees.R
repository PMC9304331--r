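# Decision-tree ensembles over the compiled histogram-CART engine.
# Features are pre-binned once per training matrix (quantile bins, at most
# 64); new data are binned with the stored cut points at predict time.

MAX_BINS <- 64L

bin_features <- function(Z) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  cuts <- vector("list", p)
  codes <- matrix(0L, nrow(Z), p)
  for (j in seq_len(p)) {
    u <- sort(unique(Z[, j]))
    if (length(u) <= MAX_BINS) {
      cj <- if (length(u) > 1) u[-length(u)] + diff(u) / 2 else numeric(0)
    } else {
      qs <- stats::quantile(Z[, j], probs = seq_len(MAX_BINS - 1) / MAX_BINS,
                            names = FALSE, type = 1)
      cj <- unique(qs)
    }
    cuts[[j]] <- cj
    codes[, j] <- findInterval(Z[, j], cj, left.open = FALSE)
  }
  list(codes = codes, cuts = cuts,
       nb = vapply(cuts, function(cc) length(cc) + 1L, integer(1)))
}

bin_apply <- function(binning, Z) {
  Z <- as.matrix(Z)
  p <- length(binning$cuts)
  if (ncol(Z) != p) stop("column count mismatch with training matrix")
  codes <- matrix(0L, nrow(Z), p)
  for (j in seq_len(p))
    codes[, j] <- findInterval(Z[, j], binning$cuts[[j]], left.open = FALSE)
  codes
}

fit_tree <- function(binning, Y, sample_idx = NULL, weights = NULL,
                     max_depth = 30L, min_leaf = 1L, mtry = NULL) {
  n <- nrow(binning$codes)
  if (is.null(sample_idx)) sample_idx <- seq_len(n)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(mtry)) mtry <- ncol(binning$codes)
  Y <- as.matrix(Y)
  cart_fit_cpp(binning$codes, binning$nb, Y, weights,
               as.integer(sample_idx - 1L), as.integer(max_depth),
               as.integer(min_leaf), as.integer(mtry))
}

predict_tree <- function(tree, codes) cart_predict_cpp(tree, codes)

# --- Random forest ---------------------------------------------------------

# Regression: bootstrap bagging, all features per split (the common library
# default), trees grown to max_depth = p per the "maximum tree height of p"
# configuration (effectively unbounded; capped at 10^6 internally).
# Classification: same engine on one-hot responses (variance reduction on a
# one-hot response equals the multiclass Gini criterion), mtry = sqrt(p),
# prediction by averaged class probabilities.
fit_rf <- function(Z, target, task, n_trees = 100, mtry = NULL,
                   max_depth = NULL, min_leaf = NULL) {
  binning <- bin_features(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (task == "classification") {
    lev <- levels(factor(target))
    Y <- outer(as.character(target), lev, "==") * 1
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
    if (is.null(min_leaf)) min_leaf <- 1L
  } else {
    lev <- NULL
    Y <- matrix(as.numeric(target), ncol = 1)
    if (is.null(mtry)) mtry <- p
    if (is.null(min_leaf)) min_leaf <- 1L
  }
  if (is.null(max_depth)) max_depth <- min(p, 1e6)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- fit_tree(binning, Y, sample_idx = idx,
                           max_depth = max_depth, min_leaf = min_leaf,
                           mtry = mtry)
  }
  imp <- Reduce(`+`, lapply(trees, `[[`, "importance")) / n_trees
  structure(list(trees = trees, binning = binning, levels = lev, task = task,
                 importance = stats::setNames(imp, colnames(Z))),
            class = "rf_model")
}

predict_rf <- function(model, Z_new) {
  codes <- bin_apply(model$binning, Z_new)
  preds <- Reduce(`+`, lapply(model$trees, predict_tree, codes = codes)) /
    length(model$trees)
  if (model$task == "classification") {
    factor(model$levels[max.col(preds, ties.method = "first")],
           levels = model$levels)
  } else {
    as.numeric(preds)
  }
}

# --- Gradient tree boosting ------------------------------------------------

# Regression: least-squares boosting, depth-3 trees, shrinkage 0.1, 100
# stages (the common library defaults). Classification: multinomial deviance
# with one multi-output tree per stage fitted to the K-dimensional softmax
# gradient. Feature importances are impurity gains summed over stages and
# normalized to mean 1e0 scale (absolute scale is irrelevant: selection uses
# the importance > mean rule).
fit_gtb <- function(Z, target, task, n_trees = 100, learning_rate = 0.1,
                    max_depth = 3, min_leaf = 1, subsample = 1) {
  binning <- bin_features(Z)
  n <- nrow(Z)
  imp <- numeric(ncol(Z))
  trees <- vector("list", n_trees)
  if (task == "classification") {
    lev <- levels(factor(target))
    K <- length(lev)
    Yh <- outer(as.character(target), lev, "==") * 1
    Fmat <- matrix(0, n, K)  # raw scores
    base <- log(pmax(colMeans(Yh), 1e-12))
    Fmat <- sweep(Fmat, 2, base, "+")
    for (b in seq_len(n_trees)) {
      P <- exp(Fmat - apply(Fmat, 1, max))
      P <- P / rowSums(P)
      G <- Yh - P  # negative gradient of multinomial deviance
      idx <- if (subsample < 1)
        sample.int(n, max(2, floor(subsample * n))) else seq_len(n)
      tr <- fit_tree(binning, G, sample_idx = idx, max_depth = max_depth,
                     min_leaf = min_leaf)
      trees[[b]] <- tr
      imp <- imp + tr$importance
      Fmat <- Fmat + learning_rate * predict_tree(tr, binning$codes)
    }
    init <- base
  } else {
    lev <- NULL
    y <- as.numeric(target)
    init <- mean(y)
    Fv <- rep(init, n)
    for (b in seq_len(n_trees)) {
      idx <- if (subsample < 1)
        sample.int(n, max(2, floor(subsample * n))) else seq_len(n)
      tr <- fit_tree(binning, matrix(y - Fv, ncol = 1), sample_idx = idx,
                     max_depth = max_depth, min_leaf = min_leaf)
      trees[[b]] <- tr
      imp <- imp + tr$importance
      Fv <- Fv + learning_rate * predict_tree(tr, binning$codes)[, 1]
    }
  }
  structure(list(trees = trees, binning = binning, levels = lev, task = task,
                 learning_rate = learning_rate, init = init,
                 importance = stats::setNames(imp, colnames(Z))),
            class = "gtb_model")
}

predict_gtb <- function(model, Z_new, type = c("response", "prob")) {
  type <- match.arg(type)
  codes <- bin_apply(model$binning, Z_new)
  agg <- Reduce(`+`, lapply(model$trees, predict_tree, codes = codes))
  if (model$task == "classification") {
    Fmat <- sweep(model$learning_rate * agg, 2, model$init, "+")
    P <- exp(Fmat - apply(Fmat, 1, max))
    P <- P / rowSums(P)
    if (type == "prob") return(P)
    factor(model$levels[max.col(P, ties.method = "first")],
           levels = model$levels)
  } else {
    model$init + model$learning_rate * agg[, 1]
  }
}

# --- AdaBoost.R2 -----------------------------------------------------------

# Drucker's AdaBoost.R2 with decision-tree base regressors and the linear
# loss for weighting boosting iterations; prediction is the weighted median
# of the base predictions.
fit_adaboost_r2 <- function(Z, y, n_trees = 50, max_depth = NULL,
                            min_leaf = 1) {
  binning <- bin_features(Z)
  n <- nrow(Z)
  if (is.null(max_depth)) max_depth <- min(ncol(Z), 1e6)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  Ymat <- matrix(as.numeric(y), ncol = 1)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)  # weighted bootstrap
    tr <- fit_tree(binning, Ymat, sample_idx = idx, max_depth = max_depth,
                   min_leaf = min_leaf)
    pred <- predict_tree(tr, binning$codes)[, 1]
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= 0) {  # perfect fit: keep and stop
      trees[[length(trees) + 1L]] <- tr
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / emax  # linear loss
    ebar <- sum(w * loss)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    trees[[length(trees) + 1L]] <- tr
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  if (length(trees) == 0) {  # fall back to a single unweighted tree
    tr <- fit_tree(binning, Ymat, max_depth = max_depth, min_leaf = min_leaf)
    trees <- list(tr); betas <- 1
  }
  structure(list(trees = trees, betas = betas, binning = binning),
            class = "adaboost_model")
}

predict_adaboost_r2 <- function(model, Z_new) {
  codes <- bin_apply(model$binning, Z_new)
  P <- vapply(model$trees, function(tr) predict_tree(tr, codes)[, 1],
              numeric(nrow(codes)))
  P <- matrix(P, nrow = nrow(codes))
  lw <- log(1 / pmax(model$betas, 1e-12))
  apply(P, 1, function(pr) weighted_median(pr, lw))
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= 0.5 * sum(w))[1]]
}
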