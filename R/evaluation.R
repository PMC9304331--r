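#' Cross-validation plan
#'
#' The evaluation protocol: 10-fold CV repeated 50 times (optionally
#' stratified on the interval classes) and leave-one-out. All fold draws
#' descend from the master seed, so a plan fully determines the partition.
#'
#' @param scheme `"kfold"`, `"stratified"` or `"loo"`.
#' @param k Folds per repeat. Default 10.
#' @param repeats Repeats (ignored for LOO). Default 50.
#' @param seed Master seed.
#' @return A `cv_plan`.
#' @export
cv_plan <- function(scheme = c("kfold", "stratified", "loo"), k = 10,
                    repeats = 50, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "loo") repeats <- 1L
  structure(list(scheme = scheme, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Build fold assignments for a plan
#'
#' @param n Number of individuals.
#' @param plan A [cv_plan()].
#' @param labels Class labels, required for stratified folds.
#' @return List (one element per repeat) of integer fold ids per
#'   individual; fold sizes differ by at most one, and stratified folds
#'   preserve class counts within one per class.
#' @export
make_folds <- function(n, plan, labels = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  if (plan$scheme == "loo") return(list(seq_len(n)))
  if (n < plan$k) stop("n must be at least the number of folds")
  set.seed(plan$seed)
  lapply(seq_len(plan$repeats), function(r) {
    if (plan$scheme == "stratified") {
      if (is.null(labels)) stop("stratified folds need labels")
      f <- factor(labels)
      small <- table(f) < plan$k
      if (any(small))
        warning("classes smaller than k (",
                paste(names(which(small)), collapse = ", "),
                "); best-effort allocation")
      fold <- integer(n)
      offset <- 0L
      for (lv in levels(f)) {
        idx <- sample(which(f == lv))
        # continue the round-robin across classes so fold sizes stay even
        fold[idx] <- ((offset + seq_along(idx) - 1L) %% plan$k) + 1L
        offset <- offset + length(idx)
      }
      fold
    } else {
      sample(rep(seq_len(plan$k), length.out = n))
    }
  })
}

#' Bayesian GP model specification for the CV harness
#'
#' @param kind `"brr"`, `"smgk"` or `"rkhs_ka"`.
#' @param control A [gp_control()].
#' @param h Bandwidth for the single-kernel model. Default 1, unscaled
#'   distances.
#' @param bandwidths Bandwidth family for kernel averaging (median-scaled
#'   distances). Default `c(15, 5, 1)`.
#' @param markers Optional marker ids: restrict the model to this subset
#'   (e.g. a CR3 `marker_set` or its ids).
#' @param fixed_markers Optional marker ids used as a fixed-effect block,
#'   with the kernel built from the remaining markers (the C3F/R3F
#'   configuration; single-kernel models only).
#' @param label Display label; defaults to a description of the spec.
#' @return A `gp_model`.
#' @export
gp_model <- function(kind = c("smgk", "brr", "rkhs_ka"),
                     control = gp_control(), h = 1,
                     bandwidths = c(15, 5, 1), markers = NULL,
                     fixed_markers = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (inherits(markers, "marker_set")) {
    if (is.null(label)) label <- paste0(toupper(kind), "/", markers$name)
    markers <- markers$markers
  }
  if (inherits(fixed_markers, "marker_set")) {
    if (is.null(label)) label <- paste0(toupper(kind), "/", fixed_markers$name, "F")
    fixed_markers <- fixed_markers$markers
  }
  if (!is.null(fixed_markers) && kind != "smgk")
    stop("fixed-effect marker blocks are supported for the single-kernel model")
  if (is.null(label)) label <- toupper(kind)
  structure(list(kind = kind, control = control, h = h,
                 bandwidths = bandwidths, markers = markers,
                 fixed_markers = fixed_markers, label = label),
            class = "gp_model")
}

#' Run cross-validation for a model specification
#'
#' Kernel models use the masked-response mechanism: the kernel is built
#' once over all individuals and each fold's phenotypes are masked for
#' prediction. Ridge regression refits per training fold and predicts
#' `Z_test %*% gamma_hat`; machine-learning configs refit per fold.
#' Per-fold model failures are recorded and the fold skipped.
#'
#' @param model A [gp_model()] or [ml_config()].
#' @param Z Genotype matrix over all individuals.
#' @param target Trait values (regression) or interval labels
#'   (classification configs).
#' @param plan A [cv_plan()].
#' @param strat_labels Labels for stratified folds.
#' @return A `cv_result`: per-repeat predictions, per-fold MSE (or
#'   accuracy for classification), per-repeat Pearson R, failures.
#' @export
run_cv <- function(model, Z, target, plan = cv_plan(), strat_labels = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (length(target) != n) stop("target must align with Z rows")
  folds <- make_folds(n, plan, labels = strat_labels)
  classification <- inherits(model, "ml_config") &&
    model$task == "classification"

  prep <- if (inherits(model, "gp_model")) cv_prepare_gp(model, Z) else NULL

  preds <- matrix(if (classification) NA_character_ else NA_real_,
                  n, length(folds))
  fold_metric <- matrix(NA_real_, length(folds), max(unlist(folds)))
  failures <- character(0)

  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    for (fi in sort(unique(fold))) {
      test <- which(fold == fi)
      train <- which(fold != fi)
      seed_rf <- (plan$seed + 7919L * r + 104729L * fi) %% 2147483647L
      pr <- tryCatch(
        cv_fit_fold(model, prep, Z, target, train, test, seed_rf),
        error = function(e) e)
      if (inherits(pr, "error")) {
        failures <- c(failures,
                      sprintf("repeat %d fold %d: %s", r, fi,
                              conditionMessage(pr)))
        next
      }
      preds[test, r] <- as.character(pr)
      fold_metric[r, fi] <- if (classification) {
        mean(as.character(pr) == as.character(target[test]))
      } else {
        mean((as.numeric(target[test]) - as.numeric(pr))^2)
      }
    }
  }

  if (classification) {
    r_stat <- apply(preds, 2, function(pv) {
      ok <- !is.na(pv)
      if (!any(ok)) NA_real_ else
        mean(pv[ok] == as.character(target[ok]))
    })
  } else {
    preds <- matrix(as.numeric(preds), n, length(folds))
    r_stat <- apply(preds, 2, function(pv) {
      ok <- !is.na(pv)
      if (sum(ok) < 3 || stats::sd(pv[ok]) == 0) return(NA_real_)
      stats::cor(pv[ok], as.numeric(target[ok]))
    })
  }

  structure(list(label = model$label %||%
                   paste0(model$algorithm, " (", model$task, ")"),
                 predictions = preds, r = r_stat, mse = fold_metric,
                 n = n, classification = classification,
                 failures = failures, plan = plan),
            class = "cv_result")
}

cv_prepare_gp <- function(model, Z) {
  if (!is.null(model$markers)) {
    miss <- setdiff(model$markers, colnames(Z))
    if (length(miss) > 0) stop("unknown markers in model spec: ",
                               paste(head(miss, 3), collapse = ", "))
    Zm <- Z[, model$markers, drop = FALSE]
  } else Zm <- Z
  if (model$kind == "brr") return(list(Z = Zm))
  X <- NULL
  if (!is.null(model$fixed_markers)) {
    X <- Z[, model$fixed_markers, drop = FALSE]
    kernel_cols <- setdiff(colnames(Zm), model$fixed_markers)
    Zm <- Zm[, kernel_cols, drop = FALSE]
  }
  kernels <- if (model$kind == "smgk") {
    list(gaussian_kernel(Zm, h = model$h, scale = "none"))
  } else {
    kernel_average_family(Zm, bandwidths = model$bandwidths)
  }
  list(kernels = kernels, X = X)
}

cv_fit_fold <- function(model, prep, Z, target, train, test, seed) {
  if (inherits(model, "gp_model")) {
    set.seed(seed)
    if (model$kind == "brr") {
      fit <- fit_brr(as.numeric(target[train]),
                     prep$Z[train, , drop = FALSE], control = model$control)
      return(predict(fit, prep$Z[test, , drop = FALSE]))
    }
    y_masked <- as.numeric(target)
    y_masked[test] <- NA_real_
    fit <- fit_kernel_model(y_masked, prep$kernels, control = model$control,
                            X = prep$X)
    return(fit$predictions[test])
  }
  cfg <- model
  cfg$seed <- seed
  pm <- fit_predictor(cfg, Z[train, , drop = FALSE], target[train])
  predict(pm, Z[test, , drop = FALSE])
}

#' @exportS3Method print cv_result
print.cv_result <- function(x, ...) {
  metric <- if (x$classification) "accuracy" else "Pearson R"
  cat("cv_result [", x$label, "]: ", length(x$r), " repeat(s), n = ", x$n,
      "\n  mean ", metric, ": ", signif(mean(x$r, na.rm = TRUE), 4),
      "   mean fold ", if (x$classification) "accuracy" else "MSE", ": ",
      signif(mean(x$mse, na.rm = TRUE), 4), "\n", sep = "")
  if (length(x$failures) > 0)
    cat("  ", length(x$failures), "failed fold fits\n")
  invisible(x)
}

#' Compare cross-validated models by ANOVA and Tukey's HSD
#'
#' One-way ANOVA across models on the per-repeat metric, followed by
#' Tukey's multiple comparisons at `alpha` and a compact letter display
#' (models sharing a letter are not significantly different). Repeats with
#' undefined Pearson R (zero-variance predictions) are dropped and counted.
#'
#' @param results List of `cv_result`s with equal repeat counts.
#' @param metric `"r"` (per-repeat correlation / accuracy) or `"mse"`
#'   (per-repeat mean of fold MSEs).
#' @param alpha Significance level. Default 0.05.
#' @return A `comparison_report`: ANOVA F and p, Tukey table, group
#'   letters, per-model means.
#' @export
compare_models <- function(results, metric = c("r", "mse"), alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, TRUE, "cv_result")))
  labels <- vapply(results, `[[`, "", "label")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    x <- results[[i]]
    value <- if (metric == "r") x$r else rowMeans(x$mse, na.rm = TRUE)
    data.frame(model = labels[i], value = value)
  }))
  dropped <- sum(is.na(df$value))
  df <- df[!is.na(df$value), ]
  if (any(table(df$model) < 2)) stop("every model needs at least 2 repeats")
  df$model <- factor(df$model, levels = labels)
  fit <- stats::aov(value ~ model, data = df)
  at <- anova(fit)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$model
  means <- sort(tapply(df$value, df$model, mean), decreasing = TRUE)
  letters <- tukey_letters(names(means), tk, alpha)
  structure(list(anova_F = at$`F value`[1], anova_p = at$`Pr(>F)`[1],
                 tukey = tk, means = means, letters = letters,
                 dropped_repeats = dropped, metric = metric, alpha = alpha),
            class = "comparison_report")
}

# compact letter display: models are ordered by mean; each maximal run of
# mutually non-significant models gets one letter
tukey_letters <- function(ordered_models, tukey, alpha) {
  m <- length(ordered_models)
  sig <- matrix(FALSE, m, m, dimnames = list(ordered_models, ordered_models))
  for (rn in rownames(tukey)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% ordered_models)) next
    s <- tukey[rn, "p adj"] < alpha
    sig[pair[1], pair[2]] <- s
    sig[pair[2], pair[1]] <- s
  }
  groups <- list()
  for (i in seq_len(m)) {
    j <- i
    while (j < m && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    groups[[length(groups) + 1]] <- i:j
  }
  # drop runs contained in another run
  keep <- !vapply(seq_along(groups), function(a)
    any(vapply(seq_along(groups), function(b)
      a != b && all(groups[[a]] %in% groups[[b]]), TRUE)), TRUE)
  groups <- groups[keep]
  lab <- stats::setNames(rep("", m), ordered_models)
  for (gi in seq_along(groups))
    lab[groups[[gi]]] <- paste0(lab[groups[[gi]]], letters[gi])
  lab
}

#' @exportS3Method print comparison_report
print.comparison_report <- function(x, ...) {
  cat("Model comparison (", x$metric, "): ANOVA F = ", signif(x$anova_F, 4),
      ", p = ", format.pval(x$anova_p), "\n", sep = "")
  out <- data.frame(model = names(x$means), mean = as.numeric(x$means),
                    group = x$letters[names(x$means)])
  print(out, row.names = FALSE)
  if (x$dropped_repeats > 0)
    cat("dropped repeats with undefined metric:", x$dropped_repeats, "\n")
  invisible(x)
}

#' Prediction accuracy metrics
#'
#' `MSE = mean((y - yhat)^2)`; Pearson R is `cor(y, yhat)` (undefined for
#' zero-variance predictions, returned as `NA`).
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Named vector with `mse` and `r`.
#' @export
prediction_metrics <- function(y, yhat) {
  mse <- mean((y - yhat)^2)
  r <- if (stats::sd(yhat) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(y, yhat)
  c(mse = mse, r = r)
}
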