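#' Joint-learning marker selection for one trait
#'
#' The full selection stage: define phenotypic intervals by cluster-index
#' consensus, run the classification trio on the intervals and the
#' regression trio on the trait, and return every marker-set combination.
#'
#' @param Z Imputed genotype matrix (individuals x markers).
#' @param y Trait vector aligned with `Z` rows.
#' @param seed Seed for the FS trios.
#' @param method Clustering method for the intervals. Default `"WardWSD"`.
#' @param k Optional fixed interval count (consensus when `NULL`).
#' @param ... Passed to [fs_marker_sets()].
#' @return As [fs_marker_sets()], plus the `intervals` assignment.
#' @export
joint_marker_selection <- function(Z, y, seed = 1, method = "WardWSD",
                                   k = NULL, ...) {
  set.seed(seed)
  intervals <- define_intervals(y, method = method, k = k)
  sets <- fs_marker_sets(Z, y, intervals$labels, seed = seed, ...)
  sets$intervals <- intervals
  sets
}

#' Benchmark the single-kernel model with and without CR3 selection
#'
#' The joint-learning contrast: k-fold CV Pearson accuracy of the
#' single-kernel Gaussian model on all markers versus on the CR3-selected
#' subset. By default feature selection runs once on the full dataset and
#' CV follows on the reduced matrix (the protocol under evaluation, which
#' shares the selection step across folds); `nested = TRUE` refits the
#' selection inside every training fold for a leakage-free estimate.
#'
#' @param Z Genotype matrix.
#' @param y Trait vector.
#' @param seed Master seed (folds and FS).
#' @param k CV folds. Default 10.
#' @param repeats CV repeats. Default 1.
#' @param control [gp_control()] for the Gibbs chains.
#' @param nested Refit FS inside each training fold. Default `FALSE`.
#' @param method Interval clustering method.
#' @return List with the two `cv_result`s (`all`, `cr3`), mean Pearson
#'   accuracies, their ratio, the CR3 `marker_set` and the marker-reduction
#'   fraction.
#' @export
smgk_cr3_benchmark <- function(Z, y, seed = 1, k = 10, repeats = 1,
                               control = gp_control(iterations = 4000,
                                                    burnin = 500),
                               nested = FALSE, method = "WardWSD") {
  Z <- as.matrix(Z)
  plan <- cv_plan("kfold", k = k, repeats = repeats, seed = seed)
  cv_all <- run_cv(gp_model("smgk", control = control, label = "SM-GK"),
                   Z, y, plan)
  if (!nested) {
    sel <- joint_marker_selection(Z, y, seed = seed, method = method)
    cr3 <- sel$CR3
    if (length(cr3$markers) < 2)
      stop("CR3 selected fewer than two markers; cannot build a kernel")
    cv_cr3 <- run_cv(gp_model("smgk", control = control, markers = cr3,
                              label = "SM-GK/CR3"),
                     Z, y, plan)
  } else {
    cr3 <- NULL
    cv_cr3 <- run_cv_nested_cr3(Z, y, plan, control, method, seed)
  }
  r_all <- mean(cv_all$r, na.rm = TRUE)
  r_cr3 <- mean(cv_cr3$r, na.rm = TRUE)
  list(all = cv_all, cr3 = cv_cr3, r_all = r_all, r_cr3 = r_cr3,
       ratio = r_cr3 / r_all, cr3_set = cr3,
       reduction = if (!is.null(cr3))
         1 - length(cr3$markers) / ncol(Z))
}

# leakage-free variant: interval definition and both FS trios are refit on
# each training fold; the kernel is then built on the selected markers over
# all individuals and the fold predicted by response masking
run_cv_nested_cr3 <- function(Z, y, plan, control, method, seed) {
  folds <- make_folds(nrow(Z), plan)
  n <- nrow(Z)
  preds <- matrix(NA_real_, n, length(folds))
  fold_mse <- matrix(NA_real_, length(folds), plan$k)
  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    for (fi in sort(unique(fold))) {
      test <- which(fold == fi)
      train <- which(fold != fi)
      sel <- joint_marker_selection(Z[train, , drop = FALSE], y[train],
                                    seed = seed + r * 131L + fi,
                                    method = method)
      ids <- sel$CR3$markers
      if (length(ids) < 2) next
      Kk <- gaussian_kernel(Z[, ids, drop = FALSE], h = 1)
      y_m <- y
      y_m[test] <- NA_real_
      set.seed((plan$seed + 7919L * r + 104729L * fi) %% 2147483647L)
      fit <- fit_kernel_model(y_m, Kk, control = control)
      preds[test, r] <- fit$predictions[test]
      fold_mse[r, fi] <- mean((y[test] - preds[test, r])^2)
    }
  }
  r_stat <- apply(preds, 2, function(pv) {
    ok <- !is.na(pv)
    if (sum(ok) < 3 || stats::sd(pv[ok]) == 0) return(NA_real_)
    stats::cor(pv[ok], y[ok])
  })
  structure(list(label = "SM-GK/CR3 (nested)", predictions = preds,
                 r = r_stat, mse = fold_mse, n = n, classification = FALSE,
                 failures = character(0), plan = plan),
            class = "cv_result")
}

#' Simulate the breeding program and benchmark marker selection
#'
#' One end-to-end simulation experiment: run the breeding program, sample
#' `n` PYT lines, and either report the CR3 marker reduction or the full
#' accuracy contrast.
#'
#' @param n Sample size from the 10,000-line pool.
#' @param seed Seed controlling the program, the sampling and the CV.
#' @param cfg A [sim_config()].
#' @param what `"reduction"` (selection only) or `"benchmark"` (selection
#'   plus the CV contrast).
#' @param control Chain settings for the benchmark.
#' @param pool Optionally, a pre-simulated `sim_dataset` to reuse across
#'   sample sizes.
#' @return For `"reduction"`: list with `reduction`, `n_selected`,
#'   `n_markers`. For `"benchmark"`: the [smgk_cr3_benchmark()] result.
#' @export
simulation_experiment <- function(n = 100, seed = 1, cfg = sim_config(),
                                  what = c("reduction", "benchmark"),
                                  control = gp_control(iterations = 4000,
                                                       burnin = 500),
                                  pool = NULL) {
  what <- match.arg(what)
  if (is.null(pool)) pool <- run_breeding_program(cfg, seed = seed)
  smp <- sample_dataset(pool, n, seed = seed + 1L)
  if (what == "reduction") {
    sel <- joint_marker_selection(smp$G, smp$y, seed = seed)
    list(reduction = 1 - length(sel$CR3$markers) / ncol(smp$G),
         n_selected = length(sel$CR3$markers), n_markers = ncol(smp$G),
         sets = sel)
  } else {
    smgk_cr3_benchmark(smp$G, smp$y, seed = seed, control = control)
  }
}
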