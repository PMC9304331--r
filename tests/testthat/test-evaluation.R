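test_that("fold construction respects sizes, stratification and reproducibility", {
  plan <- cv_plan("kfold", k = 10, repeats = 3, seed = 42)
  folds <- make_folds(100, plan)
  expect_length(folds, 3)
  for (f in folds) expect_true(all(table(f) == 10))

  # every individual tested exactly once per repeat
  expect_true(all(vapply(folds, function(f) length(f) == 100, TRUE)))

  # LOO: n singleton folds
  loo <- make_folds(57, cv_plan("loo"))
  expect_length(loo, 1)
  expect_equal(sort(unique(loo[[1]])), 1:57)

  # stratification: 60/40 labels over 10 folds -> 6 and 4 per fold (+-1)
  labs <- rep(c("a", "b"), c(60, 40))
  sf <- make_folds(100, cv_plan("stratified", k = 10, repeats = 2, seed = 1),
                   labels = labs)
  for (f in sf) {
    counts <- table(f, labs)
    expect_true(all(abs(counts[, "a"] - 6) <= 1))
    expect_true(all(abs(counts[, "b"] - 4) <= 1))
  }

  # reproducible from the master seed
  expect_identical(make_folds(100, plan), make_folds(100, plan))
  expect_warning(make_folds(12, cv_plan("stratified", k = 10, repeats = 1,
                                        seed = 2),
                            labels = rep(c("a", "b"), c(9, 3))),
                 "best-effort")
})

test_that("metric arithmetic: oracle, mean predictor, scaling laws", {
  y <- c(0.1, 0.4, 0.9, 0.3)
  expect_equal(unname(prediction_metrics(y, y)), c(0, 1))
  m <- prediction_metrics(y, rep(mean(y), 4))
  expect_true(is.na(m["r"]))
  expect_equal(unname(m["mse"]), mean((y - mean(y))^2))
  yhat <- y + rnorm(4, 0, 0.1)
  m1 <- prediction_metrics(y, yhat)
  m2 <- prediction_metrics(2 * y, 2 * yhat)
  expect_equal(m2[["r"]], m1[["r"]])
  expect_equal(m2[["mse"]], 4 * m1[["mse"]])
})

test_that("run_cv evaluates kernel and ML models fold by fold", {
  set.seed(70)
  n <- 60; p <- 40
  Z <- random_genotypes(n, p, seed = 70)
  y <- as.numeric(Z %*% rnorm(p, 0, 0.4)); y <- y + rnorm(n, 0, 0.3 * sd(y))
  plan <- cv_plan("kfold", k = 5, repeats = 2, seed = 3)

  cv_k <- run_cv(gp_model("smgk",
                          control = gp_control(iterations = 2000,
                                               burnin = 300)),
                 Z, y, plan)
  expect_equal(dim(cv_k$predictions), c(n, 2))
  expect_false(anyNA(cv_k$predictions))
  expect_gt(mean(cv_k$r), 0.3)

  cv_b <- run_cv(gp_model("brr",
                          control = gp_control(iterations = 2000,
                                               burnin = 300)),
                 Z, y, plan)
  expect_gt(mean(cv_b$r), 0.3)

  cv_ml <- run_cv(ml_config("knn", "regression", seed = 1), Z, y, plan)
  expect_true(all(is.finite(cv_ml$r)))

  # determinism under the master seed
  cv_k2 <- run_cv(gp_model("smgk",
                           control = gp_control(iterations = 2000,
                                                burnin = 300)),
                  Z, y, plan)
  expect_identical(cv_k$predictions, cv_k2$predictions)
})

test_that("non-nested selection inflates accuracy on pure noise relative to nested", {
  set.seed(71)
  n <- 60; p <- 300
  Z <- random_genotypes(n, p, seed = 71, values = c(0, 0.5, 1))
  y <- rnorm(n)  # no signal at all
  ctl <- gp_control(iterations = 1500, burnin = 300)
  plain <- smgk_cr3_benchmark(Z, y, seed = 4, k = 5, control = ctl)
  nested <- smgk_cr3_benchmark(Z, y, seed = 4, k = 5, control = ctl,
                               nested = TRUE)
  expect_gt(plain$r_cr3, mean(nested$cr3$r, na.rm = TRUE))
  # the leak produces spuriously positive accuracy
  expect_gt(plain$r_cr3, 0.2)
})

test_that("ANOVA + Tukey comparison matches hand computation and letters group sanely", {
  # textbook fixture: three groups, known sums of squares
  make_res <- function(vals, label) {
    structure(list(label = label, predictions = NULL,
                   r = vals, mse = matrix(vals, length(vals), 1),
                   n = 10, classification = FALSE, failures = character(0),
                   plan = cv_plan()),
              class = "cv_result")
  }
  g1 <- c(0.50, 0.52, 0.48, 0.51, 0.49)
  g2 <- c(0.51, 0.49, 0.52, 0.50, 0.48)
  g3 <- c(0.80, 0.82, 0.78, 0.81, 0.79)
  rep_ <- compare_models(list(make_res(g1, "A"), make_res(g2, "B"),
                              make_res(g3, "C")), metric = "r")
  # brute-force one-way ANOVA F
  vals <- c(g1, g2, g3); grp <- rep(1:3, each = 5)
  gm <- tapply(vals, grp, mean)
  ssb <- sum(5 * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  F_hand <- (ssb / 2) / (ssw / 12)
  expect_equal(rep_$anova_F, F_hand, tolerance = 1e-10)
  # C in its own letter group, A and B sharing one
  expect_equal(rep_$letters[["C"]], "a")
  expect_equal(rep_$letters[["A"]], rep_$letters[["B"]])
  expect_false(rep_$letters[["A"]] == rep_$letters[["C"]])

  # identical results: a single shared letter
  same <- compare_models(list(make_res(g1, "A"), make_res(g1, "B")),
                         metric = "r")
  expect_equal(unname(same$letters), c("a", "a"))

  # Tukey p-value against the studentized-range closed form for C vs A
  mse_w <- ssw / 12
  q_obs <- abs(gm[3] - gm[1]) / sqrt(mse_w / 5)
  p_hand <- stats::ptukey(q_obs, 3, 12, lower.tail = FALSE)
  expect_equal(unname(rep_$tukey["C-A", "p adj"]), unname(p_hand),
               tolerance = 1e-8)
})
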