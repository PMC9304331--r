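test_that("the RBF free parameter follows theta = 1/(p * var(Z))", {
  Z <- matrix(c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1), 2, 5)
  expect_equal(rbf_theta(Z), 1 / (5 * var(as.vector(Z))))
  # shuffling entries leaves the pooled variance, hence theta, unchanged
  Zs <- matrix(sample(as.vector(Z)), 2, 5)
  expect_equal(rbf_theta(Zs), rbf_theta(Z))
  # printed-arithmetic case: p = 10, var = 0.05 -> theta = 2
  expect_equal(1 / (10 * 0.05), 2)
})

test_that("regression predictors handle null and planted signal sanely", {
  set.seed(50)
  n <- 40; p <- 15
  Z <- random_genotypes(n, p, seed = 50)
  y <- as.numeric(Z %*% c(3, -2, rep(0, p - 2))) + rnorm(n, 0, 0.1)

  for (alg in c("knn", "svm", "rf", "adaboost")) {
    cfg <- ml_config(alg, "regression", seed = 7)
    m <- fit_predictor(cfg, Z, y)
    pr <- predict(m, Z)
    expect_length(pr, n)
    expect_true(all(is.finite(pr)))
    # constant target: every algorithm returns that constant on training rows
    mc <- fit_predictor(cfg, Z, rep(0.4, n))
    expect_equal(unname(predict(mc, Z)), rep(0.4, n), tolerance = 0.11)
  }

  # RF with deep trees overfits training data to near-zero MSE
  rf <- fit_predictor(ml_config("rf", "regression", seed = 3), Z, y)
  expect_lt(mean((predict(rf, Z) - y)^2), 0.25 * var(y))

  # row permutation of prediction input permutes outputs identically
  svm <- fit_predictor(ml_config("svm", "regression", seed = 3), Z, y)
  pi_ <- sample(n)
  expect_equal(predict(svm, Z[pi_, ]), predict(svm, Z)[pi_])
})

test_that("KNN with unanimous duplicated neighbors predicts their value", {
  Z <- matrix(rep(c(0.2, 0.8), each = 5), 10, 1)
  rownames(Z) <- paste0("I", 1:10); colnames(Z) <- "m"
  y <- rep(c(1, 0), each = 5)
  m <- fit_predictor(ml_config("knn", "regression", k = 5, seed = 1), Z, y)
  expect_equal(unname(predict(m, matrix(0.2, 1, 1))), 1)
  expect_error(fit_predictor(ml_config("knn", "regression", k = 50), Z, y),
               "k exceeds")
})

test_that("classifiers fit, predict labels from the training set, and reject one class", {
  set.seed(51)
  n <- 60; p <- 10
  Z <- random_genotypes(n, p, seed = 51)
  labs <- ifelse(Z[, 1] + 0.3 * rnorm(n) > 0.5, "high", "low")
  for (alg in c("svm", "rf", "mlp", "gnb")) {
    cfg <- ml_config(alg, "classification", seed = 5)
    m <- fit_predictor(cfg, Z, labs)
    pr <- predict(m, Z)
    expect_true(all(as.character(pr) %in% c("high", "low")))
    expect_gt(mean(as.character(pr) == labs), 0.6)
    expect_error(fit_predictor(cfg, Z, rep("x", n)), "single class")
  }
  # column mismatch is caught
  m <- fit_predictor(ml_config("gnb", "classification", seed = 5), Z, labs)
  expect_error(predict(m, Z[, 1:3]), "markers")
})

test_that("GNB achieves perfect training accuracy on gap-separated 1-D classes", {
  Z <- matrix(c(seq(0, 0.2, length.out = 10),
                seq(0.8, 1, length.out = 10)), 20, 1,
              dimnames = list(paste0("I", 1:20), "m"))
  labs <- rep(c("a", "b"), each = 10)
  m <- fit_predictor(ml_config("gnb", "classification", seed = 1), Z, labs)
  expect_equal(as.character(predict(m, Z)), labs)
})

test_that("predictors are pure functions of config, data and seed", {
  Z <- random_genotypes(30, 12, seed = 52)
  y <- rnorm(30)
  for (alg in c("rf", "adaboost")) {
    cfg <- ml_config(alg, "regression", seed = 21)
    p1 <- predict(fit_predictor(cfg, Z, y), Z)
    p2 <- predict(fit_predictor(cfg, Z, y), Z)
    expect_identical(p1, p2)
  }
})
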