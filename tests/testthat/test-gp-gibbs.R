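# Oracle checks for the Gibbs samplers: with variance components frozen the
# posterior means have closed forms (ridge for marker effects, mixed-model
# BLUP with a flat intercept for kernel models).

ridge_oracle <- function(y, Z, lambda) {
  Zc <- scale(Z, scale = FALSE)
  as.numeric(solve(crossprod(Zc) + diag(lambda, ncol(Z)),
                   crossprod(Zc, y - mean(y))))
}

blup_oracle <- function(y, K, s2g, s2e) {
  n <- length(y)
  V <- s2g * K + diag(s2e, n)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  g <- as.numeric(s2g * K %*% Vi %*% (y - mu))
  list(mu = mu, g = g, pred = mu + g)
}

test_that("fixed-variance BRR matches the closed-form ridge solution", {
  set.seed(31)
  n <- 80; p <- 50
  Z <- random_genotypes(n, p, seed = 31)
  y <- as.numeric(Z %*% rnorm(p, 0, 0.3)) + rnorm(n, 0, 0.4)
  s2g <- 0.09; s2e <- 0.16
  fit <- fit_brr(y, Z, gp_control(iterations = 20000, burnin = 2000,
                                  fix_variances = c(s2g, s2e), seed = 1))
  oracle <- ridge_oracle(y, Z, s2e / s2g)
  expect_lt(max(abs(fit$effects - oracle)) / sd(y), 0.02)
  expect_equal(fit$var_genetic, s2g)
})

test_that("BRR handles null and simulated-signal regimes", {
  set.seed(32)
  Z <- random_genotypes(60, 30, seed = 32)
  # constant response: effects shrink to zero, intercept to the constant
  yc <- rep(0.7, 60)
  fit0 <- fit_brr(yc, Z, gp_control(iterations = 3000, burnin = 500, seed = 2))
  expect_lt(max(abs(fit0$effects)), 0.05)
  expect_equal(fit0$mu, 0.7, tolerance = 0.05)
  expect_error(fit_brr(c(1, NA), Z[1:2, ], gp_control(2000, 100)), "finite")

  # parameter recovery at h2 = 0.8
  n <- 200; p <- 100
  Z2 <- random_genotypes(n, p, seed = 33)
  gt <- as.numeric(Z2 %*% rnorm(p, 0, 0.3))
  gt <- gt * sqrt(0.8 / var(gt))
  y <- gt + rnorm(n, 0, sqrt(0.2))
  fit <- fit_brr(y, Z2, gp_control(iterations = 5000, burnin = 1000, seed = 3))
  expect_gt(cor(fit$fitted, gt), 0.8)
})

test_that("fixed-variance kernel model matches the BLUP oracle", {
  set.seed(34)
  n <- 70
  Z <- random_genotypes(n, 40, seed = 34)
  y <- as.numeric(Z %*% rnorm(40, 0, 0.3)) + rnorm(n, 0, 0.4)
  K <- gaussian_kernel(Z, h = 5, scale = "median")  # contrastive kernel
  s2g <- 0.5 * var(y); s2e <- 0.5 * var(y)
  fit <- fit_kernel_model(y, K, gp_control(iterations = 20000, burnin = 2000,
                                           fix_variances = c(s2g, s2e),
                                           seed = 4))
  oracle <- blup_oracle(y, K, s2g, s2e)
  expect_lt(max(abs(fit$predictions - oracle$pred)) / sd(y), 0.02)
  expect_lt(max(abs(fit$genetic_values - oracle$g)) / sd(y), 0.02)
})

test_that("three identical kernels predict like one with the summed variance", {
  set.seed(35)
  n <- 50
  Z <- random_genotypes(n, 30, seed = 35)
  y <- as.numeric(Z %*% rnorm(30, 0, 0.3)) + rnorm(n, 0, 0.3)
  K <- gaussian_kernel(Z, h = 5, scale = "median")
  s2g <- 0.6 * var(y); s2e <- 0.4 * var(y)
  multi <- fit_kernel_model(y, list(K, K, K),
                            gp_control(iterations = 15000, burnin = 2000,
                                       fix_variances = c(s2g, s2e), seed = 5))
  single <- blup_oracle(y, K, s2g, s2e)
  expect_lt(max(abs(multi$predictions - single$pred)) / sd(y), 0.03)
})

test_that("identical genotype rows get identical predictions", {
  set.seed(36)
  Z <- random_genotypes(30, 20, seed = 36)
  Z[2, ] <- Z[1, ]
  y <- as.numeric(Z %*% rnorm(20, 0, 0.4)) + rnorm(30, 0, 0.3)
  y[2] <- y[1]
  K <- gaussian_kernel(Z, h = 1)
  fit <- fit_kernel_model(y, K, gp_control(iterations = 6000, burnin = 1000,
                                           seed = 6))
  expect_equal(fit$predictions[1], fit$predictions[2], tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("masked prediction follows the BLUP limit and rejects degenerate masks", {
  set.seed(37)
  n <- 60
  Z <- random_genotypes(n, 30, seed = 37)
  y <- as.numeric(Z %*% rnorm(30, 0, 0.4)) + rnorm(n, 0, 0.2)
  K <- gaussian_kernel(Z, h = 5, scale = "median")
  expect_error(predict_masked(y, K), "no masked")
  expect_error(predict_masked(rep(NA_real_, n), K), "all entries masked")

  # duplicated test individual approaches the training value as s2e -> 0
  Zdup <- rbind(Z, Z[1, , drop = FALSE])
  rownames(Zdup)[n + 1] <- "dup"
  Kd <- gaussian_kernel(Zdup, h = 5, scale = "median")
  ym <- c(y, NA)
  pr <- predict_masked(ym, Kd,
                       gp_control(iterations = 8000, burnin = 1000,
                                  fix_variances = c(var(y), 1e-4 * var(y)),
                                  seed = 7))
  expect_equal(unname(pr), y[1], tolerance = 0.05 * sd(y))
})

test_that("variance partition is recovered on model-true data", {
  # genotypes with family structure give the kernel an informative
  # eigenvalue spread; unstructured uniform genotypes leave the partition
  # weakly identified
  cfg <- sim_config(chromosomes = 4, snps_per_chrom = 150,
                    qtl_per_chrom = 10, founders = 20, burnin_years = 4,
                    record_years = 4, families = 16, family_size = 35,
                    select_per_family = 10, n_ayt = 20, n_eyt = 5)
  ds <- run_breeding_program(cfg, seed = 91)
  n <- 500
  s <- sample_dataset(ds, n, seed = 1)
  K <- gaussian_kernel(s$G, h = 1)
  ev <- eigen(K, symmetric = TRUE)
  h2 <- 0.8
  set.seed(301)
  g <- ev$vectors %*% (sqrt(pmax(ev$values, 0) * h2) * rnorm(n))
  y <- as.numeric(g) + rnorm(n, 0, sqrt(1 - h2))
  fit <- fit_kernel_model(y, K, gp_control(iterations = 6000, burnin = 1000,
                                           seed = 8))
  h2_hat <- fit$var_genetic / (fit$var_genetic + fit$var_residual)
  expect_lt(abs(h2_hat - h2), 0.15)
})

test_that("chains are bit-for-bit reproducible under a fixed seed", {
  Z <- random_genotypes(40, 25, seed = 39)
  y <- rowSums(Z[, 1:5]) + rnorm(40, 0, 0.5)
  ctl <- gp_control(iterations = 2000, burnin = 200, seed = 11)
  f1 <- fit_brr(y, Z, ctl)
  f2 <- fit_brr(y, Z, ctl)
  expect_identical(f1$effects, f2$effects)
  K <- gaussian_kernel(Z, h = 1)
  k1 <- fit_kernel_model(y, K, ctl)
  k2 <- fit_kernel_model(y, K, ctl)
  expect_identical(k1$predictions, k2$predictions)
})

test_that("rank-deficient fixed-effect blocks are rejected with the culprits named", {
  Z <- random_genotypes(30, 10, seed = 40)
  y <- rnorm(30)
  K <- gaussian_kernel(Z, h = 1)
  X <- cbind(a = Z[, 1], b = Z[, 1])  # collinear
  expect_error(fit_kernel_model(y, K, gp_control(1000, 100), X = X),
               "rank deficient")
})

test_that("fixed-effect marker blocks shift predictions by X alpha", {
  set.seed(41)
  n <- 60
  Z <- random_genotypes(n, 30, seed = 41)
  X <- Z[, 1:2]
  y <- as.numeric(X %*% c(2, -1.5)) + rnorm(n, 0, 0.3)
  K <- gaussian_kernel(Z[, -(1:2)], h = 1)
  fit <- fit_kernel_model(y, K, gp_control(iterations = 6000, burnin = 1000,
                                           seed = 9), X = X)
  expect_equal(unname(fit$alpha), c(2, -1.5), tolerance = 0.4)
  expect_gt(cor(fit$predictions, y), 0.9)
})
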