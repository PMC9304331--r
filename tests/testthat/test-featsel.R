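test_that("planted signal earns three votes; constant markers earn none", {
  set.seed(60)
  n <- 120; p <- 201
  Z <- random_genotypes(n, p, seed = 60, values = c(0, 0.5, 1))
  Z[, 201] <- 0.5  # constant marker
  y <- Z[, 1] + rnorm(n, 0, 0.15)
  vr <- fs_votes_regression(Z, y, seed = 1)
  expect_equal(vr$votes[1], 3)
  expect_equal(vr$votes[201], 0)

  labs <- ifelse(Z[, 1] >= 0.5, 2, 1)
  vc <- fs_votes_classification(Z, labs, seed = 1)
  expect_equal(vc$votes[1], 3)
  expect_equal(vc$votes[201], 0)

  # determinism given (data, seed)
  vr2 <- fs_votes_regression(Z, y, seed = 1)
  expect_identical(vr$votes, vr2$votes)

  expect_error(fs_votes_regression(Z, rep(1, n)), "constant")
  expect_error(fs_votes_classification(Z, rep(1, n)), "two")
})

test_that("univariate screens hold their 5% size on pure noise", {
  p <- 250; n <- 60
  frac_anova <- frac_pearson <- numeric(20)
  for (s in 1:20) {
    Z <- random_genotypes(n, p, seed = 600 + s, values = c(0, 0.5, 1))
    set.seed(6000 + s)
    y <- rnorm(n)
    labs <- rep(1:3, length.out = n)
    frac_pearson[s] <- mean(jointgp:::pearson_pvalues(Z, y) < 0.05)
    frac_anova[s] <- mean(jointgp:::anova_f_pvalues(Z, factor(labs)) < 0.05)
  }
  ci <- 1.96 * sqrt(0.05 * 0.95 / (20 * p))
  expect_lt(abs(mean(frac_pearson) - 0.05), ci + 0.005)
  expect_lt(abs(mean(frac_anova) - 0.05), ci + 0.005)
})

test_that("vote thresholding and set algebra follow the definitions", {
  votes <- data.frame(marker = c("m1", "m2", "m3"),
                      l1 = c(TRUE, TRUE, TRUE),
                      univariate = c(TRUE, TRUE, FALSE),
                      gtb = c(TRUE, FALSE, FALSE))
  votes$votes <- votes$l1 + votes$univariate + votes$gtb
  attr(votes, "task") <- "classification"
  class(votes) <- c("fs_votes", class(votes))
  C2 <- threshold_votes(votes, 2)
  C3 <- threshold_votes(votes, 3)
  expect_equal(C2$markers, c("m1", "m2"))
  expect_equal(C3$markers, "m1")
  expect_equal(C2$name, "C2"); expect_equal(C3$name, "C3")

  rvotes <- votes
  attr(rvotes, "task") <- "regression"
  rvotes$gtb <- c(FALSE, TRUE, TRUE); rvotes$l1 <- c(FALSE, TRUE, TRUE)
  rvotes$votes <- rvotes$l1 + rvotes$univariate + rvotes$gtb
  R2 <- threshold_votes(rvotes, 2)
  R3 <- threshold_votes(rvotes, 3)
  expect_equal(combine_marker_sets(C2, R2, "ICR2")$markers, "m2")
  expect_equal(sort(combine_marker_sets(C2, R2, "CR2")$markers),
               c("m1", "m2", "m3"))
  # union with empty: CR3 from C3 = {m1}, R3 = {m2}
  expect_equal(sort(combine_marker_sets(C3, R3, "CR3")$markers),
               c("m1", "m2"))

  # all-zero votes: empty set with a warning, not an error
  zv <- votes; zv$l1 <- zv$univariate <- zv$gtb <- FALSE; zv$votes <- 0L
  expect_warning(z <- threshold_votes(zv, 3), "empty")
  expect_length(z$markers, 0)

  other <- marker_set("R2", "x1", universe = c("x1", "x2"))
  expect_error(combine_marker_sets(C2, other, "CR2"), "universe")
})

test_that("subset invariants hold on planted-signal runs", {
  set.seed(61)
  n <- 80; p <- 150
  Z <- random_genotypes(n, p, seed = 61, values = c(0, 0.5, 1))
  y <- rowSums(Z[, 1:4]) + rnorm(n, 0, 0.4)
  labs <- cut(y, quantile(y, c(0, 0.5, 1)), include.lowest = TRUE,
              labels = FALSE)
  sets <- fs_marker_sets(Z, y, labs, seed = 2)
  expect_true(all(sets$C3$markers %in% sets$C2$markers))
  expect_true(all(sets$R3$markers %in% sets$R2$markers))
  expect_setequal(sets$ICR2$markers,
                  intersect(sets$C2$markers, sets$R2$markers))
  expect_setequal(sets$CR2$markers, union(sets$C2$markers, sets$R2$markers))
  expect_true(all(sets$CR3$markers %in% sets$CR2$markers))
})

test_that("marker-set TSV export records votes and memberships", {
  set.seed(62)
  Z <- random_genotypes(50, 60, seed = 62, values = c(0, 0.5, 1))
  y <- Z[, 3] + rnorm(50, 0, 0.2)
  labs <- ifelse(y > median(y), 2, 1)
  sets <- fs_marker_sets(Z, y, labs, seed = 3)
  tf <- tempfile(fileext = ".tsv")
  write_marker_sets(sets, tf)
  out <- read.delim(tf)
  expect_equal(nrow(out), 60)
  expect_true(all(c("votes_classification", "votes_regression", "CR3") %in%
                    names(out)))
  expect_setequal(out$marker[out$CR3], sets$CR3$markers)
})
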