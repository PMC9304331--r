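# a small genome / small program configuration keeps these tests fast
small_cfg <- function(...) {
  args <- list(chromosomes = 4, snps_per_chrom = 150, qtl_per_chrom = 10,
               founders = 20, burnin_years = 3, record_years = 3,
               families = 12, family_size = 30, select_per_family = 5,
               n_ayt = 15, n_eyt = 4)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("founders are fully homozygous with polymorphic sites", {
  cfg <- small_cfg()
  set.seed(80)
  H <- simulate_founders(cfg)
  expect_equal(dim(H), c(20, 600))
  expect_true(all(H %in% c(0L, 1L)))
  freq <- colMeans(H)
  expect_true(all(freq > 0 & freq < 1))  # strictly inside (0, 1)
  # full-scale layout: 21 chromosomes x 1000 SNPs
  expect_equal(21 * 1000, sim_config()$chromosomes * sim_config()$snps_per_chrom)
})

test_that("doubled haploids are homozygous recombinants of the parents", {
  cfg <- small_cfg()
  L <- 600
  p1 <- rep(0L, L); p2 <- rep(2L, L)
  set.seed(81)
  off <- cross_and_dh(p1, p2, 50, cfg)
  expect_true(all(off %in% c(0L, 2L)))       # never heterozygous
  # mosaics: most offspring carry both parental blocks
  both <- mean(apply(off, 1, function(r) any(r == 0) && any(r == 2)))
  expect_gt(both, 0.9)
  # selfing a homozygous parent reproduces it exactly
  self <- cross_and_dh(p2, p2, 5, cfg)
  expect_true(all(self == 2L))
  expect_error(cross_and_dh(rep(1L, L), p2, 5, cfg), "homozygous")

  # offspring mean breeding value matches the parental midpoint
  set.seed(82)
  H <- simulate_founders(cfg)
  qtl <- jointgp:::sample_qtl_map(cfg)
  o2 <- cross_and_dh(2L * H[1, ], 2L * H[2, ], 2000, cfg)
  tbv <- as.numeric((o2[, qtl$snp] %*% qtl$effect))
  midpoint <- mean(c(2 * sum(H[1, qtl$snp] * qtl$effect),
                     2 * sum(H[2, qtl$snp] * qtl$effect)))
  expect_equal(mean(tbv), midpoint, tolerance = 0.02 * abs(midpoint))
})

test_that("the breeding program yields the recorded PYT pool with gain and stated heritability", {
  cfg <- small_cfg(burnin_years = 4, record_years = 5)
  ds <- run_breeding_program(cfg, seed = 83)
  n_pyt <- cfg$families * cfg$select_per_family
  expect_equal(length(ds$tbv), n_pyt * 5)
  expect_equal(dim(ds$haplotypes[[1]]), c(n_pyt, 600))
  expect_equal(ds$year, rep(1:5, each = n_pyt))

  # response to selection: upward trend of mean true breeding value
  ym <- tapply(ds$tbv, ds$year, mean)
  expect_gt(unname(ym[5] - ym[1]), 0)
  expect_gt(cor(seq_along(ym), ym), 0.7)

  # realized within-year heritability near the stated PYT value
  h2 <- vapply(1:5, function(yr) {
    i <- ds$year == yr
    var(ds$tbv[i]) / var(ds$pheno_pyt[i])
  }, numeric(1))
  expect_lt(abs(mean(h2) - cfg$h2_pyt), 0.08)

  # determinism under (cfg, seed)
  ds2 <- run_breeding_program(cfg, seed = 83)
  expect_identical(ds$tbv, ds2$tbv)
  expect_identical(ds$pheno_pyt, ds2$pheno_pyt)
})

test_that("sampling rescales codes to allele proportions and respects bounds", {
  cfg <- small_cfg()
  ds <- run_breeding_program(cfg, seed = 84)
  pool <- length(ds$tbv)
  s <- sample_dataset(ds, 50, seed = 1)
  expect_equal(dim(s$G), c(50, 600))
  expect_true(all(s$G %in% c(0, 1)))  # doubled haploids: no 0.5 codes
  expect_equal(range(s$y), c(0, 1))
  expect_error(sample_dataset(ds, pool + 1), "pool")

  # full-pool draw is a permutation of the pool
  sall <- sample_dataset(ds, pool, seed = 2)
  expect_setequal(sall$idx, seq_len(pool))
  # different seeds give different subsets, same dimensions
  sa <- sample_dataset(ds, 30, seed = 3); sb <- sample_dataset(ds, 30, seed = 4)
  expect_false(identical(sort(sa$idx), sort(sb$idx)))
  # large-sample trait variance tracks the pool variance
  big <- sample_dataset(ds, round(0.9 * pool), seed = 5)
  expect_equal(var(big$y_raw), var(ds$pheno_pyt), tolerance = 0.15 * var(ds$pheno_pyt))
})

test_that("QTL count per chromosome drives the causal-locus count", {
  cfg2 <- small_cfg(qtl_per_chrom = 2)
  set.seed(85)
  qtl <- jointgp:::sample_qtl_map(cfg2)
  expect_equal(nrow(qtl), 2 * 4)
  cfg_all <- small_cfg(qtl_per_chrom = 150)
  set.seed(85)
  qtl_all <- jointgp:::sample_qtl_map(cfg_all)
  expect_equal(sort(unique(qtl_all$snp)), 1:600)  # every SNP causal
})
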