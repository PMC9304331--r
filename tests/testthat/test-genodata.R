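test_that("allele-proportion encoding applies the depth filter and drops multi-allelic sites", {
  tab <- toy_depth_table()
  g <- encode_allele_proportions(tab, min_depth = 50)
  # multi-allelic m4 excluded
  expect_equal(sort(colnames(g)), c("m1", "m2", "m3"))
  expect_equal(rownames(g), paste0("I", 1:4))
  # (ref 30, alt 30) -> 0.5; (ref 50, alt 0) -> 1.0
  expect_equal(g["I1", "m1"], 0.5)
  expect_equal(g["I2", "m1"], 1.0)
  # total depth 45 < 50 -> missing
  expect_true(is.na(g["I3", "m1"]))
  # zero total depth -> missing, not an error
  expect_true(is.na(g["I1", "m3"]))
  # depth 55 -> 55/55
  expect_equal(g["I2", "m3"], 1.0)
})

test_that("missingness filter and mean imputation behave as specified", {
  g <- matrix(c(0.5, NA, 1.0,
                0.2, 0.4, 0.6,
                NA, NA, 0.8,
                0.5, 0.5, 0.5), 3, 4,
              dimnames = list(paste0("I", 1:3), paste0("m", 1:4)))
  out <- filter_and_impute(g, max_missing = 0.25)
  # m1 has 1/3 = 0.33 > 0.25 missing -> dropped; m3 has 2/3 -> dropped;
  # m4 constant -> dropped
  expect_equal(colnames(out), "m2")
  expect_false(anyNA(out))

  # imputation preserves the marker mean exactly
  g2 <- matrix(c(0.5, NA, 1.0, 0.75), 4, 1,
               dimnames = list(paste0("I", 1:4), "mk"))
  out2 <- filter_and_impute(g2, max_missing = 0.5)
  expect_equal(out2["I2", "mk"], 0.75)
  expect_equal(mean(out2), mean(g2, na.rm = TRUE))

  expect_error(filter_and_impute(matrix(NA_real_, 3, 1,
                                        dimnames = list(1:3, "m")),
                                 max_missing = 0.25),
               "no markers left")
})

test_that("encode-filter-impute is idempotent on its own output", {
  set.seed(5)
  g <- random_genotypes(20, 30, seed = 5)
  g[sample(length(g), 50)] <- NA
  once <- filter_and_impute(g)
  twice <- filter_and_impute(once)
  expect_equal(once, twice)
})

test_that("min-max normalization follows the closed form and its invariances", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.3, 0.7, 1)
  expect_equal(minmax_normalize(v), v)  # already spanning [0,1]
  expect_error(minmax_normalize(c(5, 5, 5)), "constant")
  # affine invariance: f(a v + b) = f(v), a > 0
  set.seed(1)
  v <- rnorm(50)
  expect_equal(minmax_normalize(3.7 * v + 11), minmax_normalize(v))
  # order preserving
  expect_equal(order(minmax_normalize(v)), order(v))
})

test_that("TSV round trip preserves the matrix and flags bad cells", {
  g <- random_genotypes(5, 8, seed = 2)
  g[2, 3] <- NA
  tf <- tempfile(fileext = ".tsv")
  write_genotypes(g, tf)
  g2 <- read_genotypes(tf, format = "tsv")
  expect_equal(g2, g)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("marker\tI1\tI2", "m1\t0.5\toops", "m2\t0.1\t0.9"), bad)
  expect_error(read_genotypes(bad, format = "tsv"), "non-numeric")
})

test_that("VCF route extracts allelic depths and flags multi-allelic records", {
  skip_if_not_installed("VariantAnnotation")
  vf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  tab <- read_genotypes(vf, format = "vcf")
  expect_s3_class(tab, "raw_genotype_table")
  expect_equal(nrow(tab$markers), 3)
  expect_equal(tab$individuals, c("S1", "S2"))
  expect_equal(tab$markers$multiallelic, c(FALSE, FALSE, TRUE))
  expect_equal(tab$ref_depth["v1", "S1"], 30)
  expect_equal(tab$alt_depth["v3", "S1"], 20)  # sum of the two ALT depths
  g <- encode_allele_proportions(tab, min_depth = 50)
  expect_equal(colnames(g), c("v1", "v2"))
  expect_equal(g["S1", "v1"], 0.5)
  expect_true(is.na(g["S1", "v2"]))  # depth 45 < 50
})

test_that("phenotype alignment keeps the genotype ordering", {
  g <- random_genotypes(4, 3, seed = 3)
  ph <- data.frame(id = c("I3", "I1", "I9"), trait = c(3, 1, 9))
  al <- align_genotypes_phenotypes(g, ph)
  expect_equal(rownames(al$g), c("I1", "I3"))
  expect_equal(al$pheno$trait, c(1, 3))
})
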