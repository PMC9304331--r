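#' Configuration of the simplified breeding-program simulator
#'
#' Emulates a line-breeding (wheat-type) program: a 21-chromosome genome
#' with 1000 SNPs per chromosome, yield controlled by a configurable number
#' of additive QTLs per chromosome with effects drawn from Normal(4, 0.1),
#' 70 inbred founders, and 20 years of phenotypic selection (first 10
#' burn-in). Each year 100 biparental families of 100 doubled haploids are
#' evaluated in a nursery (h2 = 0.1, best 10 per family advance), a
#' preliminary yield trial (PYT, h2 = 0.2, best 100 advance), an advanced
#' yield trial (AYT, h2 = 0.5, best 10 advance) and an elite yield trial
#' (EYT, h2 = 0.67). Genotype-by-environment variance 0.2 and environmental
#' variance 0.4 are expressed relative to the founder genetic variance;
#' each stage's environmental noise is scaled so its heritability
#' (`H2 = var_g / (var_g + var_gxe + var_e)` against the founder genetic
#' variance) matches the stated value.
#'
#' @param chromosomes,snps_per_chrom Genome layout. Defaults 21 x 1000.
#' @param qtl_per_chrom QTLs per chromosome (2, 10, 100 or 1000 in the
#'   study design). Default 100.
#' @param qtl_effect_mean,qtl_effect_var Additive-effect distribution.
#'   Defaults 4 and 0.1.
#' @param env_var,gxe_var Environmental and GxE variance, relative to the
#'   founder genetic variance. Defaults 0.4 and 0.2.
#' @param founders Number of inbred founders. Default 70.
#' @param burnin_years,record_years Years discarded / recorded. Defaults
#'   10 and 10.
#' @param families,family_size Biparental crosses per year and DH per
#'   cross. Defaults 100 and 100.
#' @param select_per_family Nursery survivors per family. Default 10.
#' @param n_ayt,n_eyt Lines advanced to AYT / EYT. Defaults 100 and 10.
#' @param h2_nursery,h2_pyt,h2_ayt,h2_eyt Stage heritabilities. Defaults
#'   0.1, 0.2, 0.5, 0.67.
#' @return A `sim_config`.
#' @export
sim_config <- function(chromosomes = 21, snps_per_chrom = 1000,
                       qtl_per_chrom = 100, qtl_effect_mean = 4,
                       qtl_effect_var = 0.1, env_var = 0.4, gxe_var = 0.2,
                       founders = 70, burnin_years = 10, record_years = 10,
                       families = 100, family_size = 100,
                       select_per_family = 10, n_ayt = 100, n_eyt = 10,
                       h2_nursery = 0.1, h2_pyt = 0.2, h2_ayt = 0.5,
                       h2_eyt = 0.67) {
  stopifnot(qtl_per_chrom <= snps_per_chrom, qtl_per_chrom >= 1,
            env_var >= 0, gxe_var >= 0, qtl_effect_var >= 0,
            select_per_family <= family_size,
            n_ayt <= families * select_per_family)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate founder haplotypes
#'
#' Creates fully homozygous founder lines (one haplotype each). Per-site
#' derived-allele counts are drawn from a neutral-like 1/i frequency
#' spectrum over 1..(founders-1) carriers, so every site is polymorphic
#' with frequency strictly inside (0, 1).
#'
#' @param cfg A [sim_config()].
#' @return Integer haplotype matrix, founders x (chromosomes *
#'   snps_per_chrom), entries 0/1.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$chromosomes * cfg$snps_per_chrom
  nf <- cfg$founders
  counts <- sample(seq_len(nf - 1), L, replace = TRUE,
                   prob = 1 / seq_len(nf - 1))
  H <- matrix(0L, nf, L)
  for (j in seq_len(L)) H[sample.int(nf, counts[j]), j] <- 1L
  colnames(H) <- paste0("M", seq_len(L))
  rownames(H) <- paste0("F", seq_len(nf))
  H
}

sample_qtl_map <- function(cfg) {
  idx <- unlist(lapply(seq_len(cfg$chromosomes), function(cc) {
    (cc - 1) * cfg$snps_per_chrom +
      sort(sample.int(cfg$snps_per_chrom, cfg$qtl_per_chrom))
  }))
  data.frame(chrom = rep(seq_len(cfg$chromosomes), each = cfg$qtl_per_chrom),
             snp = idx,
             effect = rnorm(length(idx), cfg$qtl_effect_mean,
                            sqrt(cfg$qtl_effect_var)))
}

# true breeding value of homozygous lines from their haplotypes:
# genotype code = 2 * haplotype allele
tbv_of <- function(hap, qtl) {
  2 * as.numeric(hap[, qtl$snp, drop = FALSE] %*% qtl$effect)
}

#' Cross two homozygous lines and derive doubled haploids
#'
#' Forms the (fully heterozygous at segregating sites) F1 of two inbred
#' parents and returns doubled haploids of its gametes: each offspring is
#' one recombinant gamete, doubled, hence fully homozygous (no genotype
#' code 1). Chromosomes are 1 Morgan with uniformly spaced loci and
#' Poisson(1) crossovers per meiosis.
#'
#' @param parent1,parent2 Genotype-code vectors in \{0, 2\} (fully
#'   homozygous), length `chromosomes * snps_per_chrom`.
#' @param n_offspring Number of doubled haploids.
#' @param cfg A [sim_config()] (genome layout).
#' @return Integer matrix `n_offspring` x loci of genotype codes in
#'   \{0, 2\}.
#' @export
cross_and_dh <- function(parent1, parent2, n_offspring, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$chromosomes * cfg$snps_per_chrom
  if (length(parent1) != L || length(parent2) != L)
    stop("parents must have ", L, " loci")
  if (any(parent1 == 1) || any(parent2 == 1))
    stop("parents must be fully homozygous (codes 0/2)")
  h1 <- as.integer(parent1 / 2)
  h2 <- as.integer(parent2 / 2)
  2L * dh_gametes_cpp(h1, h2, as.integer(n_offspring),
                      cfg$chromosomes, cfg$snps_per_chrom)
}

# Stage phenotype with the stated plot-level heritability realized against
# the evaluated cohort's current genetic variance (the way trial
# heritabilities are stated): h2 = var_g / (var_g + var_gxe + var_e) with
# var_gxe = gxe_var * var_g and var_e the remainder.
stage_phenotype <- function(tbv, h2, gxe_var) {
  var_g <- stats::var(tbv)
  if (!is.finite(var_g) || var_g <= 0) var_g <- 1e-8
  gxe_sd <- sqrt(gxe_var * var_g)
  var_e <- max(var_g * (1 / h2 - 1) - gxe_sd^2, 0.01 * var_g)
  tbv + rnorm(length(tbv), 0, gxe_sd) + rnorm(length(tbv), 0, sqrt(var_e))
}

#' Run the breeding program and collect the PYT pool
#'
#' Executes burn-in plus recorded years of the multi-stage program and
#' returns, for each recorded year, the 1000 PYT entries' genotypes
#' (stored as per-line haplotypes; lines are doubled haploids), their true
#' breeding values and PYT-stage phenotypes. Crossing parents are recycled
#' each year as the current EYT plus AYT selections.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer; `set.seed(seed)` if given.
#' @return A `sim_dataset`: list with `haplotypes` (pool x loci, raw
#'   storage), `tbv`, `pheno_pyt`, `year`, `qtl` (map with effects),
#'   `var_g0` and `cfg`.
#' @export
run_breeding_program <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  founders <- simulate_founders(cfg)
  qtl <- sample_qtl_map(cfg)
  var_g0 <- stats::var(tbv_of(founders, qtl))

  parents <- founders
  n_years <- cfg$burnin_years + cfg$record_years
  n_pyt <- cfg$families * cfg$select_per_family
  L <- cfg$chromosomes * cfg$snps_per_chrom

  rec_hap <- vector("list", cfg$record_years)
  rec_tbv <- vector("list", cfg$record_years)
  rec_pheno <- vector("list", cfg$record_years)

  # cohorts advance one stage per year (crossing/DH -> nursery -> PYT ->
  # AYT -> EYT), so selections feed back into the crossing block with the
  # pipeline lag of a real line-breeding program
  nursery_cohort <- NULL  # list(hap raw, tbv): this year's head rows
  pyt_cohort <- NULL      # 1000 nursery survivors awaiting the PYT
  ayt_cohort <- NULL      # 100 PYT survivors awaiting the AYT
  eyt_cohort <- NULL      # 10 AYT survivors awaiting the EYT

  for (year in seq_len(n_years)) {
    # EYT: large multilocation replicated trial (variety release)
    if (!is.null(eyt_cohort))
      invisible(stage_phenotype(eyt_cohort$tbv, cfg$h2_eyt, cfg$gxe_var))

    # AYT: small multilocation replicated trial; best lines to the EYT
    new_eyt <- NULL
    if (!is.null(ayt_cohort)) {
      ph <- stage_phenotype(ayt_cohort$tbv, cfg$h2_ayt, cfg$gxe_var)
      top <- order(ph, decreasing = TRUE)[seq_len(cfg$n_eyt)]
      new_eyt <- list(hap = ayt_cohort$hap[top, , drop = FALSE],
                      tbv = ayt_cohort$tbv[top], pheno = ph[top])
      ayt_cohort$pheno <- ph
    }

    # PYT: unreplicated trial; best lines to the AYT; this is the recorded
    # genotype/phenotype pool
    new_ayt <- NULL
    if (!is.null(pyt_cohort)) {
      ph <- stage_phenotype(pyt_cohort$tbv, cfg$h2_pyt, cfg$gxe_var)
      top <- order(ph, decreasing = TRUE)[seq_len(cfg$n_ayt)]
      new_ayt <- list(hap = pyt_cohort$hap[top, , drop = FALSE],
                      tbv = pyt_cohort$tbv[top])
      if (year > cfg$burnin_years) {
        ry <- year - cfg$burnin_years
        rec_hap[[ry]] <- pyt_cohort$hap
        rec_tbv[[ry]] <- pyt_cohort$tbv
        rec_pheno[[ry]] <- ph
      }
    }

    # nursery (head rows): within-family selection on the whole cohort
    new_pyt <- NULL
    if (!is.null(nursery_cohort)) {
      ph <- stage_phenotype(nursery_cohort$tbv, cfg$h2_nursery, cfg$gxe_var)
      keep <- integer(0)
      for (fam in seq_len(cfg$families)) {
        rows <- (fam - 1) * cfg$family_size + seq_len(cfg$family_size)
        keep <- c(keep,
                  rows[order(ph[rows],
                             decreasing = TRUE)[seq_len(cfg$select_per_family)]])
      }
      new_pyt <- list(hap = compact_hap(expand_hap(nursery_cohort$hap, keep)),
                      tbv = nursery_cohort$tbv[keep])
      nursery_cohort <- NULL  # free the 10,000-line cohort before recrossing
    }

    # crossing block: founders until trial selections exist, then the
    # current EYT entrants plus the best AYT entrants
    if (!is.null(new_ayt)) {
      rank_pool <- if (!is.null(new_eyt)) {
        list(hap = rbind(expand_hap(new_eyt$hap), expand_hap(new_ayt$hap)),
             tbv = c(new_eyt$tbv, new_ayt$tbv))
      } else list(hap = expand_hap(new_ayt$hap), tbv = new_ayt$tbv)
      n_par <- min(cfg$founders, nrow(rank_pool$hap))
      parents <- rank_pool$hap[seq_len(n_par), , drop = FALSE]
    }

    # new crosses and doubled haploids: next year's nursery cohort
    fam_hap <- vector("list", cfg$families)
    fam_tbv <- vector("list", cfg$families)
    for (fam in seq_len(cfg$families)) {
      pr <- sample.int(nrow(parents), 2)
      off <- dh_gametes_cpp(parents[pr[1], ], parents[pr[2], ],
                            cfg$family_size, cfg$chromosomes,
                            cfg$snps_per_chrom)
      fam_tbv[[fam]] <- tbv_of(off, qtl)
      fam_hap[[fam]] <- compact_hap(off)
    }
    crosses <- list(
      hap = do.call(rbind, fam_hap),
      tbv = unlist(fam_tbv))
    rm(fam_hap)

    eyt_cohort <- new_eyt
    ayt_cohort <- new_ayt
    pyt_cohort <- new_pyt
    nursery_cohort <- crosses
  }

  structure(list(haplotypes = rec_hap,
                 tbv = unlist(rec_tbv),
                 pheno_pyt = unlist(rec_pheno),
                 year = rep(seq_len(cfg$record_years), each = n_pyt),
                 qtl = qtl, var_g0 = var_g0, cfg = cfg),
            class = "sim_dataset")
}

# memory-lean storage: one raw byte per 0/1 haplotype allele
compact_hap <- function(m) {
  r <- as.raw(m)
  dim(r) <- dim(m)
  r
}

expand_hap <- function(r, rows = NULL) {
  if (!is.null(rows)) r <- r[rows, , drop = FALSE]
  m <- matrix(as.integer(r), nrow(r), ncol(r))
  m
}

#' @exportS3Method print sim_dataset
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", length(x$tbv), "PYT lines over", x$cfg$record_years,
      "years;", x$cfg$chromosomes * x$cfg$snps_per_chrom, "markers;",
      nrow(x$qtl), "QTLs\n")
  invisible(x)
}

#' Sample a genotype/phenotype dataset from the simulated PYT pool
#'
#' Uniform sampling without replacement. Doubled-haploid genotype codes
#' \{0, 2\} are rescaled to allele proportions \{0, 1\} (code / 2) for
#' pipeline compatibility, and the PYT phenotype is min-max normalized.
#'
#' @param ds A `sim_dataset`.
#' @param n Sample size (at most the pool size).
#' @param seed Optional integer seed.
#' @return List with `G` (n x loci allele-proportion matrix), `y`
#'   (normalized phenotypes), `y_raw`, `tbv`, `idx` (pool rows).
#' @export
sample_dataset <- function(ds, n, seed = NULL) {
  stopifnot(inherits(ds, "sim_dataset"))
  pool <- length(ds$tbv)
  if (n > pool) stop("n exceeds the ", pool, "-line pool")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(pool, n)
  n_per_year <- length(ds$tbv) / length(ds$haplotypes)
  yr <- (idx - 1) %/% n_per_year + 1
  within <- (idx - 1) %% n_per_year + 1
  G <- matrix(0, n, ncol(ds$haplotypes[[1]]))
  for (u in unique(yr)) {
    sel <- which(yr == u)
    G[sel, ] <- expand_hap(ds$haplotypes[[u]], within[sel])
  }
  colnames(G) <- paste0("M", seq_len(ncol(G)))
  rownames(G) <- paste0("L", idx)
  y_raw <- ds$pheno_pyt[idx]
  list(G = G, y = minmax_normalize(y_raw), y_raw = y_raw,
       tbv = ds$tbv[idx], idx = idx)
}
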