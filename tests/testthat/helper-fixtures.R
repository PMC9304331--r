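# Fixtures are built in code; the only cached object is the full-scale
# simulated breeding pool shared by the acceptance tests.

random_genotypes <- function(n, p, seed = 1, values = NULL) {
  set.seed(seed)
  g <- if (is.null(values)) matrix(runif(n * p), n, p) else
    matrix(sample(values, n * p, replace = TRUE), n, p)
  dimnames(g) <- list(paste0("I", seq_len(n)), paste0("M", seq_len(p)))
  g
}

# small raw depth table: 3 biallelic markers + 1 multi-allelic, 4 individuals
toy_depth_table <- function() {
  markers <- data.frame(
    id = c("m1", "m2", "m3", "m4"),
    chrom = "chr1", pos = c(100, 200, 300, 400),
    ref = "A", alt = c("T", "G", "C", "G,T"),
    multiallelic = c(FALSE, FALSE, FALSE, TRUE))
  rd <- matrix(c(30, 50, 20, 10,
                 60, 25, 40, 80,
                 0, 55, 25, 90,
                 10, 10, 10, 10), 4, 4, byrow = TRUE,
               dimnames = list(markers$id, paste0("I", 1:4)))
  ad <- matrix(c(30, 0, 25, 45,
                 0, 30, 15, 20,
                 0, 0, 30, 10,
                 5, 5, 5, 5), 4, 4, byrow = TRUE,
               dimnames = list(markers$id, paste0("I", 1:4)))
  raw_genotype_table(markers, rd, ad)
}

# write a minimal VCF 4.2 with FORMAT/AD for the VCF reading route
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\tv1\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:30,30\t0/0:50,0",
    "chr1\t200\tv2\tC\tG\t.\tPASS\t.\tGT:AD\t0/1:20,25\t1/1:0,60",
    "chr1\t300\tv3\tG\tA,T\t.\tPASS\t.\tGT:AD\t0/1:10,10,10\t0/0:40,5,5")
  writeLines(lines, path)
  path
}

# shared full-scale simulation pool for the acceptance suite (built once)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_pool <- function() {
  if (is.null(.acceptance_cache$pool)) {
    .acceptance_cache$pool <- run_breeding_program(sim_config(), seed = 2024)
  }
  .acceptance_cache$pool
}

# selection + CV contrast at a given sample size, computed once and shared
# across the acceptance criteria
acceptance_bench <- function(n) {
  key <- paste0("bench", n)
  if (is.null(.acceptance_cache[[key]])) {
    s <- sample_dataset(acceptance_pool(), n, seed = 2024 + n)
    .acceptance_cache[[key]] <-
      smgk_cr3_benchmark(s$G, s$y, seed = 2024,
                         control = gp_control(iterations = 4000,
                                              burnin = 500))
  }
  .acceptance_cache[[key]]
}
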