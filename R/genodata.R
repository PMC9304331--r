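#' Read genotype data from VCF or a marker-matrix TSV
#'
#' Two input routes are supported. A VCF 4.x file with per-sample allelic
#' depths (`FORMAT/AD`) yields a raw genotype table of reference/alternative
#' read counts, to be encoded with [encode_allele_proportions()]. A TSV file
#' holding an already-encoded numeric marker matrix (rows = markers, header =
#' individual ids, missing cells written as `NA`) bypasses depth encoding and
#' yields the genotype matrix directly.
#'
#' @param path Path to a `.vcf`/`.vcf.gz` file or a tab-separated marker
#'   matrix.
#' @param format `"auto"` (default, decided from the file name/first line),
#'   `"vcf"` or `"tsv"`.
#' @param missing Sentinel string marking missing cells in the TSV route.
#' @return For VCF input, a `raw_genotype_table`: list with `markers` (data
#'   frame of id, chrom, pos, ref, alt, multiallelic flag), integer matrices
#'   `ref_depth` and `alt_depth` (markers x individuals), and `individuals`.
#'   For TSV input, a numeric genotype matrix (individuals x markers, values
#'   in \[0, 1\] or `NA`).
#' @seealso [encode_allele_proportions()], [filter_and_impute()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           missing = "NA") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_tsv(path, missing = missing)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  geno_fields <- rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))
  if (!"AD" %in% geno_fields)
    stop("VCF lacks the FORMAT/AD field (per-sample allelic depths), ",
         "required to encode allele proportions")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  ad <- VariantAnnotation::geno(vcf)$AD
  ids <- rownames(vcf)
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  samples <- colnames(vcf)
  nm <- length(ids)
  ref_depth <- matrix(NA_integer_, nm, length(samples),
                      dimnames = list(ids, samples))
  alt_depth <- ref_depth
  for (j in seq_along(samples)) {
    for (i in seq_len(nm)) {
      d <- ad[[i, j]]
      if (length(d) >= 2L && !all(is.na(d))) {
        ref_depth[i, j] <- d[1L]
        # depth of all non-reference alleles; multi-allelic sites are flagged
        # below and excluded at encoding time anyway
        alt_depth[i, j] <- sum(d[-1L], na.rm = TRUE)
      }
    }
  }
  markers <- data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_len(nm), function(i)
      paste(as.character(alt[[i]]), collapse = ","), character(1)),
    multiallelic = n_alt > 1L,
    stringsAsFactors = FALSE
  )
  raw_genotype_table(markers, ref_depth, alt_depth)
}

#' Construct a raw genotype table of per-sample read depths
#'
#' @param markers Data frame with columns `id`, and optionally `chrom`,
#'   `pos`, `ref`, `alt`, `multiallelic`.
#' @param ref_depth,alt_depth Non-negative integer matrices, markers x
#'   individuals, reference- and alternative-allele read counts.
#' @return An object of class `raw_genotype_table`.
#' @export
raw_genotype_table <- function(markers, ref_depth, alt_depth) {
  stopifnot(is.data.frame(markers), "id" %in% names(markers))
  if (anyDuplicated(markers$id)) stop("marker ids must be unique")
  ref_depth <- as.matrix(ref_depth); alt_depth <- as.matrix(alt_depth)
  if (!identical(dim(ref_depth), dim(alt_depth)))
    stop("ref_depth and alt_depth dimensions differ")
  if (nrow(ref_depth) != nrow(markers))
    stop("depth matrices must have one row per marker")
  bad <- c(ref_depth, alt_depth)
  if (any(bad < 0, na.rm = TRUE)) stop("read depths must be non-negative")
  if (is.null(rownames(ref_depth))) {
    rownames(ref_depth) <- rownames(alt_depth) <- markers$id
  }
  if (is.null(colnames(ref_depth)))
    stop("depth matrices need individual ids as column names")
  if (!"multiallelic" %in% names(markers)) markers$multiallelic <- FALSE
  structure(
    list(markers = markers, ref_depth = ref_depth, alt_depth = alt_depth,
         individuals = colnames(ref_depth)),
    class = "raw_genotype_table")
}

#' @exportS3Method print raw_genotype_table
print.raw_genotype_table <- function(x, ...) {
  cat("raw_genotype_table:", nrow(x$markers), "markers x",
      length(x$individuals), "individuals\n")
  cat("  multi-allelic markers:", sum(x$markers$multiallelic), "\n")
  invisible(x)
}

read_genotypes_tsv <- function(path, missing = "NA") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = missing, data.table = FALSE,
                          colClasses = list(character = 1))
  marker_ids <- dt[[1L]]
  if (anyDuplicated(marker_ids)) stop("marker ids must be unique")
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "non-numeric genotype cell at marker '%s', individual '%s'",
        marker_ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- marker_ids
  g <- t(m)  # file is markers x individuals; matrix is individuals x markers
  validate_genotype_matrix(g, allow_missing = TRUE)
  g
}

#' Write a genotype matrix as a marker-matrix TSV
#'
#' Inverse of the TSV route of [read_genotypes()]: rows are markers, the
#' first column holds marker ids, remaining columns are individuals.
#'
#' @param g Genotype matrix (individuals x markers).
#' @param path Output path.
#' @export
write_genotypes <- function(g, path) {
  validate_genotype_matrix(g, allow_missing = TRUE)
  out <- data.frame(marker = colnames(g), t(g), check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

validate_genotype_matrix <- function(g, allow_missing = FALSE) {
  if (!is.matrix(g) || !is.numeric(g)) stop("genotype matrix must be numeric")
  if (is.null(rownames(g)) || is.null(colnames(g)))
    stop("genotype matrix needs individual (row) and marker (column) names")
  if (!all(is.na(g))) {
    rng <- range(g, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("allele proportions must lie in [0, 1]")
  }
  if (!allow_missing && anyNA(g)) stop("genotype matrix contains missing values")
  invisible(g)
}

#' Encode read depths as allele proportions
#'
#' Each genotype call becomes the ratio of reference-allele reads to total
#' reads, a continuous code in \[0, 1\] that sidesteps allele-dosage calling
#' in polyploids. Calls whose total depth falls below `min_depth` are set
#' missing (the per-individual depth filter), and multi-allelic markers are
#' excluded so only biallelic variants remain.
#'
#' @param table A `raw_genotype_table` from [read_genotypes()] or
#'   [raw_genotype_table()].
#' @param min_depth Minimum total read count per individual call; lower-depth
#'   calls become missing. Default 50.
#' @return Genotype matrix (individuals x markers) with `NA` for missing.
#' @export
encode_allele_proportions <- function(table, min_depth = 50) {
  stopifnot(inherits(table, "raw_genotype_table"), min_depth >= 0)
  keep <- !table$markers$multiallelic
  rd <- table$ref_depth[keep, , drop = FALSE]
  ad <- table$alt_depth[keep, , drop = FALSE]
  tot <- rd + ad
  prop <- rd / tot            # zero total depth -> NaN, masked below
  prop[!is.finite(prop)] <- NA_real_
  prop[is.na(tot) | tot < min_depth] <- NA_real_
  g <- t(prop)
  validate_genotype_matrix(g, allow_missing = TRUE)
  g
}

#' Filter markers on missingness and impute remaining gaps with marker means
#'
#' Markers missing in more than `max_missing` of individuals are dropped;
#' surviving missing calls are imputed with the per-marker mean of the
#' observed calls (which leaves each marker's mean unchanged). Markers with
#' zero variance after imputation carry no information and break downstream
#' variance-based computations, so they are removed by default.
#'
#' @param g Genotype matrix (individuals x markers), `NA` for missing.
#' @param max_missing Maximum tolerated missing fraction per marker.
#'   Default 0.25.
#' @param drop_zero_variance Drop post-imputation constant markers
#'   (default `TRUE`).
#' @return Fully imputed genotype matrix.
#' @export
filter_and_impute <- function(g, max_missing = 0.25,
                              drop_zero_variance = TRUE) {
  validate_genotype_matrix(g, allow_missing = TRUE)
  miss_frac <- colMeans(is.na(g))
  g <- g[, miss_frac <= max_missing, drop = FALSE]
  if (ncol(g) == 0)
    stop("no markers left after the ", max_missing * 100,
         "% missing-data filter")
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx) > 0) g[idx] <- mu[idx[, 2]]
  if (drop_zero_variance) {
    v <- matrixStats_colVars(g)
    g <- g[, v > 0, drop = FALSE]
    if (ncol(g) == 0) stop("no markers left after removing zero-variance markers")
  }
  g
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m * m) - n * mu * mu) / (n - 1)
}

#' Min-max normalization to \[0, 1\]
#'
#' Rescales values as `f(v) = (v - min(v)) / (max(v) - min(v))`, mapping the
#' minimum to 0 and the maximum to 1. Applied to BLUPs/corrected phenotypes
#' before prediction so accuracies are comparable across traits.
#'
#' @param v Numeric vector with at least two distinct finite values.
#' @return Normalized vector of the same length (names preserved).
#' @export
minmax_normalize <- function(v) {
  if (!is.numeric(v)) stop("v must be numeric")
  r <- range(v, na.rm = TRUE)
  if (!all(is.finite(r))) stop("v has no finite values")
  if (r[1] == r[2])
    stop("min-max normalization undefined for a constant vector")
  (v - r[1]) / (r[2] - r[1])
}

#' Read a phenotype table
#'
#' Expects a CSV with a column `id` and one numeric column per trait
#' (BLUPs or corrected phenotypes from the field-trial mixed models).
#'
#' @param path CSV path.
#' @return Data frame with `id` as character and traits numeric.
#' @export
read_phenotypes <- function(path) {
  ph <- data.table::fread(path, data.table = FALSE)
  if (!"id" %in% names(ph)) stop("phenotype file needs an 'id' column")
  ph$id <- as.character(ph$id)
  if (anyDuplicated(ph$id)) stop("phenotype ids must be unique")
  ph
}

#' Align a genotype matrix and a phenotype table on shared individuals
#'
#' Keeps the id intersection, ordered as in the genotype matrix.
#'
#' @param g Genotype matrix (individuals x markers).
#' @param pheno Phenotype data frame with an `id` column.
#' @return List with aligned `g` and `pheno`.
#' @export
align_genotypes_phenotypes <- function(g, pheno) {
  ids <- intersect(rownames(g), pheno$id)
  if (length(ids) == 0) stop("no shared individuals between genotypes and phenotypes")
  list(g = g[ids, , drop = FALSE],
       pheno = pheno[match(ids, pheno$id), , drop = FALSE])
}
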