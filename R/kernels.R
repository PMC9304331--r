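#' Median squared Euclidean distance across genotypes
#'
#' The scale constant M used by the kernel-averaging bandwidth family: the
#' median over all unordered pairs of individuals of the squared Euclidean
#' distance between their marker vectors.
#'
#' @param g Imputed genotype matrix (individuals x markers).
#' @return A positive scalar.
#' @export
median_sq_distance <- function(g) {
  if (!is.matrix(g)) g <- as.matrix(g)
  if (nrow(g) < 2) stop("need at least two individuals")
  d2 <- sq_dist_matrix(g)
  stats::median(d2[lower.tri(d2)])
}

# full n x n squared-Euclidean-distance matrix, via the Gram expansion
sq_dist_matrix <- function(g) {
  q <- rowSums(g * g)
  d2 <- outer(q, q, "+") - 2 * tcrossprod(g)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Gaussian kernel genomic similarity matrix
#'
#' Computes `K[i,i'] = exp(-(h/p) * d2(i,i') / s)` where `d2` is the squared
#' Euclidean distance between marker vectors, `p` the number of loci and `h`
#' the bandwidth. With `scale = "none"` (the single-kernel model, `h = 1`)
#' distances enter raw; with `scale = "median"` they are first divided by
#' `M`, the median squared pairwise distance, so a bandwidth family such as
#' `h = 15, 5, 1` spans local to global kernels regardless of marker count.
#'
#' @param g Imputed genotype matrix (individuals x markers).
#' @param h Positive bandwidth. Default 1.
#' @param scale `"none"` or `"median"`.
#' @return Symmetric positive semidefinite matrix with unit diagonal, of
#'   class `matrix`, with a `bandwidth` attribute.
#' @export
gaussian_kernel <- function(g, h = 1, scale = c("none", "median")) {
  scale <- match.arg(scale)
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("h must be positive")
  if (anyNA(g)) stop("genotype matrix must be imputed before kernel computation")
  p <- ncol(g)
  d2 <- sq_dist_matrix(g)
  s <- 1
  if (scale == "median") {
    s <- stats::median(d2[lower.tri(d2)]) / p
    if (!is.finite(s) || s <= 0)
      stop("median squared distance is zero; genotypes are degenerate")
  }
  K <- exp(-(h / p) * d2 / s)
  dimnames(K) <- list(rownames(g), rownames(g))
  attr(K, "bandwidth") <- h
  K
}

#' The three-bandwidth kernel family used for kernel averaging
#'
#' Builds Gaussian kernels at bandwidths `h = 15, 5, 1` on median-normalized
#' squared distances (the median genotype pair maps to distance 1), giving a
#' local, an intermediate and a global kernel for the multi-kernel model.
#'
#' @param g Imputed genotype matrix.
#' @param bandwidths Numeric vector of bandwidths. Default `c(15, 5, 1)`.
#' @return Named list of kernel matrices.
#' @export
kernel_average_family <- function(g, bandwidths = c(15, 5, 1)) {
  stats::setNames(
    lapply(bandwidths, function(h) gaussian_kernel(g, h = h, scale = "median")),
    paste0("h", bandwidths))
}

check_kernel <- function(K, tol = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("kernel must be square")
  if (max(abs(K - t(K))) > 1e-8) stop("kernel must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev)) - tol)
    stop("kernel is not positive semidefinite within tolerance")
  invisible(K)
}

#' Write / read a kernel matrix as TSV with an id header
#'
#' @param K Kernel matrix with dimnames.
#' @param path File path.
#' @export
write_kernel <- function(K, path) {
  out <- data.frame(id = rownames(K), K, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  K <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(K) <- dt[[1L]]
  K
}
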