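#' Clustering schemes for phenotypic interval definition
#'
#' Nine strategies over pairwise Euclidean distances: Ward's minimum
#' variance with squared dissimilarities (WardWSD, `hclust` method
#' `ward.D2`) and without (WardWoSD, `ward.D`), single and complete
#' linkage, UPGMA (`average`), WPGMA (`mcquitty`), WPGMC (`median`), UPGMC
#' (`centroid`), and k-means.
#'
#' @format Character vector of method names.
#' @export
CLUSTER_METHODS <- c("WardWSD", "WardWoSD", "single", "complete", "UPGMA",
                     "WPGMA", "WPGMC", "UPGMC", "kmeans")

hclust_method_map <- c(WardWSD = "ward.D2", WardWoSD = "ward.D",
                       single = "single", complete = "complete",
                       UPGMA = "average", WPGMA = "mcquitty",
                       WPGMC = "median", UPGMC = "centroid")

#' Cluster a trait vector into k groups
#'
#' Hierarchical methods are deterministic; k-means uses 25 restarts under
#' the caller's RNG state (set a seed for reproducibility).
#'
#' @param y Numeric trait vector.
#' @param method One of [CLUSTER_METHODS]. Default `"WardWSD"`.
#' @param k Number of clusters, `2 <= k <= length(y)`.
#' @return Integer cluster labels (arbitrary numbering).
#' @export
cluster_labels <- function(y, method = "WardWSD", k) {
  method <- match.arg(method, CLUSTER_METHODS)
  y <- as.numeric(y)
  n <- length(y)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of individuals")
  if (method == "kmeans") {
    km <- stats::kmeans(y, centers = k, nstart = 25, iter.max = 50)
    km$cluster
  } else {
    hc <- stats::hclust(stats::dist(y), method = hclust_method_map[[method]])
    stats::cutree(hc, k = k)
  }
}

# ---- cluster-number quality indices --------------------------------------
# All computed on the 1-D trait values with Euclidean distance. wss(k) is
# the total within-cluster sum of squares.

wss_of <- function(y, labels) {
  sum(tapply(y, labels, function(v) sum((v - mean(v))^2)))
}

index_ch <- function(y, labels) {  # Calinski-Harabasz, maximize
  n <- length(y); k <- length(unique(labels))
  W <- wss_of(y, labels)
  B <- sum((y - mean(y))^2) - W
  if (k == 1 || W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

index_silhouette <- function(d, labels) {  # maximize
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

index_db <- function(y, labels) {  # Davies-Bouldin, minimize
  lev <- sort(unique(labels))
  cent <- vapply(lev, function(l) mean(y[labels == l]), numeric(1))
  disp <- vapply(lev, function(l) {
    v <- y[labels == l]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  k <- length(lev)
  r <- vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) {
      dc <- abs(cent[i] - cent[j])
      if (dc == 0) Inf else (disp[i] + disp[j]) / dc
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

index_dunn <- function(y, labels) {  # maximize
  lev <- sort(unique(labels))
  k <- length(lev)
  diam <- max(vapply(lev, function(l) {
    v <- y[labels == l]
    if (length(v) < 2) 0 else max(v) - min(v)
  }, numeric(1)))
  sep <- Inf
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vi <- y[labels == lev[i]]; vj <- y[labels == lev[j]]
    sep <- min(sep, min(abs(outer(vi, vj, "-"))))
  }
  if (diam == 0) Inf else sep / diam
}

index_cindex <- function(d, labels) {  # minimize
  dv <- as.vector(d)
  within <- as.vector(stats::as.dist(outer(labels, labels, "==")))
  sw <- sum(dv[within == 1])
  nw <- sum(within == 1)
  if (nw == 0) return(NA_real_)
  ds <- sort(dv)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq.int(length(ds) - nw + 1, length(ds))])
  if (smax == smin) return(NA_real_)
  (sw - smin) / (smax - smin)
}

#' Consensus number of clusters for a trait
#'
#' Computes, for each candidate `k` in `k_range`, eight cluster-quality
#' indices (Calinski-Harabasz, mean silhouette, Davies-Bouldin, Dunn,
#' Hartigan's rule, Krzanowski-Lai, C-index and the gap statistic) on the
#' labels produced by `method`, takes each index's preferred `k`, and
#' returns the plurality vote (ties resolved toward the smallest `k`).
#'
#' @param y Numeric trait vector (`n >= 3`; `n >= 11` recommended so the
#'   full range is reachable).
#' @param method Clustering method, see [CLUSTER_METHODS].
#' @param k_range Candidate cluster numbers. Default `2:10`.
#' @param gap_B Reference sets for the gap statistic. Default 25.
#' @return List with `k` (the consensus), `votes` (named integer of each
#'   index's best k) and `table` (per-k index values).
#' @export
consensus_cluster_count <- function(y, method = "WardWSD", k_range = 2:10,
                                    gap_B = 25) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least three individuals")
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (length(k_range) == 0) stop("no feasible cluster numbers")
  d <- stats::dist(y)
  ks <- sort(k_range)
  # wss over an extended range for Hartigan / Krzanowski-Lai differences
  k_ext <- seq(max(2, min(ks) - 1), min(n - 1, max(ks) + 1))
  labels_ext <- lapply(k_ext, function(k) cluster_labels(y, method, k))
  names(labels_ext) <- k_ext
  wss_ext <- vapply(labels_ext, function(lb) wss_of(y, lb), numeric(1))
  wss_all <- c(stats::setNames(sum((y - mean(y))^2), "1"), wss_ext)

  tab <- data.frame(k = ks)
  lab_of <- function(k) labels_ext[[as.character(k)]]
  tab$ch <- vapply(ks, function(k) index_ch(y, lab_of(k)), numeric(1))
  tab$silhouette <- vapply(ks, function(k) index_silhouette(d, lab_of(k)),
                           numeric(1))
  tab$db <- vapply(ks, function(k) index_db(y, lab_of(k)), numeric(1))
  tab$dunn <- vapply(ks, function(k) index_dunn(y, lab_of(k)), numeric(1))
  tab$cindex <- vapply(ks, function(k) index_cindex(d, lab_of(k)), numeric(1))

  w_at <- function(k) wss_all[[as.character(k)]]
  # Hartigan: H(k) = (W_k / W_{k+1} - 1) (n - k - 1); first k with H <= 10
  tab$hartigan <- vapply(ks, function(k) {
    wk1 <- tryCatch(w_at(k + 1), error = function(e) NA_real_)
    if (is.na(wk1) || wk1 == 0) return(NA_real_)
    (w_at(k) / wk1 - 1) * (n - k - 1)
  }, numeric(1))
  # Krzanowski-Lai with m = 1 dimension: DIFF_k = (k-1)^2 W_{k-1} - k^2 W_k
  diff_kl <- function(k) {
    wkm <- tryCatch(w_at(k - 1), error = function(e) NA_real_)
    if (is.na(wkm)) return(NA_real_)
    (k - 1)^2 * wkm - k^2 * w_at(k)
  }
  tab$kl <- vapply(ks, function(k) {
    dk <- diff_kl(k); dk1 <- diff_kl(k + 1)
    if (is.na(dk) || is.na(dk1) || dk1 == 0) return(NA_real_)
    abs(dk / dk1)
  }, numeric(1))
  # gap statistic against uniform references on range(y)
  logW_ref <- matrix(NA_real_, gap_B, length(ks))
  for (b in seq_len(gap_B)) {
    yb <- runif(n, min(y), max(y))
    for (i in seq_along(ks))
      logW_ref[b, i] <- log(wss_of(yb, cluster_labels(yb, method, ks[i])))
  }
  logW <- log(pmax(vapply(ks, function(k) w_at(k), numeric(1)), 1e-300))
  gap <- colMeans(logW_ref) - logW
  s_k <- apply(logW_ref, 2, sd) * sqrt(1 + 1 / gap_B)
  tab$gap <- gap

  best <- c(
    ch = ks[which.max(tab$ch)],
    silhouette = ks[which.max(tab$silhouette)],
    db = ks[which.min(tab$db)],
    dunn = ks[which.max(tab$dunn)],
    cindex = ks[which.min(tab$cindex)],
    hartigan = {
      ok <- which(!is.na(tab$hartigan) & tab$hartigan <= 10)
      if (length(ok) > 0) ks[ok[1]] else ks[which.min(tab$hartigan)]
    },
    kl = ks[which.max(tab$kl)],
    gap = {
      pick <- NA_integer_
      for (i in seq_along(ks)[-length(ks)]) {
        if (!is.na(gap[i]) && gap[i] >= gap[i + 1] - s_k[i + 1]) {
          pick <- ks[i]; break
        }
      }
      if (is.na(pick)) ks[which.max(gap)] else pick
    }
  )
  votes <- table(best)
  top <- max(votes)
  k_star <- min(as.integer(names(votes)[votes == top]))
  list(k = k_star, votes = best, table = tab)
}

#' Define phenotypic interval classes for a trait
#'
#' Clusters the trait at the consensus cluster number, renames classes
#' `1..k` by ascending class mean, and records each class's value range —
#' the classification target for interval prediction.
#'
#' @param y Numeric trait vector, optionally named by individual.
#' @param method Clustering method (default `"WardWSD"`).
#' @param k Optional fixed number of clusters; when `NULL` (default) the
#'   consensus of [consensus_cluster_count()] is used.
#' @param k_range Candidate range for the consensus. Default `2:10`.
#' @return An `interval_assignment`: list with `labels` (ordered integer
#'   classes), `k`, `method`, `ranges` (per-class min/max) and `votes`.
#' @export
define_intervals <- function(y, method = "WardWSD", k = NULL,
                             k_range = 2:10) {
  y <- stats::setNames(as.numeric(y), names(y))
  votes <- NULL
  if (is.null(k)) {
    cc <- consensus_cluster_count(y, method = method, k_range = k_range)
    k <- cc$k
    votes <- cc$votes
  }
  raw <- cluster_labels(y, method, k)
  means <- tapply(y, raw, mean)
  remap <- stats::setNames(rank(means, ties.method = "first"), names(means))
  labels <- as.integer(remap[as.character(raw)])
  ranges <- do.call(rbind, lapply(seq_len(k), function(cl) {
    v <- y[labels == cl]
    data.frame(class = cl, n = length(v), min = min(v), max = max(v))
  }))
  structure(list(labels = stats::setNames(labels, names(y)), k = k,
                 method = method, ranges = ranges, votes = votes),
            class = "interval_assignment")
}

#' @exportS3Method print interval_assignment
print.interval_assignment <- function(x, ...) {
  cat("interval_assignment:", x$k, "classes by", x$method, "\n")
  print(x$ranges, row.names = FALSE)
  invisible(x)
}

#' Write interval assignments as CSV
#'
#' Columns: id, label, class_min, class_max.
#'
#' @param x An `interval_assignment`.
#' @param path Output path.
#' @export
write_intervals <- function(x, path) {
  ids <- names(x$labels)
  if (is.null(ids)) ids <- as.character(seq_along(x$labels))
  out <- data.frame(id = ids, label = x$labels,
                    class_min = x$ranges$min[x$labels],
                    class_max = x$ranges$max[x$labels])
  data.table::fwrite(out, path)
  invisible(path)
}
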