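#' Feature-selection votes from the classification trio
#'
#' Three techniques vote per marker: (i) an L1-penalized linear classifier
#' (a marker votes if any class coefficient is nonzero at penalty strength
#' `lambda`; glmnet logistic/multinomial stands in for the L1 linear
#' support-vector classifier), (ii) a per-marker one-way ANOVA F-test at
#' `p < alpha`, and (iii) gradient tree boosting, voting for markers whose
#' impurity importance exceeds the mean importance over all markers.
#'
#' @param Z Imputed genotype matrix (individuals x markers).
#' @param labels Interval class labels (at least two classes).
#' @param seed Integer seed (GTB subsampling and glmnet internals).
#' @param alpha Univariate-screen significance cut-off. Default 0.05.
#' @param lambda L1 penalty; default `1/n`, the analogue of the soft-margin
#'   constant C = 1.
#' @param gtb_trees Boosting stages. Default 100.
#' @return An `fs_votes` data frame: marker, per-technique logicals
#'   (`l1`, `univariate`, `gtb`) and `votes` (0-3).
#' @export
fs_votes_classification <- function(Z, labels, seed = 1, alpha = 0.05,
                                    lambda = NULL, gtb_trees = 100) {
  Z <- as.matrix(Z)
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least two interval classes")
  if (anyNA(Z)) stop("Z must be imputed")
  set.seed(seed)
  n <- nrow(Z)
  if (is.null(lambda)) lambda <- 1 / n

  l1 <- l1_selected(Z, f, family = if (nlevels(f) == 2) "binomial"
                    else "multinomial", lambda = lambda)
  uni <- anova_f_pvalues(Z, f) < alpha
  uni[is.na(uni)] <- FALSE
  gtb <- fit_gtb(Z, f, task = "classification", n_trees = gtb_trees)
  imp <- gtb$importance
  gtb_sel <- imp > mean(imp)

  fs_votes_frame(Z, l1, uni, gtb_sel, task = "classification")
}

#' Feature-selection votes from the regression trio
#'
#' As [fs_votes_classification()] with regression counterparts: an
#' L1-penalized linear regression (glmnet lasso standing in for L1 linear
#' support-vector regression), a per-marker Pearson correlation test at
#' `p < alpha` (t transform of r with n-2 d.f.), and gradient-tree-boosting
#' regression importances above their mean.
#'
#' @inheritParams fs_votes_classification
#' @param y Numeric, non-constant trait vector.
#' @return An `fs_votes` data frame.
#' @export
fs_votes_regression <- function(Z, y, seed = 1, alpha = 0.05, lambda = NULL,
                                gtb_trees = 100) {
  Z <- as.matrix(Z)
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("trait vector is constant")
  if (anyNA(Z)) stop("Z must be imputed")
  set.seed(seed)
  n <- nrow(Z)
  if (is.null(lambda)) lambda <- 1 / n

  l1 <- l1_selected(Z, y, family = "gaussian", lambda = lambda)
  uni <- pearson_pvalues(Z, y) < alpha
  uni[is.na(uni)] <- FALSE
  gtb <- fit_gtb(Z, y, task = "regression", n_trees = gtb_trees)
  imp <- gtb$importance
  gtb_sel <- imp > mean(imp)

  fs_votes_frame(Z, l1, uni, gtb_sel, task = "regression")
}

fs_votes_frame <- function(Z, l1, uni, gtb_sel, task) {
  out <- data.frame(marker = colnames(Z) %||% as.character(seq_len(ncol(Z))),
                    l1 = as.logical(l1), univariate = as.logical(uni),
                    gtb = as.logical(gtb_sel), stringsAsFactors = FALSE)
  out$votes <- out$l1 + out$univariate + out$gtb
  attr(out, "task") <- task
  class(out) <- c("fs_votes", class(out))
  out
}

l1_selected <- function(Z, target, family, lambda) {
  if (family != "gaussian") {
    # glmnet needs >= 2 observations per class; fold classes that are too
    # small into their ordered neighbor (interval labels are ordered), and
    # drop any still-too-small stragglers
    target <- merge_rare_classes(target, min_size = 2)
    tab <- table(target)
    keep_cls <- names(tab)[tab >= 2]
    keep_rows <- target %in% as.integer(keep_cls)
    target <- target[keep_rows]
    Z <- Z[keep_rows, , drop = FALSE]
    if (length(unique(target)) < 2) return(rep(FALSE, ncol(Z)))
    family <- if (length(unique(target)) == 2) "binomial" else "multinomial"
  }
  # a short descending path ending at the target penalty stabilizes the
  # coordinate-descent warm starts
  path <- lambda * c(16, 8, 4, 2, 1)
  # glmnet grumbles about small classes and slow convergence at weak
  # penalties; selection only needs the support, so soften those to notes
  fit <- suppressWarnings(
    glmnet::glmnet(Z, target, family = family, lambda = path,
                   standardize = FALSE))
  cf <- glmnet::coef.glmnet(fit, s = lambda, exact = FALSE)
  if (is.list(cf)) {  # multinomial: one coefficient vector per class
    nz <- Reduce(`|`, lapply(cf, function(m) as.vector(m[-1, 1] != 0)))
  } else {
    nz <- as.vector(cf[-1, 1] != 0)
  }
  nz
}

# fold classes smaller than min_size into the adjacent class in label order
merge_rare_classes <- function(labels, min_size = 2) {
  lv <- as.integer(factor(labels, levels = sort(unique(labels))))
  repeat {
    tab <- table(lv)
    small <- names(tab)[tab < min_size]
    if (length(small) == 0 || length(tab) <= 2) break
    s <- as.integer(small[1])
    others <- as.integer(names(tab))[as.integer(names(tab)) != s]
    nearest <- others[which.min(abs(others - s))]
    lv[lv == s] <- nearest
  }
  lv
}

# vectorized one-way ANOVA F-test p-value per marker column
anova_f_pvalues <- function(Z, f) {
  f <- factor(f)
  n <- nrow(Z)
  k <- nlevels(f)
  counts <- as.vector(table(f))
  gsum <- rowsum(Z, f)
  gmean2 <- gsum^2 / counts
  ssb <- colSums(gmean2) - colSums(Z)^2 / n
  sst <- colSums(Z^2) - colSums(Z)^2 / n
  ssw <- sst - ssb
  Fst <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fst, k - 1, n - k, lower.tail = FALSE)
  p[!is.finite(Fst)] <- NA_real_
  p
}

# vectorized Pearson correlation test per marker column
pearson_pvalues <- function(Z, y) {
  n <- nrow(Z)
  r <- suppressWarnings(as.vector(stats::cor(Z, y)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[!is.finite(r)] <- NA_real_
  p
}

#' Threshold feature-selection votes into a named marker set
#'
#' A marker is kept when at least `min_votes` of the three techniques
#' selected it: 2-of-3 gives C2/R2, 3-of-3 gives C3/R3.
#'
#' @param votes An `fs_votes` data frame.
#' @param min_votes 2 or 3.
#' @return A `marker_set` (name, marker ids, provenance votes, universe).
#' @export
threshold_votes <- function(votes, min_votes = 2) {
  stopifnot(inherits(votes, "fs_votes"), min_votes %in% c(2, 3))
  task <- attr(votes, "task")
  name <- paste0(if (task == "classification") "C" else "R", min_votes)
  ids <- votes$marker[votes$votes >= min_votes]
  if (length(ids) == 0)
    warning("no marker reached ", min_votes, " votes; ", name, " is empty")
  marker_set(name, ids, universe = votes$marker,
             votes = stats::setNames(votes$votes, votes$marker))
}

#' Construct a marker set
#'
#' @param name Set name (C2, C3, R2, R3, ICR2, CR2, CR3, ...).
#' @param markers Character vector of selected marker ids.
#' @param universe All marker ids the selection was computed over.
#' @param votes Optional named per-marker vote counts.
#' @return A `marker_set`.
#' @export
marker_set <- function(name, markers, universe, votes = NULL) {
  markers <- as.character(markers)
  universe <- as.character(universe)
  if (!all(markers %in% universe))
    stop("marker set contains ids outside its universe")
  structure(list(name = name, markers = markers, universe = universe,
                 votes = votes),
            class = "marker_set")
}

#' @exportS3Method print marker_set
print.marker_set <- function(x, ...) {
  cat("marker_set ", x$name, ": ", length(x$markers), " of ",
      length(x$universe), " markers\n", sep = "")
  invisible(x)
}

#' Combine classification and regression marker sets
#'
#' `ICR2` is the intersection of C2 and R2, `CR2` their union, and `CR3`
#' the union of C3 and R3.
#'
#' @param c_set,r_set Classification- and regression-derived `marker_set`s
#'   over the same marker universe.
#' @param rule `"ICR2"`, `"CR2"` or `"CR3"`.
#' @return A `marker_set` named after the rule.
#' @export
combine_marker_sets <- function(c_set, r_set, rule = c("ICR2", "CR2", "CR3")) {
  rule <- match.arg(rule)
  stopifnot(inherits(c_set, "marker_set"), inherits(r_set, "marker_set"))
  if (length(intersect(c_set$universe, r_set$universe)) == 0)
    stop("marker sets have disjoint universes")
  if (!setequal(c_set$universe, r_set$universe))
    stop("marker sets must share the same marker universe")
  ids <- switch(rule,
                ICR2 = intersect(c_set$markers, r_set$markers),
                CR2 = union(c_set$markers, r_set$markers),
                CR3 = union(c_set$markers, r_set$markers))
  marker_set(rule, ids, universe = c_set$universe)
}

#' All marker-set combinations from one trait
#'
#' Runs both feature-selection trios (classification on the interval
#' labels, regression on the trait values), thresholds at 2 and 3 votes and
#' forms the combinations: C2, C3, R2, R3, ICR2 = C2 n R2, CR2 = C2 u R2,
#' CR3 = C3 u R3. C3F/R3F are modelling modes (C3/R3 as fixed effects with
#' the kernel from the remaining markers) and reuse the C3/R3 sets.
#'
#' @param Z Imputed genotype matrix.
#' @param y Trait vector.
#' @param labels Interval labels (e.g. from [define_intervals()]).
#' @param seed Seed passed to both trios.
#' @param ... Passed on to the vote functions.
#' @return Named list of `marker_set`s plus the two `fs_votes` frames.
#' @export
fs_marker_sets <- function(Z, y, labels, seed = 1, ...) {
  vc <- fs_votes_classification(Z, labels, seed = seed, ...)
  vr <- fs_votes_regression(Z, y, seed = seed, ...)
  C2 <- threshold_votes(vc, 2); C3 <- threshold_votes(vc, 3)
  R2 <- threshold_votes(vr, 2); R3 <- threshold_votes(vr, 3)
  list(C2 = C2, C3 = C3, R2 = R2, R3 = R3,
       ICR2 = combine_marker_sets(C2, R2, "ICR2"),
       CR2 = combine_marker_sets(C2, R2, "CR2"),
       CR3 = combine_marker_sets(C3, R3, "CR3"),
       votes_classification = vc, votes_regression = vr)
}

#' Write a marker set (with vote provenance) as TSV
#'
#' @param sets Output of [fs_marker_sets()].
#' @param path Output path.
#' @export
write_marker_sets <- function(sets, path) {
  universe <- sets$C2$universe
  memb <- vapply(c("C2", "C3", "R2", "R3", "ICR2", "CR2", "CR3"),
                 function(nm) universe %in% sets[[nm]]$markers,
                 logical(length(universe)))
  out <- data.frame(
    marker = universe,
    votes_classification = sets$votes_classification$votes,
    votes_regression = sets$votes_regression$votes,
    memb)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
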