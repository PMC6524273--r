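#' PCA scores of samples over a miRNA subset
#'
#' Samples are observations and miRNAs variables; variables are centered but
#' not scaled, and scores come from the eigendecomposition of the covariance
#' (via SVD).
#'
#' @param expr A `normalized_expression` object.
#' @param subset miRNA identifiers to use (default: all).
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (sample x component matrix), `explained`
#'   (variance fractions, non-increasing) and the full `prcomp` fit.
#' @export
pca_scores <- function(expr, subset = rownames(expr$log2cpm), n_components = 2) {
  stopifnot(inherits(expr, "normalized_expression"), length(subset) > 0)
  missing_ids <- setdiff(subset, rownames(expr$log2cpm))
  if (length(missing_ids))
    stop("miRNA ids not in expression matrix: ",
         paste(missing_ids, collapse = ", "))
  m <- t(expr$log2cpm[subset, , drop = FALSE])   # samples x miRNAs
  if (nrow(m) < 2) stop("PCA needs at least 2 samples")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       explained = expl,
       fit = fit)
}

#' Correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` with the correlation computed across miRNAs, so
#' affinely related samples are at Pearson distance 0 and perfectly
#' anti-correlated samples at distance 2.
#'
#' @param expr A `normalized_expression` object or a numeric miRNA x sample
#'   matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
correlation_distance <- function(expr, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (inherits(expr, "normalized_expression")) expr$log2cpm else as.matrix(expr)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(m, method = method)
  diag(d) <- 0
  d
}

#' Silhouette widths for a given clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is the mean distance
#' of point i to the other members of its cluster and `b(i)` the smallest
#' mean distance to any other cluster. Points in singleton clusters get 0.
#'
#' @param d Symmetric distance matrix.
#' @param labels Integer/character cluster assignment per point.
#' @return Numeric vector of per-point widths in \[-1, 1\].
#' @export
silhouette_widths <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  ulab <- unique(labels)
  sizes <- table(labels)
  vapply(seq_len(n), function(i) {
    li <- labels[i]
    if (sizes[[li]] == 1) return(0)
    a <- mean(d[i, labels == li & seq_len(n) != i])
    b <- min(vapply(setdiff(ulab, li),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Estimate the optimal number of clusters by average silhouette width
#'
#' For each correlation distance (Pearson and Spearman), samples are
#' hierarchically clustered (average linkage by default), the tree is cut at
#' each k in `2..k_max`, and the average silhouette width is recorded; the
#' chosen k maximizes the average width (ties go to the smallest k).
#'
#' @param expr A `normalized_expression` object or miRNA x sample matrix.
#' @param k_max Largest number of clusters to evaluate (default 10); must be
#'   at least 2 and smaller than the number of samples.
#' @param methods Correlation distance methods to profile.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List of class `silhouette_profile`: `profile` (data frame with
#'   `method`, `k`, `avg_width`) and `chosen_k` (named vector per method).
#' @export
estimate_optimal_k <- function(expr, k_max = 10,
                               methods = c("pearson", "spearman"),
                               linkage = "average") {
  m <- if (inherits(expr, "normalized_expression")) expr$log2cpm else as.matrix(expr)
  if (k_max < 2) stop("k_max must be at least 2")
  if (k_max >= ncol(m)) stop("k_max must be smaller than the number of samples")
  rows <- lapply(methods, function(meth) {
    d <- correlation_distance(m, meth)
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    widths <- vapply(2:k_max, function(k) {
      mean(silhouette_widths(d, stats::cutree(hc, k = k)))
    }, numeric(1))
    data.frame(method = meth, k = 2:k_max, avg_width = widths,
               stringsAsFactors = FALSE)
  })
  profile <- do.call(rbind, rows)
  chosen <- vapply(methods, function(meth) {
    sub <- profile[profile$method == meth, ]
    sub$k[which.max(sub$avg_width)]       # ties: smallest k (first max)
  }, integer(1))
  structure(list(profile = profile, chosen_k = chosen),
            class = "silhouette_profile")
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat("silhouette profile (average width by k):\n")
  print(x$profile, row.names = FALSE)
  cat("chosen k: ",
      paste(sprintf("%s=%d", names(x$chosen_k), x$chosen_k), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
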