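#' TMM scaling factors
#'
#' Computes trimmed-mean-of-M-values (TMM) scaling factors between samples.
#' The reference sample is the one whose 75th-percentile count fraction lies
#' closest to the mean of those fractions. For each sample, per-miRNA M-values
#' (log2 ratio of count fractions versus the reference) and A-values (mean
#' log2 abundance) are formed over miRNAs nonzero in both samples, doubly
#' trimmed (two-sided, `trim_m` of the M distribution and `trim_a` of the A
#' distribution), and averaged with precision weights from the delta-method
#' binomial variance. The factor is 2 to that weighted mean; factors are
#' rescaled to geometric mean 1.
#'
#' @param cm A [count_matrix()] (typically already expression-filtered).
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return Named numeric vector of positive per-sample scaling factors with
#'   geometric mean 1.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$counts
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("sample with zero library size: ",
         paste(colnames(x)[lib == 0], collapse = ", "))

  # reference: 75th-percentile count fraction closest to the mean fraction
  f75 <- apply(x, 2, stats::quantile, probs = 0.75) / lib
  ref_i <- which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(x)), function(i) {
    .tmm_pair(x[, i], x[, ref_i], lib[i], lib[ref_i],
              trim_m = trim_m, trim_a = trim_a,
              sample_id = colnames(x)[i])
  }, numeric(1))
  f <- f / exp(mean(log(f)))     # geometric mean 1
  names(f) <- colnames(x)
  f
}

# One sample vs reference; obs/ref are count vectors, nobs/nref library sizes.
.tmm_pair <- function(obs, ref, nobs, nref, trim_m, trim_a, sample_id = "?") {
  both <- obs > 0 & ref > 0
  if (!any(both))
    stop("sample '", sample_id, "' shares no nonzero miRNA with the reference")
  obs <- as.numeric(obs[both]); ref <- as.numeric(ref[both])

  m <- log2((obs / nobs) / (ref / nref))
  a <- (log2(obs / nobs) + log2(ref / nref)) / 2
  # delta-method binomial variance of M; weight is its inverse
  v <- (nobs - obs) / (nobs * obs) + (nref - ref) / (nref * ref)

  if (max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
          rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Normalized log2 counts-per-million expression
#'
#' Converts raw counts to log2-CPM on TMM-effective library sizes:
#' `log2(count * 1e6 / (library_size * factor) + pseudocount)`. With the
#' default pseudocount of 1, a zero count maps to 0 and values are finite
#' everywhere.
#'
#' @param cm A [count_matrix()].
#' @param factors Positive per-sample scaling factors aligned with the samples
#'   (default: computed by [tmm_factors()]).
#' @param pseudocount Value added inside the log (default 1).
#' @return An object of class `normalized_expression`: a list with `log2cpm`
#'   (miRNA x sample matrix), `tmm_factors`, `library_sizes`,
#'   `effective_library_sizes` and the sample `metadata`.
#' @export
log2cpm <- function(cm, factors = tmm_factors(cm), pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- colSums(cm$counts)
  if (any(lib == 0))
    stop("sample with zero library size: ",
         paste(colnames(cm$counts)[lib == 0], collapse = ", "))
  if (length(factors) != ncol(cm$counts) || any(factors <= 0))
    stop("factors must be positive and aligned with samples")
  eff <- lib * factors
  mat <- log2(sweep(cm$counts, 2, 1e6 / eff, `*`) + pseudocount)
  structure(list(log2cpm = mat,
                 tmm_factors = factors,
                 library_sizes = lib,
                 effective_library_sizes = eff,
                 metadata = cm$metadata),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("normalized_expression: ", nrow(x$log2cpm), " miRNAs x ",
      ncol(x$log2cpm), " samples (log2-CPM, TMM-effective library sizes)\n",
      sep = "")
  invisible(x)
}
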