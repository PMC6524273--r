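#' Build the covariate-adjusted design matrices for the group test
#'
#' Full model: intercept + group indicators (HC is the reference level, so one
#' column each for PC and BTC) + age + gender + BMI. The reduced model drops
#' the group columns. Age and BMI are centered and scaled to unit variance for
#' numerical conditioning; gender is coded 0/1 (F/M). Covariates may be
#' dropped (e.g. when metadata lacks them) via `covariates`.
#'
#' @param metadata Sample metadata data frame (`group`, `age`, `gender`, `bmi`).
#' @param covariates Character vector of adjustment covariates to include,
#'   any of `"age"`, `"gender"`, `"bmi"`.
#' @return List with `full` and `reduced` design matrices and `group_cols`,
#'   the columns dropped under the null.
#' @export
group_design <- function(metadata, covariates = c("age", "gender", "bmi")) {
  covariates <- match.arg(covariates, c("age", "gender", "bmi"),
                          several.ok = TRUE)
  n <- nrow(metadata)
  grp <- as.character(metadata$group)
  full <- cbind(`(Intercept)` = rep(1, n),
                groupPC  = as.numeric(grp == "PC"),
                groupBTC = as.numeric(grp == "BTC"))
  zscore <- function(x) {           # constant columns become all-zero,
    x <- as.numeric(x)              # caught below as rank deficiency
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  if ("age" %in% covariates) {
    if (anyNA(metadata$age)) stop("age contains NA; drop it from covariates")
    full <- cbind(full, age = zscore(metadata$age))
  }
  if ("gender" %in% covariates) {
    full <- cbind(full, genderM = as.numeric(metadata$gender == "M"))
  }
  if ("bmi" %in% covariates) {
    if (anyNA(metadata$bmi)) stop("bmi contains NA; drop it from covariates")
    full <- cbind(full, bmi = zscore(metadata$bmi))
  }
  qrf <- qr(full)
  if (qrf$rank < ncol(full)) {
    dropped <- colnames(full)[qrf$pivot[(qrf$rank + 1):ncol(full)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  group_cols <- c("groupPC", "groupBTC")
  list(full = full,
       reduced = full[, setdiff(colnames(full), group_cols), drop = FALSE],
       group_cols = group_cols)
}

#' Fit a negative-binomial log-link GLM to one miRNA
#'
#' Fits by iteratively reweighted least squares (relative tolerance 1e-8,
#' at most 50 iterations) at a fixed dispersion, with log effective library
#' sizes as offsets.
#'
#' @param y Integer counts, one per sample.
#' @param design Full-column-rank model matrix.
#' @param offsets Log effective library sizes, aligned with `y`.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2); 0 is
#'   treated as (near-)Poisson.
#' @return List with `coefficients`, `deviance`, `fitted` and `converged`.
#' @export
fit_nb_glm <- function(y, design, offsets = rep(0, length(y)), dispersion = 0) {
  stopifnot(length(y) == nrow(design), length(offsets) == length(y))
  theta <- 1 / max(dispersion, 1e-8)
  fit <- suppressWarnings(
    stats::glm.fit(x = design, y = y,
                   family = MASS::negative.binomial(theta = theta, link = "log"),
                   offset = offsets,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  list(coefficients = stats::setNames(fit$coefficients, colnames(design)),
       deviance = fit$deviance,
       fitted = fit$fitted.values,
       converged = isTRUE(fit$converged))
}

# NB log-likelihood at fitted means mu for dispersion phi
.nb_loglik <- function(y, mu, dispersion) {
  theta <- 1 / max(dispersion, 1e-8)
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

#' Estimate NB dispersions across miRNAs
#'
#' A self-contained two-step estimator. The common dispersion maximizes the
#' Cox-Reid adjusted profile likelihood summed over miRNAs on a grid of
#' log-dispersions. Per-miRNA dispersions are then a weighted average of each
#' miRNA's moment (pseudo-Pearson) estimate and the common value,
#' `shrink` of the weight going to the common value.
#'
#' @param cm A filtered [count_matrix()].
#' @param design Model matrix (the full design from [group_design()]).
#' @param offsets Log effective library sizes (default: log of raw library
#'   sizes scaled by TMM factors).
#' @param grid Candidate dispersions for the common estimate (log-spaced).
#' @param shrink Weight pulled toward the common dispersion (default 0.7).
#' @return List with `common` (scalar) and `dispersion` (per-miRNA vector).
#' @export
estimate_dispersion <- function(cm, design,
                                offsets = log(colSums(cm$counts) * tmm_factors(cm)),
                                grid = 10^seq(-4, 0.7, length.out = 24),
                                shrink = 0.7) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$counts
  if (all(apply(x, 1, function(r) length(unique(r)) == 1))) {
    warning("all miRNAs have identical counts across samples; dispersion floored")
    return(list(common = 1e-6,
                dispersion = rep(1e-6, nrow(x))))
  }
  # subsample rows for the grid search when the matrix is large
  rows <- seq_len(nrow(x))
  if (length(rows) > 400) {
    o <- order(rowMeans(x), decreasing = TRUE)
    rows <- o[round(seq(1, length(o), length.out = 400))]
  }
  apl_sum <- function(phi) {
    sum(vapply(rows, function(g) .cr_apl(x[g, ], design, offsets, phi),
               numeric(1)))
  }
  apl <- vapply(grid, apl_sum, numeric(1))
  i <- which.max(apl)
  # refine the grid maximum inside its bracketing interval, on the log scale
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  common <- if (lo < hi) {
    opt <- stats::optimize(function(lphi) apl_sum(exp(lphi)),
                           c(log(lo), log(hi)), maximum = TRUE, tol = 1e-3)
    exp(opt$maximum)
  } else grid[i]

  # per-miRNA moment estimate from a fit at the common dispersion
  p <- ncol(design)
  disp <- vapply(seq_len(nrow(x)), function(g) {
    y <- x[g, ]
    if (length(unique(y)) == 1 && stats::var(as.numeric(y)) == 0) return(1e-6)
    fit <- fit_nb_glm(y, design, offsets, common)
    mu <- pmax(fit$fitted, 1e-8)
    mom <- (sum((y - mu)^2 / mu^2) - sum(1 / mu)) / (length(y) - p)
    mom <- max(mom, 1e-6)
    max(shrink * common + (1 - shrink) * mom, 1e-6)
  }, numeric(1))
  names(disp) <- rownames(x)
  list(common = common, dispersion = disp)
}

# Cox-Reid adjusted profile log-likelihood for one miRNA at dispersion phi
.cr_apl <- function(y, design, offsets, phi) {
  fit <- fit_nb_glm(y, design, offsets, phi)
  mu <- pmax(fit$fitted, 1e-10)
  w <- mu / (1 + phi * mu)                   # IRLS working weights, log link
  xtwx <- crossprod(design * sqrt(w))
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  .nb_loglik(y, mu, phi) - 0.5 * as.numeric(ld)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, with the original order restored.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of FDR-adjusted values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Likelihood-ratio test for a group effect, adjusted for covariates
#'
#' For each miRNA, fits negative-binomial GLMs under the full (intercept +
#' group + covariates) and reduced (covariates only) models at that miRNA's
#' dispersion; the LR statistic is the deviance difference, referred to a
#' chi-square with 2 degrees of freedom, and p-values are BH-adjusted.
#' Pairwise log2 fold changes are read off the fitted group coefficients
#' (log2fc_PN = PC vs HC, log2fc_BN = BTC vs HC, log2fc_BP = BTC vs PC).
#'
#' @param cm A filtered [count_matrix()].
#' @param covariates Adjustment covariates, a subset of
#'   `c("age", "gender", "bmi")`.
#' @param factors Per-sample TMM factors (default computed from `cm`).
#' @param dispersion Optional per-miRNA dispersion vector; estimated via
#'   [estimate_dispersion()] when `NULL`.
#' @return Data frame with one row per miRNA: `mirna_id`, `log2fc_PN`,
#'   `log2fc_BN`, `log2fc_BP`, `lr_statistic`, `p_value`, `fdr`, `dispersion`,
#'   `converged`. Non-converged fits carry `NA` p-values and are excluded from
#'   the FDR adjustment (with a warning).
#' @export
lrt_group_effect <- function(cm, covariates = c("age", "gender", "bmi"),
                             factors = tmm_factors(cm), dispersion = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  des <- group_design(cm$metadata, covariates)
  offsets <- log(colSums(cm$counts) * factors)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(cm, des$full, offsets)$dispersion
  if (length(dispersion) == 1) dispersion <- rep(dispersion, nrow(cm$counts))

  res <- lapply(seq_len(nrow(cm$counts)), function(g) {
    y <- cm$counts[g, ]
    full <- fit_nb_glm(y, des$full, offsets, dispersion[g])
    red  <- fit_nb_glm(y, des$reduced, offsets, dispersion[g])
    lr <- max(red$deviance - full$deviance, 0)
    b <- full$coefficients
    data.frame(mirna_id = rownames(cm$counts)[g],
               log2fc_PN = b[["groupPC"]] / log(2),
               log2fc_BN = b[["groupBTC"]] / log(2),
               log2fc_BP = (b[["groupBTC"]] - b[["groupPC"]]) / log(2),
               lr_statistic = lr,
               p_value = stats::pchisq(lr, df = 2, lower.tail = FALSE),
               dispersion = dispersion[g],
               converged = full$converged && red$converged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  if (any(!res$converged)) {
    warning(sum(!res$converged),
            " miRNA fit(s) did not converge; excluded from FDR adjustment")
    res$p_value[!res$converged] <- NA_real_
  }
  res$fdr <- NA_real_
  ok <- !is.na(res$p_value)
  res$fdr[ok] <- bh_adjust(res$p_value[ok])
  res[, c("mirna_id", "log2fc_PN", "log2fc_BN", "log2fc_BP",
          "lr_statistic", "p_value", "fdr", "dispersion", "converged")]
}

#' Pairwise descriptive fold changes on normalized expression
#'
#' Computes, per miRNA, the difference of group mean log2-CPM for each of the
#' standard pairwise comparisons and flags changes exceeding a fold threshold.
#' Pair codes: `"PN"` = PC vs HC, `"BN"` = BTC vs HC, `"BP"` = BTC vs PC
#' (first group minus second).
#'
#' @param expr A `normalized_expression` object from [log2cpm()].
#' @param labels Group label per sample (default: the object's metadata).
#' @param pairs Which comparisons to compute.
#' @param threshold_fold Fold-change threshold for flagging (default 2).
#' @return Data frame with `mirna_id` and, per pair, `log2fc_<pair>`,
#'   `flag_<pair>` (logical, |log2FC| > log2(threshold)) and
#'   `direction_<pair>` (`"up"`/`"down"`).
#' @export
pairwise_log2fc <- function(expr, labels = expr$metadata$group,
                            pairs = c("BP", "PN", "BN"), threshold_fold = 2) {
  stopifnot(inherits(expr, "normalized_expression"))
  pair_def <- list(PN = c("PC", "HC"), BN = c("BTC", "HC"), BP = c("BTC", "PC"))
  bad <- setdiff(pairs, names(pair_def))
  if (length(bad)) stop("unknown pair code: ", paste(bad, collapse = ", "))
  out <- data.frame(mirna_id = rownames(expr$log2cpm),
                    stringsAsFactors = FALSE)
  for (p in pairs) {
    ga <- pair_def[[p]][1]; gb <- pair_def[[p]][2]
    if (!any(labels == ga) || !any(labels == gb))
      stop("empty group in pair ", p)
    fc <- rowMeans(expr$log2cpm[, labels == ga, drop = FALSE]) -
          rowMeans(expr$log2cpm[, labels == gb, drop = FALSE])
    out[[paste0("log2fc_", p)]] <- fc
    out[[paste0("flag_", p)]] <- abs(fc) > log2(threshold_fold)
    out[[paste0("direction_", p)]] <- ifelse(fc >= 0, "up", "down")
  }
  out
}
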