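#' Per-miRNA two-sample t tests on an independent expression table
#'
#' Re-tests candidate miRNAs on an external (typically qRT-PCR-derived)
#' normalized expression table with a two-sided two-sample t test between the
#' cancer and control groups. The Welch unequal-variance test is the default
#' (group sizes and variances differ in practice); no multiplicity correction
#' is applied — each candidate is a pre-specified hypothesis.
#'
#' @param expr_table Numeric matrix or data frame, samples in rows and miRNAs
#'   in columns (per-sample normalized expression). Missing values are
#'   dropped per miRNA.
#' @param labels `"cancer"` / `"control"` per sample (row).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return Data frame, one row per miRNA: `mirna_id`, `t_statistic`,
#'   `p_value`, `mean_cancer`, `mean_control`, `mean_difference`, `direction`
#'   (`"up"`/`"down"` in cancer) and `tested` (FALSE when a group was
#'   entirely missing, in which case the statistics are `NA`).
#' @export
ttest_per_mirna <- function(expr_table, labels, var_equal = FALSE) {
  m <- as.matrix(expr_table)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  bad <- setdiff(unique(labels), c("cancer", "control"))
  if (length(bad)) stop("labels must be cancer/control; got: ",
                        paste(bad, collapse = ", "))
  ids <- colnames(m)
  if (is.null(ids)) ids <- paste0("mirna_", seq_len(ncol(m)))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[labels == "cancer", j]; x <- x[!is.na(x)]
    y <- m[labels == "control", j]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(mirna_id = ids[j], t_statistic = NA_real_,
                        p_value = NA_real_, mean_cancer = NA_real_,
                        mean_control = NA_real_, mean_difference = NA_real_,
                        direction = NA_character_, tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = 0, p.value = 1)   # degenerate: identical groups
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    diff <- mean(x) - mean(y)
    data.frame(mirna_id = ids[j],
               t_statistic = unname(tt$statistic),
               p_value = tt$p.value,
               mean_cancer = mean(x), mean_control = mean(y),
               mean_difference = diff,
               direction = if (diff >= 0) "up" else "down",
               tested = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
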