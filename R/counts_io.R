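#' Construct a validated miRNA count matrix
#'
#' Bundles a raw read-count matrix (miRNAs in rows, samples in columns) with
#' its per-sample metadata and validates the pair. This is the container every
#' downstream stage of the pipeline consumes.
#'
#' @param counts Integer matrix of non-negative read counts, with rownames
#'   giving miRNA identifiers and colnames giving sample identifiers.
#' @param metadata Data frame with one row per sample and at least the columns
#'   `sample_id`, `group` (one of `"PC"`, `"BTC"`, `"HC"`), `age` (years),
#'   `gender` (`"M"`/`"F"`) and `bmi` (kg/m^2). Rows are matched to the count
#'   columns by `sample_id`; the column order of `counts` wins.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `metadata` (data frame aligned to the columns).
#' @export
count_matrix <- function(counts, metadata) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have miRNA rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate miRNA ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop("NA count at miRNA '", rownames(counts)[bad[1]], "', sample '",
         colnames(counts)[bad[2]], "'")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop("counts must be non-negative integers; offending cell: miRNA '",
         rownames(counts)[bad[1]], "', sample '", colnames(counts)[bad[2]], "'")
  }
  storage.mode(counts) <- "integer"

  metadata <- as.data.frame(metadata)
  required <- c("sample_id", "group", "age", "gender", "bmi")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate metadata sample ids: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]), collapse = ", "))
  absent <- setdiff(colnames(counts), metadata$sample_id)
  if (length(absent))
    stop("samples missing from metadata: ", paste(absent, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- metadata$sample_id
  bad_group <- setdiff(unique(as.character(metadata$group)), c("PC", "BTC", "HC"))
  if (length(bad_group))
    stop("unknown group labels: ", paste(bad_group, collapse = ", "))
  metadata$group <- as.character(metadata$group)

  structure(list(counts = counts, metadata = metadata), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " miRNAs x ", ncol(x$counts), " samples\n",
      sep = "")
  cat("groups: ", paste(sprintf("%s=%d", names(table(x$metadata$group)),
                                table(x$metadata$group)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and sample metadata from TSV files
#'
#' The counts file is tab-separated with the miRNA identifier in the first
#' column and a header row of sample identifiers; the metadata file has one
#' row per sample with columns `sample_id`, `group`, `age`, `gender`, `bmi`.
#' Sample order is taken from the counts header and metadata rows are joined
#' by `sample_id`.
#'
#' @param counts_path Path to the counts TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, metadata_path) {
  for (p in c(counts_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' @param cm A [count_matrix()].
#' @param counts_path Output path for the counts TSV.
#' @param metadata_path Optional output path for the metadata TSV.
#' @return `cm`, invisibly.
#' @export
write_counts <- function(cm, counts_path, metadata_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(mirna_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(cm$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(cm)
}

#' Filter miRNAs by minimum expression
#'
#' Retains miRNAs whose count exceeds `min_reads` (strictly) in at least
#' `min_samples` samples — the standard "expressed" screen applied before
#' normalization. Row order of retained miRNAs and the sample set are
#' unchanged; the operation is idempotent.
#'
#' @param cm A [count_matrix()].
#' @param min_reads Count a sample must strictly exceed to count as expressing
#'   the miRNA (default 10, i.e. at least 11 reads).
#' @param min_samples Minimum number of expressing samples (default 2).
#' @return The filtered [count_matrix()].
#' @export
filter_expressed <- function(cm, min_reads = 10, min_samples = 2) {
  stopifnot(inherits(cm, "count_matrix"), min_reads >= 0, min_samples >= 0)
  keep <- rowSums(cm$counts > min_reads) >= min_samples
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  out
}
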