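#' Map miRNAs to their target genes
#'
#' Takes a miRNA-to-gene interaction table (e.g. in the shape of an
#' experimentally curated target database export) and returns the
#' de-duplicated, sorted union of target genes of the given miRNAs. miRNAs
#' absent from the map contribute nothing, with a warning.
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @param target_map Data frame with columns `mirna_id` and `gene_symbol`
#'   (one interaction per row).
#' @return Sorted character vector of unique target genes.
#' @export
map_targets <- function(mirna_ids, target_map) {
  stopifnot(is.data.frame(target_map), nrow(target_map) > 0,
            all(c("mirna_id", "gene_symbol") %in% names(target_map)))
  absent <- setdiff(mirna_ids, target_map$mirna_id)
  if (length(absent))
    warning("miRNA(s) absent from target map: ",
            paste(absent, collapse = ", "))
  sort(unique(as.character(
    target_map$gene_symbol[target_map$mirna_id %in% mirna_ids])))
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (tab-separated: set name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Gene-set over-representation test
#'
#' For each gene set, forms the 2x2 table (list-and-set, list-not-set,
#' set-not-list, rest of the background) and computes the hypergeometric
#' upper-tail p-value of the overlap, the fold enrichment
#' `(overlap/list_size) / (set_size/background_size)`, and the Bonferroni
#' adjustment over the tested sets. The EASE variant subtracts one from the
#' overlap before the tail probability (conservative; overlap 0 or 1 then
#' yields p = 1).
#'
#' @param gene_list Character vector of genes of interest (intersected with
#'   the background).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Gene universe (default: union of all supplied sets).
#' @param ease Use the EASE-score variant (default FALSE).
#' @return Data frame sorted by p-value: `term`, `count`, `percent`,
#'   `p_value`, `fold_enrichment`, `bonferroni`, `set_size`, `genes`
#'   (comma-separated overlap).
#' @export
enrich <- function(gene_list, gene_sets,
                   background = sort(unique(unlist(gene_sets))),
                   ease = FALSE) {
  if (!length(background)) stop("background gene universe is empty")
  background <- unique(background)
  gene_list <- intersect(unique(gene_list), background)
  n_list <- length(gene_list)
  n_bg <- length(background)
  n_sets <- length(gene_sets)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), background)
    hits <- intersect(gene_list, set)
    count <- length(hits)
    q <- if (ease) max(count - 1, 0) else count
    # P(X >= q) drawing n_list from n_bg with length(set) successes
    p <- if (q == 0) 1 else
      stats::phyper(q - 1, length(set), n_bg - length(set), n_list,
                    lower.tail = FALSE)
    fe <- if (n_list == 0 || length(set) == 0) NA_real_ else
      (count / n_list) / (length(set) / n_bg)
    data.frame(term = term, count = count,
               percent = if (n_list) 100 * count / n_list else 0,
               p_value = p, fold_enrichment = fe,
               bonferroni = min(1, p * n_sets),
               set_size = length(set),
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
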