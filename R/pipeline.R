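#' Run the full discovery pipeline on a simulated cohort
#'
#' Chains simulate -> filter -> normalize -> differential expression ->
#' marker ranking/classification, writing each stage's table as TSV under
#' `out_dir`. Everything is deterministic given `seed`.
#'
#' Files written: `counts.tsv`, `meta.tsv`, `filtered.tsv`, `factors.tsv`,
#' `expr.tsv`, `de.tsv`, `ranking_two_group.tsv`, `cumulative_two_group.tsv`,
#' `contingency_three_group.tsv`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving the simulation.
#' @param sim_args List of overrides passed to [simulate_cohort()].
#' @param fdr FDR threshold selecting candidate markers (default 0.05).
#' @param k Number of KNN neighbours (default 11).
#' @param max_candidates Cap on the candidate set fed to the ranking stage
#'   (most-significant first; default 42).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(out_dir, seed = 1, sim_args = list(), fdr = 0.05,
                         k = 11, max_candidates = 42) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  tsv <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)

  sim <- do.call(simulate_cohort, c(list(seed = seed), sim_args))
  write_counts(sim$cm, p("counts.tsv"), p("meta.tsv"))

  filt <- filter_expressed(sim$cm)
  write_counts(filt, p("filtered.tsv"))

  factors <- tmm_factors(filt)
  tsv(data.frame(sample_id = names(factors),
                 library_size = colSums(filt$counts),
                 tmm_factor = factors), "factors.tsv")
  expr <- log2cpm(filt, factors)
  tsv(data.frame(mirna_id = rownames(expr$log2cpm), expr$log2cpm,
                 check.names = FALSE), "expr.tsv")

  de <- lrt_group_effect(filt, factors = factors)
  tsv(de, "de.tsv")

  sig <- de$mirna_id[!is.na(de$fdr) & de$fdr <= fdr]
  sig <- sig[order(de$fdr[match(sig, de$mirna_id)])]
  if (length(sig) > max_candidates) sig <- sig[seq_len(max_candidates)]
  results <- list(sim = sim, filtered = filt, expr = expr, de = de,
                  candidates = sig)

  if (length(sig) >= 1) {
    labels3 <- expr$metadata$group
    labels2 <- two_group_collapse(labels3)
    rank2 <- rank_and_accumulate(expr, labels2, sig, k = k)
    rank3 <- rank_and_accumulate(expr, labels3, sig, k = k)
    tsv(rank2$individual, "ranking_two_group.tsv")
    tsv(rank2$cumulative, "cumulative_two_group.tsv")
    best3 <- rank3$reports[[which.max(rank3$cumulative$cum_accuracy)]]
    cont <- as.data.frame.matrix(best3$contingency)
    tsv(cbind(predicted = rownames(cont), cont), "contingency_three_group.tsv")
    results$rank_two_group <- rank2
    results$rank_three_group <- rank3
  }
  invisible(results)
}
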