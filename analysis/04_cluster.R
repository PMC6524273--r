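#!/usr/bin/env Rscript
# Stage 4: sample structure — PCA and cluster-number estimation.
#
# PCA is run on all expressed miRNAs and on the DE subset; the optimal
# number of clusters is estimated by average silhouette width under Pearson
# and Spearman correlation distances with average-linkage hierarchical
# clustering.

library(seromiR)

filt <- read_counts("results/data/filtered.tsv", "results/data/meta.tsv")
expr <- log2cpm(filt, read.delim("results/factors.tsv")$tmm_factor)
de_ids <- readLines("results/de_ids.txt")

subsets <- list(all = rownames(expr$log2cpm), de = de_ids)
for (name in names(subsets)) {
  p <- pca_scores(expr, subset = subsets[[name]], n_components = 2)
  set <- subsets[[name]]
  out <- data.frame(sample_id = rownames(p$scores),
                    group = expr$metadata$group, p$scores)
  write.table(out, sprintf("results/pca_%s.tsv", name), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("PCA (%s, %d miRNAs): PC1 %.1f%%, PC2 %.1f%% of variance\n",
              name, length(set), 100 * p$explained[1], 100 * p$explained[2]))
}

prof <- estimate_optimal_k(expr$log2cpm[de_ids, ], k_max = 10)
write.table(prof$profile, "results/silhouette_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("optimal number of clusters (DE subset): pearson =",
    prof$chosen_k[["pearson"]], ", spearman =",
    prof$chosen_k[["spearman"]], "\n")
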