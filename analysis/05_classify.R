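#!/usr/bin/env Rscript
# Stage 5: KNN biomarker evaluation.
#
# The FDR-significant miRNAs are ranked by individual LOOCV accuracy and
# added one by one to the KNN feature set (k = 11, Euclidean distance on
# log2-CPM), for the three-group task (PC / BTC / HC) and the two-group task
# (cancer vs control). The contingency table of the best three-group model
# shows where the two cancers are confused. A bootstrap over k checks the
# choice of the number of neighbours.

library(seromiR)

filt <- read_counts("results/data/filtered.tsv", "results/data/meta.tsv")
expr <- log2cpm(filt, read.delim("results/factors.tsv")$tmm_factor)
de <- read.delim("results/de.tsv")
candidates <- readLines("results/de_ids.txt")
candidates <- candidates[order(de$fdr[match(candidates, de$mirna_id)])]
if (length(candidates) > 42) candidates <- candidates[1:42]

labels3 <- expr$metadata$group
labels2 <- two_group_collapse(labels3)

rank3 <- rank_and_accumulate(expr, labels3, candidates, k = 11)
rank2 <- rank_and_accumulate(expr, labels2, candidates, k = 11)

write.table(rank3$cumulative, "results/cumulative_three_group.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rank2$individual, "results/ranking_two_group.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rank2$cumulative, "results/cumulative_two_group.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

b3 <- which.max(rank3$cumulative$cum_accuracy)
b2 <- which.max(rank2$cumulative$cum_accuracy)
cat(sprintf("three-group: best cumulative accuracy %.1f%% at %d miRNA(s)\n",
            100 * rank3$cumulative$cum_accuracy[b3], b3))
cat(sprintf("two-group:   best cumulative accuracy %.1f%% at %d miRNA(s)\n",
            100 * rank2$cumulative$cum_accuracy[b2], b2))

best3 <- rank3$reports[[b3]]
cont <- as.data.frame.matrix(best3$contingency)
write.table(cbind(predicted = rownames(cont), cont),
            "results/contingency_three_group.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("three-group contingency (predicted x true):\n")
print(best3$contingency)
cat(sprintf("BTC sensitivity %.1f%%: most BTC samples land in the PC row\n",
            100 * best3$sensitivity[["BTC"]]))

sel <- select_k_bootstrap(expr, labels2,
                          feature_set = rank2$individual$mirna_id[1:3],
                          B = 200, seed = 20260920L)
write.table(sel$per_k, "results/bootstrap_k.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("bootstrap-selected k:", sel$chosen_k, "\n")
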