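#!/usr/bin/env Rscript
# Stage 2: expression filter and TMM normalization.
#
# miRNAs with more than 10 reads in at least two samples are kept; TMM
# scaling factors put samples on a common composition scale and expression is
# reported as log2-CPM with pseudocount 1 on TMM-effective library sizes.

library(seromiR)

cm <- read_counts("results/data/counts.tsv", "results/data/meta.tsv")
filt <- filter_expressed(cm, min_reads = 10, min_samples = 2)
cat("expressed miRNAs:", nrow(filt$counts), "of", nrow(cm$counts), "\n")
write_counts(filt, "results/data/filtered.tsv")

factors <- tmm_factors(filt)
write.table(data.frame(sample_id = names(factors),
                       library_size = colSums(filt$counts),
                       tmm_factor = factors),
            "results/factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("TMM factors in [", round(min(factors), 3), ",",
    round(max(factors), 3), "]\n")

expr <- log2cpm(filt, factors)
write.table(data.frame(mirna_id = rownames(expr$log2cpm), expr$log2cpm,
                       check.names = FALSE),
            "results/expr_log2cpm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
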