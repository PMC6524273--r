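#!/usr/bin/env Rscript
# Stage 1: generate the study cohorts.
#
# The discovery cohort mirrors a 24 PC / 10 BTC / 21 HC serum miRNA-seq
# study: 677 miRNAs, 42 planted dysregulated ones (80% shared between the two
# cancer groups), NB counts with dispersion 0.2, library sizes 0.5-2 M, and
# deliberately confounded covariates (cancer patients ~19 y older). A second,
# independent Gaussian expression table stands in for the qRT-PCR validation
# cohort (34 cancer vs 19 control).

library(seromiR)

seed <- 20260920L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

sim <- simulate_cohort(seed = seed)
write_counts(sim$cm, "results/data/counts.tsv", "results/data/meta.tsv")
writeLines(sim$truth$de_ids, "results/data/planted_de_ids.txt")
cat("discovery cohort:", nrow(sim$cm$counts), "miRNAs x",
    ncol(sim$cm$counts), "samples;", length(sim$truth$de_ids),
    "planted DE miRNAs\n")

qp <- simulate_qpcr(mirnas = c("sim-mir-A", "sim-mir-B", "sim-mir-C"),
                    effect_sizes = c(2, -0.8, 0.6), seed = seed + 1L)
write.table(data.frame(sample_id = rownames(qp$expr), label = qp$labels,
                       qp$expr, check.names = FALSE),
            "results/data/qpcr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("validation table:", nrow(qp$expr), "samples x", ncol(qp$expr),
    "miRNAs\n")
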