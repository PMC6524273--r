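#!/usr/bin/env Rscript
# Stage 6: validation on the independent expression table.
#
# Each candidate miRNA is re-tested with a two-sided Welch t test between
# the cancer and control groups of the validation cohort; no multiplicity
# correction is applied since each candidate is a pre-specified hypothesis.

library(seromiR)

tab <- read.delim("results/data/qpcr.tsv", check.names = FALSE)
expr <- as.matrix(tab[, setdiff(names(tab), c("sample_id", "label"))])
rownames(expr) <- tab$sample_id

val <- ttest_per_mirna(expr, tab$label)
write.table(val, "results/validation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (i in seq_len(nrow(val)))
  cat(sprintf("%s: t = %.2f, p = %.3g, %s in cancer\n",
              val$mirna_id[i], val$t_statistic[i], val$p_value[i],
              val$direction[i]))
cat(sum(val$p_value < 0.05, na.rm = TRUE), "of", nrow(val),
    "validated at p < 0.05\n")
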