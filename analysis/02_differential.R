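#!/usr/bin/env Rscript
# Per-metabolite differential statistics: Welch's t-test between the two
# simulated groups, log2 fold changes, BH FDR and direction calls.

suppressPackageStartupMessages(library(nbmet))
dir.create("results", showWarnings = FALSE)

fm <- read_feature_matrix("results/data/metabolomics_matrix.tsv")
grp <- read.table("results/data/metabolomics_groups.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
fm$sample_metadata$group <- grp$group[match(rownames(fm$values), grp$sample_id)]

diff <- differential_table(fm, comparison = c("group2", "group1"),
                           method = "welch", alpha = 0.05)
write.table(diff, "results/differential_metabolites.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.table("results/data/metabolomics_truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
planted_sp <- truth$sub_pathway[truth$direction != "null"]
ann <- read.table("results/data/metabolomics_annotation.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
planted_feats <- ann$feature_id[ann$sub_pathway %in% planted_sp]

n_sig <- sum(diff$p <= 0.05, na.rm = TRUE)
sig_planted <- sum(diff$p <= 0.05 & diff$feature_id %in% planted_feats,
                   na.rm = TRUE)
cat(sprintf("Tested %d metabolites; %d significant at p <= 0.05 (%d of them planted).\n",
            nrow(diff), n_sig, sig_planted))
cat(sprintf("Median |log2FC| among planted features: %.2f; among null features: %.2f\n",
            median(abs(diff$log2FC[diff$feature_id %in% planted_feats]), na.rm = TRUE),
            median(abs(diff$log2FC[!diff$feature_id %in% planted_feats]), na.rm = TRUE)))
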