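#!/usr/bin/env Rscript
# Generate the synthetic study datasets with known ground truth: a
# metabolomics experiment with planted glycerolipid subpathway shifts, a
# lipidomics experiment with a planted TG/DG accumulation, an expression
# cohort driven by a latent oncogene-activity variable, and a synergistic
# two-drug viability grid. Later drivers re-analyze these files.

suppressPackageStartupMessages(library(nbmet))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

# Metabolomics: MNA-like group2 vs group1, DG and TG planted up, one amino
# acid subpathway planted down (effect sizes in log2 units).
cfg_met <- sim_config(
  n_samples_per_group = 18,   # matches a 18 vs 18 tumor comparison
  n_subpathways = 20, metabolites_per_subpathway = 5,
  planted_effects = list(
    Diacylglycerol = list(direction = "up", effect = 2),
    Triacylglycerol = list(direction = "up", effect = 1.5),
    `Urea cycle` = list(direction = "down", effect = 1)
  ),
  noise_sd = 1, missing_fraction = 0.05, seed = 20261002
)
met <- simulate_metabolomics(cfg_met)
write_feature_matrix(met$matrix, "results/data/metabolomics_matrix.tsv")
write.table(data.frame(sample_id = rownames(met$matrix$values),
                       met$matrix$sample_metadata),
            "results/data/metabolomics_groups.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(met$annotation, "results/data/metabolomics_annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_metabolite_sets_gmt(annotation_to_sets(met$annotation),
                          "results/data/metabolomics_subpathways.gmt")
write.table(met$truth, "results/data/metabolomics_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# Lipidomics: TG and DG classes planted up (glycerolipid accumulation).
cfg_lip <- sim_config(
  n_samples_per_group = 8, n_subpathways = 10, metabolites_per_subpathway = 6,
  planted_effects = list(TG = list(direction = "up", effect = 2),
                         DG = list(direction = "up", effect = 2)),
  noise_sd = 1, seed = 20261003
)
lip <- simulate_lipidomics(cfg_lip)
write_feature_matrix(lip$matrix, "results/data/lipidomics_matrix.tsv")
write.table(data.frame(sample_id = rownames(lip$matrix$values),
                       lip$matrix$sample_metadata),
            "results/data/lipidomics_groups.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(lip$truth, "results/data/lipidomics_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# Expression cohort: 500 patients, a 40-gene up/down signature at effect 2.
cohort <- simulate_expression_cohort(
  n_patients = 500,
  signature = list(up = sprintf("UPG%02d", 1:20), down = sprintf("DNG%02d", 1:20)),
  effect = 2, seed = 20261004
)
write_feature_matrix(cohort$matrix, "results/data/cohort_expression.tsv")
write.table(cohort$clinical, "results/data/cohort_clinical.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# Dose grid: 3x3 combination with a planted +15 point Bliss excess.
grid <- simulate_dose_grid(doses_a = c(0.4, 1, 2.5), doses_b = c(5, 20, 50),
                           model = "synergistic", excess = 15, reps = 3,
                           noise_sd = 2, seed = 20261005)
write.table(grid, "results/data/dose_grid.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated datasets written under results/data/:\n")
cat(sprintf("  metabolomics: %d samples x %d metabolites, planted %s\n",
            nrow(met$matrix$values), ncol(met$matrix$values),
            paste(names(cfg_met$planted_effects), collapse = ", ")))
cat(sprintf("  lipidomics:   %d samples x %d species, planted TG/DG up\n",
            nrow(lip$matrix$values), ncol(lip$matrix$values)))
cat(sprintf("  cohort:       %d patients, %d genes, %d MNA-labelled\n",
            nrow(cohort$matrix$values), ncol(cohort$matrix$values),
            sum(cohort$clinical$mna)))
cat(sprintf("  dose grid:    %d cells x %d replicates, planted excess +15\n",
            16L, 3L))
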