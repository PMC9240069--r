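---
title: "Methods: subpathway-level metabolomics, lipid chain analysis, signature survival and Bliss synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subpathway-level metabolomics, lipid chain analysis, signature survival and Bliss synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented in `nbmet`, the
defaults they ship with, the numerical conventions that affect results at
the margin, and the scope and limits of the synthetic-data generators. The
package targets a recurring analysis pattern in cancer metabolism studies:
an oncogene-driven tumor model is profiled by untargeted metabolomics and
lipidomics, the perturbed subpathways are ranked, the lipid-level changes
are decomposed into fatty-acyl chains, a transcriptional signature of the
driver is scored against patient survival, and a candidate transporter is
tested for drug synergy.

## 1. Differential statistics

`differential_table()` computes per-feature two-group statistics. Raw
intensity matrices are log2-transformed before testing, so fold changes and
test statistics live on the same additive scale. The default test is
Welch's t (`stats::t.test`, unequal variances), with Student's t and
one-way ANOVA (`stats::oneway.test`, `var.equal = TRUE`) as alternatives.
Multiplicity is handled by Benjamini–Hochberg FDR (`stats::p.adjust`).
Features with fewer than `min_n = 2` complete observations per group are
reported with `NA` statistics rather than dropped, so the output always has
one row per measured feature.

For raw-unit matrices the fold change is `log2(mean(test) / mean(ref))`
(ratio of arithmetic means on the intensity scale); for log2 matrices it is
the difference of group means. The lipidomics driver illustrates the
distinction: tests run on normalized log2 values while the selection rule
uses intensity-scale fold changes.

`median_iqr_normalize()` log2-transforms first, then centers each sample at
its median and scales by its IQR. Doing the transform first keeps the
median/IQR statistics on the scale on which the tests run; samples with
zero IQR are flagged via the `zero_iqr` attribute instead of silently
producing infinities.

## 2. Differential-abundance (DA) scores and subpathway ranking

The DA score of a subpathway is

```
DA = (n_up - n_down) / n_measured * 100
```

where `n_up`/`n_down` count members with raw p <= 0.05 (not FDR) in each
direction and `n_measured` counts all annotated members present in the
differential table. Raw p is deliberate at this stage: the score is a
descriptive direction summary, and the FDR control happens one level up, at
the subpathway enrichment test. A subpathway enters the score table when it
has at least `min_altered = 3` significantly altered members
(`rule = "altered"`, the default); `rule = "measured"` relaxes this to at
least 3 measured members and is the appropriate choice when screening for
planted signal in simulations, where power per metabolite varies.

Each scored subpathway also gets an over-representation p-value: the
upper-tail hypergeometric probability (`stats::phyper`) of drawing at least
the observed number of significant members, given the total significant
count in the measured universe. Stars mark subpathways at ORA FDR < 0.25.
`rank_subpathways()` orders subpathways by star count across conditions
(descending), then mean |DA| (descending), then name — so reproducibly
enriched pathways outrank single large excursions.

## 3. GSEA-style enrichment with a random-set null

`gsea_enrichment()` implements a weighted Kolmogorov–Smirnov running-sum
enrichment score on a ranked metabolite list. The ranking metric is
signal-to-noise, `(mu1 - mu2) / (sd1 + sd2)`, with each SD floored at
`max(0.2 * |mu|, 1e-8)` so near-constant features cannot dominate the
ranking through vanishing denominators. The ES is computed analytically
from the hit positions (O(n log n) per permutation) rather than by scanning
the full running sum; when the maximal positive and negative deviations tie
in magnitude within 1e-12, the positive one is reported.

The null distribution is built from random metabolite sets of the same
size drawn from the ranked universe (`n_perm = 10000` by default; one
shared null per distinct set size). The permutation p-value is one-sided in
the sign of the observed ES:

```
p = (1 + #{ null ES with same sign, |null| >= |ES| }) / (#same-sign + 1)
```

The denominator counts only same-sign null draws. Normalizing by all
permutations would cap the p-value near the same-sign fraction (~0.5) and
break uniformity of p under the null, which is an invariant the test suite
checks by Kolmogorov–Smirnov against U(0,1). The +1 terms keep p >= 1 /
(n_perm + 1), so significance is never overstated beyond the Monte-Carlo
resolution. NES is ES divided by the mean |null ES| over same-sign draws.

## 4. Lipid nomenclature and chain analysis

`parse_lipid_name()` understands the shorthand used by lipidomics vendors:
a class code (TG, DG, PC, PE, PS, PI, PG, PA, SM, Cer, CE, MG, LPC, LPE,
CL, …) followed by either per-chain notation (`TG(16:0/18:1/18:2)`) or sum
notation (`TG 52:3`). Each class carries a fixed chain arity (TG = 3,
CL = 4, diacyl classes = 2, lyso/CE/MG = 1) used to validate per-chain
notation and to interpret sum notation. `chain_composition()` tabulates
chain frequencies over a species list (sum-notation species contribute no
chains and are flagged), which is how an "altered lipids" list is reduced
to its constituent fatty acids.

The desaturation index is a ratio of a monounsaturated to its saturated
precursor chain amount (e.g. 16:1/16:0); pairs with a missing or zero
denominator come back `NA` with the reason recorded in an `errors`
attribute. `tracer_uptake()` ((initial − remaining labeled substrate) per
mg protein), `desaturase_activity()` (labeled product / labeled substrate)
and the linear calibration pair `fit_calibration_curve()` /
`concentration_from_calibration()` (inverse prediction from an
internal-standard response ratio) cover the targeted quantification steps.

## 5. Signature activity and survival

`zscore_genes()` standardizes each gene across the cohort using the sample
SD (`stats::sd`, n−1 denominator) — the conventional choice for cohort
z-scores; zero-SD genes become all-zero and are flagged rather than
dropped. The activity score of an up/down signature is the sum of up-gene
z-scores minus the sum of down-gene z-scores per sample.

`masked_correlations()` reports pairwise Pearson r with two-sided p-values
and masks entries with p >= 0.05 — the heat-map convention of showing only
significant correlations.

`tertile_stratify()` cuts at the empirical 1/3 and 2/3 quantiles; a value
exactly on a boundary goes to the lower stratum, so ties cannot inflate
the top group. `km_logrank()` wraps `survival::survfit` and
`survival::survdiff` for two-group product-limit curves and the 1-df
log-rank chi-square. `geneset_survival_ranking()` runs the top-vs-bottom
tertile log-rank per gene and endpoint and calls a gene `red` (high
expression harmful) when p < 0.05 and the top tertile shows more observed
than expected events, `blue` for the reverse, `gray` otherwise.
`dependency_rank()` aggregates CRISPR gene-effect scores per disease
(mean by default; median available) and ranks ascending, so the most
dependent lineage is first.

## 6. Bliss synergy

`bliss_synergy()` converts viabilities to inhibition fractions (clipping to
[0, 1] with a flag), averages replicates per dose cell, and compares each
combination cell against the Bliss independence expectation
`e = iA + iB − iA·iB` from the matching single-agent margins. The per-cell
excess is `(observed − expected) × 100` percentage points and the summary
score is the mean over combination cells. Calls use strict thresholds
(synergy > 10, antagonism < −10) with a 1e-9 guard, so a score that is
exactly 10 up to floating-point error is classified additive, not synergy.
`replicate_handling = "average_scores"` instead scores each replicate's
grid and averages the scores; with complete grids the two conventions agree
in expectation and the driver prints both.

## 7. Synthetic-data generators: scope and defaults

The generators exist to produce datasets with known ground truth for
validating the pipeline; they are deliberately simple.

- `simulate_metabolomics()`: baseline log2 abundances ~ N(20, 2) per
  metabolite, i.i.d. Gaussian noise (`noise_sd = 1`) per sample, additive
  log2 shifts applied to every member of a planted subpathway in group 2,
  and left-censoring of the lowest intensities at `missing_fraction`.
  Defaults (20 subpathways × 5 metabolites, 10 samples per group) give
  moderate per-metabolite power, which is the realistic regime for the
  subpathway-level methods.
- `simulate_lipidomics()`: same intensity model (baseline N(18, 2)) over
  species named with per-chain notation drawn from a chain pool, with
  class-level planted shifts.
- `simulate_expression_cohort()`: a latent driver-activity variable
  shifts the signature genes (up-genes up, down-genes down) and sets an
  exponential survival hazard proportional to `exp(0.7 × latent)`; the
  amplified-driver label is the top latent tertile with a small flip error,
  so label and survival are correlated but not deterministic.
- `simulate_dose_grid()`: Hill-shaped single-agent margins with EC50 at
  the top dose (keeping single-agent inhibition ≤ 50%), an optional
  planted Bliss excess in the combination cells, Gaussian viability noise,
  and renormalization to the (0, 0) anchor. At zero noise the pipeline
  recovers the planted excess exactly.

All generators take a seed and use `withr::with_seed`, so they never
disturb the caller's RNG state. What they do **not** model: feature–feature
correlation, batch effects, heteroscedastic or intensity-dependent noise,
non-additive effects, informative censoring, or missingness mechanisms
beyond left-censoring.

## 8. Monte-Carlo sizes used in validation

The test suite cross-checks every nontrivial computation against an
independent oracle: BH against a literal step-up implementation over 1000
random p-vectors, the hypergeometric ORA against exhaustive enumeration for
universes up to 12, the analytic ES against a full running-sum scan, the
log-rank chi-square against an observed-minus-expected hand computation
with tie variance, and GSEA null uniformity with 1000 random sets at
`n_perm = 199`. Planted-signal recovery (the glycerolipid subpathway
ranking first) is required in at least 95 of 100 seeds at the generator
defaults. These sizes balance statistical resolution against a test-suite
runtime of well under a minute.

## 9. External datasets

Several analyses are designed to run on published datasets that cannot be
redistributed with the package. Place the files below (tab-separated,
with a header) under `external_data_dir()` — i.e.
`tools::R_user_dir("nbmet", "data")` — and the corresponding tests and
analyses activate; absent files produce an honest failure, never a silent
skip.

| file | contents |
|---|---|
| `metabolomics_mycn3_matrix.tsv`, `metabolomics_mycn3_groups.tsv` | inducible-driver cell-line metabolomics: samples × metabolites matrix; `sample_id`, `group` |
| `metabolomics_lan5_matrix.tsv`, `metabolomics_lan5_groups.tsv` | knockdown cell-line metabolomics, same layout |
| `metabolomics_tumor_matrix.tsv`, `metabolomics_tumor_groups.tsv` | amplified vs non-amplified tumor metabolomics, same layout |
| `metabolomics_cells_annotation.tsv`, `metabolomics_tumor_annotation.tsv` | `feature_id`, `super_pathway`, `sub_pathway` |
| `avana_20q4v2_slc27a2.tsv` | CRISPR gene effect: `cell_line`, `disease`, `SLC27A2` |
| `gse45547_clinical.tsv` | tumor cohort clinical table including `mycn_amplified` |

## 10. Known limitations

- The ORA universe is the set of measured, annotated metabolites; pathway
  cross-talk and overlapping annotations are not modeled.
- The GSEA null permutes metabolite labels, not samples, so it tests set
  coherence given the observed ranking rather than the group labels.
- `km_logrank()` is strictly two-group, 1 df; stratified or multi-group
  log-rank tests are out of scope.
- The Bliss score treats each combination cell equally; no dose-surface
  smoothing or confidence interval is attempted.
- Calibration fitting is ordinary least squares on a presumed-linear
  response range; no weighting or lack-of-fit diagnostics.
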