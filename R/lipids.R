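# Lipid class vocabulary and fatty-acyl chain arity (number of chains when
# written in per-chain notation). lyso and plasmenyl variants are distinct
# classes with their own arity.
LIPID_CLASS_ARITY <- c(
  MG = 1, DG = 2, TG = 3,
  PC = 2, PE = 2, PG = 2, PI = 2, PS = 2, PA = 2,
  CE = 1, SM = 2, CL = 4, dhCER = 2,
  MGDG = 2, DGDG = 2,
  `lyso.PC` = 1, `lyso.PE` = 1,
  `plasmenyl.PC` = 2, `plasmenyl.PE` = 2
)

#' Parse a lipid name into class and fatty-acyl chains
#'
#' Accepts names of the form `CLASS(C1:D1/C2:D2/...)` with explicit chains
#' (e.g. `TG(16:0/18:1/16:1)`) or sum notation `CLASS(C:D)` (e.g.
#' `TG(52:2)`), where `C` is the carbon count and `D` the number of double
#' bonds. Per-chain vs sum notation is distinguished by comparing the chain
#' token count with the class arity (TG = 3 chains, DG/PC/PE/... = 2,
#' lyso/CE = 1, CL = 4). Ether/oxidized modifiers are rejected rather than
#' guessed.
#'
#' @param name lipid name string.
#' @return A `lipid_species`: list with `class_code`, `chains` (two-column
#'   matrix carbons/double_bonds), `sum_notation`, `raw_name`.
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  m <- regmatches(name, regexec("^([A-Za-z.]+)\\(([^()]*)\\)$", name))[[1]]
  if (length(m) != 3) stop("malformed lipid name: '", name, "'")
  cls <- m[2]
  if (!cls %in% names(LIPID_CLASS_ARITY)) stop("unknown lipid class: '", cls, "'")
  tokens <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  if (length(tokens) == 0) stop("no chain tokens in '", name, "'")
  chains <- t(vapply(tokens, function(tok) {
    cm <- regmatches(tok, regexec("^([0-9]+):([0-9]+)$", tok))[[1]]
    if (length(cm) != 3) stop("malformed chain token '", tok, "' in '", name, "'")
    c(carbons = as.integer(cm[2]), double_bonds = as.integer(cm[3]))
  }, c(carbons = 0L, double_bonds = 0L)))
  rownames(chains) <- NULL
  if (any(chains[, "carbons"] <= 0)) stop("chain with zero carbons in '", name, "'")
  arity <- LIPID_CLASS_ARITY[[cls]]
  sum_notation <- length(tokens) == 1L && arity > 1L
  if (!sum_notation && length(tokens) != arity)
    stop("class ", cls, " expects ", arity, " chain(s), got ", length(tokens),
         " in '", name, "'")
  structure(
    list(class_code = cls, chains = chains, sum_notation = sum_notation,
         raw_name = name),
    class = "lipid_species"
  )
}

#' Canonical lipid name from a parsed species
#'
#' @param species a `lipid_species`.
#' @return character name, `CLASS(C:D/...)`.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  toks <- paste0(species$chains[, "carbons"], ":", species$chains[, "double_bonds"])
  paste0(species$class_code, "(", paste(toks, collapse = "/"), ")")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(format_lipid_name(x),
      if (x$sum_notation) " [sum notation]" else "", "\n", sep = "")
  invisible(x)
}

#' Select significantly altered lipids
#'
#' Filters a differential table to records with `fdr < fdr_max` and
#' `|log2FC| > min_abs_log2fc` (both strict inequalities), split by sign —
#' the selection rule used for lipidomics heatmaps.
#'
#' @param diff a [differential_table()] result.
#' @param fdr_max FDR ceiling (default 0.25).
#' @param min_abs_log2fc absolute log2FC floor (default 0, i.e. FDR only).
#' @return the selected subset with an added `sign` column in {up, down}.
#' @export
select_altered_lipids <- function(diff, fdr_max = 0.25, min_abs_log2fc = 0) {
  keep <- !is.na(diff$fdr) & diff$fdr < fdr_max &
    !is.na(diff$log2FC) & abs(diff$log2FC) > min_abs_log2fc
  out <- diff[keep, , drop = FALSE]
  out$sign <- ifelse(out$log2FC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Fatty-acyl chain composition
#'
#' Counts chain occurrences across species with explicit chains and reports
#' each chain's frequency among all chain occurrences (frequencies sum to 1).
#' Sum-notation species are excluded and counted in the `n_sum_notation`
#' attribute.
#'
#' @param species list of `lipid_species` (or character names, parsed here).
#' @return data.frame with columns `chain` ("C:D"), `count`, `frequency`,
#'   ordered by descending frequency then chain.
#' @export
chain_composition <- function(species) {
  if (length(species) == 0) stop("chain_composition: empty input")
  if (is.character(species)) species <- lapply(species, parse_lipid_name)
  explicit <- Filter(function(s) !s$sum_notation, species)
  n_sum <- length(species) - length(explicit)
  if (length(explicit) == 0)
    stop("chain_composition: all species are in sum notation; nothing countable")
  chains <- unlist(lapply(explicit, function(s)
    paste0(s$chains[, "carbons"], ":", s$chains[, "double_bonds"])))
  tab <- table(chains)
  out <- data.frame(chain = names(tab), count = as.integer(tab),
                    frequency = as.numeric(tab) / length(chains),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sum_notation") <- n_sum
  out
}

#' Desaturation indices
#'
#' Ratios of monounsaturated to saturated fatty-acid abundance for the
#' requested pairs (e.g. 16:1/16:0, 14:1/14:0), the readout of
#' stearoyl-CoA-desaturase activity on profiled fatty acids.
#'
#' @param abundances named numeric vector, chain "C:D" -> amount.
#' @param pairs list of `c(unsaturated, saturated)` chain pairs.
#' @return data.frame with columns `unsaturated`, `saturated`, `ratio`;
#'   a pair with zero or missing saturated abundance gets `NA` with a
#'   message in the `errors` attribute, other pairs are still returned.
#' @export
desaturation_index <- function(abundances, pairs) {
  rows <- lapply(pairs, function(p) {
    u <- abundances[[p[1]]]; s <- abundances[[p[2]]]
    err <- NULL
    ratio <- if (is.null(u) || is.null(s)) {
      err <- paste0(p[1], "/", p[2], ": missing abundance"); NA_real_
    } else if (s <= 0) {
      err <- paste0(p[1], "/", p[2], ": zero saturated denominator"); NA_real_
    } else u / s
    list(row = data.frame(unsaturated = p[1], saturated = p[2], ratio = ratio,
                          stringsAsFactors = FALSE),
         err = err)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  errs <- unlist(lapply(rows, `[[`, "err"))
  if (length(errs) == length(pairs)) stop("desaturation_index: every pair failed: ",
                                          paste(errs, collapse = "; "))
  attr(out, "errors") <- errs
  out
}

#' Labeled fatty-acid uptake from tracer medium depletion
#'
#' Uptake = (initial labeled FA in medium - remaining labeled FA in medium)
#' normalized by total protein. A negative difference (remaining > initial)
#' is a measurement inconsistency: the value is still returned, flagged.
#'
#' @param initial_medium_labeled,remaining_medium_labeled nmol of labeled FA.
#' @param protein_mg total protein (mg), must be positive.
#' @return nmol per mg protein; attribute `flagged_negative` when the
#'   difference is negative.
#' @export
tracer_uptake <- function(initial_medium_labeled, remaining_medium_labeled, protein_mg) {
  if (protein_mg <= 0) stop("protein mass must be positive")
  if (initial_medium_labeled < 0 || remaining_medium_labeled < 0)
    stop("labeled amounts must be non-negative")
  val <- (initial_medium_labeled - remaining_medium_labeled) / protein_mg
  if (val < 0) attr(val, "flagged_negative") <- TRUE
  val
}

#' Fatty-acid desaturase activity from tracer incorporation
#'
#' Ratio of labeled monounsaturated FA to labeled saturated FA (e.g.
#' [13C16]16:1 / [13C16]16:0) after a uniformly labeled palmitate pulse.
#'
#' @param labeled_mono,labeled_sat nmol of labeled FA; `labeled_sat` > 0.
#' @return the ratio.
#' @export
desaturase_activity <- function(labeled_mono, labeled_sat) {
  if (labeled_sat <= 0) stop("labeled saturated FA must be positive")
  if (labeled_mono < 0) stop("labeled amounts must be non-negative")
  labeled_mono / labeled_sat
}

#' Fit a calibration curve of response ratio vs concentration
#'
#' Ordinary least-squares line through (concentration, analyte/internal
#' standard area ratio) points, used to back-calculate FA concentrations.
#'
#' @param concentration,ratio numeric vectors with at least two distinct
#'   concentrations.
#' @return a `calibration_curve`: list with `slope`, `intercept`, `range`
#'   (ratio range spanned by the calibration points).
#' @export
fit_calibration_curve <- function(concentration, ratio) {
  if (length(unique(concentration)) < 2)
    stop("calibration needs at least two distinct concentrations")
  fit <- stats::lm(ratio ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("calibration slope is zero")
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         range = range(ratio)),
    class = "calibration_curve"
  )
}

#' Back-calculate a concentration from a calibration curve
#'
#' Inverse prediction `(ratio - intercept) / slope`. Ratios outside the
#' range covered by the calibration points are extrapolations: the value is
#' returned with an `extrapolated` flag.
#'
#' @param ratio observed analyte / internal-standard response ratio.
#' @param curve a [fit_calibration_curve()] result.
#' @return concentration; attribute `extrapolated` when out of range.
#' @export
concentration_from_calibration <- function(ratio, curve) {
  if (!inherits(curve, "calibration_curve")) stop("`curve` must be a fitted calibration_curve")
  val <- (ratio - curve$intercept) / curve$slope
  if (ratio < curve$range[1] || ratio > curve$range[2])
    attr(val, "extrapolated") <- TRUE
  val
}

#' Labeled fraction of a fatty-acid pool
#'
#' Simplified de novo lipogenesis readout from heavy-water labeling:
#' labeled amount over total (labeled + unlabeled) pool.
#'
#' @param labeled,unlabeled nmol; total must be positive.
#' @return fraction in `[0, 1]`.
#' @export
labeled_fraction <- function(labeled, unlabeled) {
  if (labeled < 0 || unlabeled < 0) stop("pool amounts must be non-negative")
  tot <- labeled + unlabeled
  if (tot <= 0) stop("empty pool: labeled + unlabeled must be positive")
  labeled / tot
}
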