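#' Per-gene Z-scores across a cohort
#'
#' Standardizes each gene (feature) to mean 0, sample SD 1 across samples.
#' Zero-SD genes are emitted as all-zero and flagged in the `zero_sd`
#' attribute.
#'
#' @param fm a [feature_matrix()] with >= 2 samples.
#' @return a log2-unit [feature_matrix()] of Z-scores.
#' @export
zscore_genes <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (nrow(v) < 2) stop("zscore_genes needs at least 2 samples")
  mu <- colMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 2, stats::sd, na.rm = TRUE)
  zero <- !is.na(sd_) & sd_ == 0
  scl <- ifelse(zero, 1, sd_)
  z <- sweep(sweep(v, 2, mu, "-"), 2, scl, "/")
  out <- feature_matrix(z, fm$sample_metadata, unit = "log2")
  attr(out, "zero_sd") <- colnames(v)[zero]
  out
}

#' Signature activity score
#'
#' Per-sample activity of an up/down gene signature: the sum of Z-scores of
#' the up-regulated genes minus the sum of Z-scores of the down-regulated
#' genes. Used to score MYCN transcriptional activity per patient from a
#' knockdown-derived signature.
#'
#' @param z a Z-scored [feature_matrix()] (see [zscore_genes()]).
#' @param up_genes,down_genes disjoint character vectors; genes absent from
#'   the matrix are skipped (recorded in the `missing_genes` attribute).
#' @return named numeric vector of per-sample scores.
#' @export
activity_score <- function(z, up_genes, down_genes = character(0)) {
  stopifnot(inherits(z, "feature_matrix"))
  if (length(intersect(up_genes, down_genes)) > 0)
    stop("up and down gene lists overlap: ",
         paste(utils::head(intersect(up_genes, down_genes), 3), collapse = ", "))
  genes <- colnames(z$values)
  up <- intersect(up_genes, genes); down <- intersect(down_genes, genes)
  missing <- setdiff(c(up_genes, down_genes), genes)
  if (length(up) + length(down) == 0)
    stop("no signature genes present in the matrix")
  score_part <- function(g) {
    if (length(g) == 0) return(rep(0, nrow(z$values)))
    rowSums(z$values[, g, drop = FALSE], na.rm = TRUE)
  }
  score <- score_part(up) - score_part(down)
  names(score) <- rownames(z$values)
  attr(score, "missing_genes") <- missing
  score
}

#' Masked pairwise Pearson correlations
#'
#' Pairwise Pearson r with two-sided p-values ([stats::cor.test()]) among
#' selected genes plus optional extra per-sample variables (e.g. an
#' activity score). Entries with p >= `alpha` are masked (NA in `masked`);
#' zero-variance variables yield masked, flagged entries.
#'
#' @param fm a [feature_matrix()] with >= 3 samples.
#' @param targets gene (feature) names to correlate.
#' @param extra optional named list of per-sample numeric vectors.
#' @param alpha significance mask threshold (default 0.05).
#' @return list with matrices `r`, `p`, `masked` (r with non-significant
#'   entries NA) and character vector `degenerate` (zero-variance variables).
#' @export
masked_correlations <- function(fm, targets, extra = NULL, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 3) stop("masked_correlations needs at least 3 samples")
  missing <- setdiff(targets, colnames(fm$values))
  if (length(missing) > 0) stop("gene(s) not in matrix: ", missing[1])
  vars <- lapply(targets, function(g) fm$values[, g])
  names(vars) <- targets
  if (!is.null(extra)) vars <- c(vars, lapply(extra, as.numeric))
  k <- length(vars)
  nm <- names(vars)
  degenerate <- nm[vapply(vars, function(x) stats::sd(x, na.rm = TRUE) == 0, TRUE)]
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (nm[i] %in% degenerate || nm[j] %in% degenerate) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(vars[[i]], vars[[j]], method = "pearson")
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  masked <- r
  masked[is.na(p) | p >= alpha] <- NA_real_
  list(r = r, p = p, masked = masked, degenerate = degenerate)
}

#' Tertile stratification
#'
#' Splits samples into bottom / middle / top tertiles at the 1/3 and 2/3
#' empirical quantiles. A value equal to a boundary goes to the lower
#' stratum. If all values are equal every sample lands in `bottom` and the
#' result carries a `degenerate` flag.
#'
#' @param values named numeric vector, length >= 3.
#' @return factor with levels bottom/middle/top, named like `values`.
#' @export
tertile_stratify <- function(values) {
  if (length(values) < 3) stop("tertile_stratify needs at least 3 values")
  q <- stats::quantile(values, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  lab <- ifelse(values <= q[1], "bottom", ifelse(values <= q[2], "middle", "top"))
  out <- factor(lab, levels = c("bottom", "middle", "top"))
  names(out) <- names(values)
  if (q[1] == q[2] && all(values == values[1], na.rm = TRUE))
    attr(out, "degenerate") <- TRUE
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival curves per group ([survival::survfit()]) and the
#' two-group log-rank chi-square with 1 df ([survival::survdiff()]).
#'
#' @param surv data.frame with columns `time`, `event` and `group`.
#' @param groups the two group labels to compare.
#' @return list with `fit` (survfit object), `chisq`, `p`, `obs`, `exp`
#'   (per-group observed and expected event counts), `groups`.
#' @export
km_logrank <- function(surv, groups) {
  if (length(groups) != 2) stop("km_logrank compares exactly two groups")
  d <- surv[surv$group %in% groups, , drop = FALSE]
  present <- intersect(groups, unique(as.character(d$group)))
  if (length(present) < 2)
    stop("group absent from the table: ", setdiff(groups, present)[1])
  if (any(d$time <= 0)) stop("survival times must be positive")
  if (sum(d$event) == 0) stop("log-rank needs at least one event")
  d$group <- factor(as.character(d$group), levels = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (length(unique(d$group[d$event == 1])) == 0) stop("no events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chisq <- unname(sd_$chisq)
  list(
    fit = fit,
    chisq = chisq,
    p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    obs = sd_$obs, exp = sd_$exp,
    groups = groups
  )
}

#' Survival ranking of a gene set by tertile log-rank significance
#'
#' For each gene: stratify the cohort into expression tertiles, compare top
#' vs bottom with the log-rank test on each endpoint, and report
#' -log10(p). Direction class: `red` when the high-expression tertile fares
#' worse (observed > expected events) at p < `alpha`, `blue` when the
#' low-expression tertile fares worse, `gray` otherwise.
#'
#' @param fm expression [feature_matrix()].
#' @param survival_tables named list of data.frames (e.g. `OS`, `EFS`) with
#'   columns `subject_id`, `time`, `event`; subjects matched to matrix
#'   sample ids.
#' @param gene_set character vector of genes; absent genes are skipped
#'   (recorded in the `missing_genes` attribute).
#' @param alpha significance level for the color call (default 0.05).
#' @return data.frame with one row per gene x endpoint: `gene`, `endpoint`,
#'   `p`, `neg_log10_p`, `direction` in {red, blue, gray}.
#' @export
geneset_survival_ranking <- function(fm, survival_tables, gene_set, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  genes <- intersect(gene_set, colnames(fm$values))
  missing <- setdiff(gene_set, genes)
  rows <- list()
  for (g in genes) {
    tert <- tertile_stratify(stats::setNames(fm$values[, g], rownames(fm$values)))
    for (ep in names(survival_tables)) {
      st <- survival_tables[[ep]]
      idx <- match(st$subject_id, rownames(fm$values))
      d <- data.frame(time = st$time, event = st$event,
                      group = as.character(tert[idx]), stringsAsFactors = FALSE)
      d <- d[!is.na(d$group) & d$group %in% c("bottom", "top"), , drop = FALSE]
      res <- tryCatch(km_logrank(d, c("top", "bottom")), error = function(e) NULL)
      if (is.null(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, endpoint = ep, p = NA_real_, neg_log10_p = NA_real_,
          direction = "gray", stringsAsFactors = FALSE)
        next
      }
      # excess events in the top tertile => high expression is harmful
      top_excess <- res$obs[1] - res$exp[1]
      dir_ <- if (res$p < alpha) {
        if (top_excess > 0) "red" else "blue"
      } else "gray"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, endpoint = ep, p = res$p, neg_log10_p = -log10(res$p),
        direction = dir_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no genes from the set are present in the matrix")
  out <- out[order(-out$neg_log10_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_genes") <- missing
  out
}

#' Per-disease aggregation and ranking of CRISPR dependency scores
#'
#' Aggregates a gene's knockout dependency scores (gene-effect values; lower
#' means stronger dependency) per disease and orders diseases ascending, so
#' the most dependent disease ranks first.
#'
#' @param gene_effect data.frame with columns `cell_line`, `disease`, and
#'   one numeric column per gene.
#' @param gene gene column to rank.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @param disease optional disease label whose rank to report.
#' @return data.frame `disease`, `n_lines`, `score`, `rank` (ascending by
#'   score); when `disease` is given, attributes `disease_rank` and
#'   `disease_score` are set.
#' @export
dependency_rank <- function(gene_effect, gene, aggregate = c("mean", "median"),
                            disease = NULL) {
  aggregate <- match.arg(aggregate)
  if (!gene %in% colnames(gene_effect)) stop("gene absent from table: ", gene)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  sp <- split(gene_effect[[gene]], gene_effect$disease)
  out <- data.frame(
    disease = names(sp),
    n_lines = vapply(sp, length, 1L),
    score = vapply(sp, function(x) agg_fun(x, na.rm = TRUE), 1),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$score, out$disease), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(disease)) {
    i <- match(disease, out$disease)
    if (is.na(i)) stop("disease absent from table: ", disease)
    attr(out, "disease_rank") <- out$rank[i]
    attr(out, "disease_score") <- out$score[i]
  }
  out
}
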