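#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value, the test used to compare metabolite levels between
#' MYCN-amplified and non-amplified tumor groups. Wraps [stats::t.test()].
#'
#' @param a,b numeric vectors (missing values dropped); each needs at least
#'   two non-missing values.
#' @return list with elements `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t needs at least 2 non-missing values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate: zero variance in both groups; identical means => no evidence
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("welch_t: zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' One-way ANOVA F-test
#'
#' Classical between/within-group F with standard degrees of freedom, used
#' for the multi-level time-course comparisons. Wraps [stats::oneway.test()]
#' with equal variances (the textbook ANOVA).
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 non-missing values.
#' @return list with elements `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("one_way_anova needs at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("one_way_anova needs at least 2 non-missing values per group")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(y) == 0)
    return(list(F = 0, df1 = length(groups) - 1L,
                df2 = length(y) - length(groups), p = 1))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = ht$p.value)
}

#' Log2 fold change between two groups
#'
#' On the raw intensity scale, `log2(mean(a) / mean(b))`; on the log2 scale,
#' `mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors (missing values dropped), non-empty.
#' @param scale `"raw"` or `"log2"`.
#' @return numeric log2 fold change.
#' @export
log2_fold_change <- function(a, b, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("log2_fold_change: empty group")
  if (scale == "raw") {
    ma <- mean(a); mb <- mean(b)
    if (ma <= 0 || mb <= 0)
      stop("log2_fold_change: nonpositive group mean on the raw scale")
    log2(ma / mb)
  } else {
    mean(a) - mean(b)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment (via [stats::p.adjust()]), order-preserving.
#' NA p-values are propagated and do not enter the adjustment.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of adjusted p-values, same order and length as the input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Median / interquartile-range normalization for lipidomics
#'
#' log2-transforms raw intensities, then centers each feature by its median
#' and scales by its interquartile range across samples. Zero-IQR features
#' are centered only and flagged.
#'
#' @param fm a raw-unit [feature_matrix()] with positive intensities.
#' @return A log2-unit [feature_matrix()]; attribute `zero_iqr` lists the
#'   flagged feature ids.
#' @export
median_iqr_normalize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$unit != "raw") stop("median_iqr_normalize expects raw intensities")
  v <- fm$values
  if (any(v <= 0, na.rm = TRUE)) stop("nonpositive intensity in raw matrix")
  lv <- log2(v)
  med <- apply(lv, 2, stats::median, na.rm = TRUE)
  iqr <- apply(lv, 2, stats::IQR, na.rm = TRUE)
  zero <- iqr == 0
  scl <- ifelse(zero, 1, iqr)
  out <- sweep(sweep(lv, 2, med, "-"), 2, scl, "/")
  res <- feature_matrix(out, fm$sample_metadata, unit = "log2")
  attr(res, "zero_iqr") <- colnames(v)[zero]
  res
}

#' Per-feature differential statistics table
#'
#' Runs the chosen test per feature between labelled sample groups and
#' tabulates log2FC, raw p, BH FDR and a direction call. Features with
#' fewer than `min_n` non-missing values in any compared group are emitted
#' with missing statistics and excluded from the FDR adjustment.
#'
#' With `method = "anova"`, the p-value comes from the F-test across all
#' levels of the grouping column, while log2FC is still the named two-group
#' contrast (`comparison[1]` vs `comparison[2]`). With `method = "welch"` or
#' `"student"`, the two-group test uses only the contrast groups.
#'
#' Raw-unit matrices are log2-transformed before testing (the platform
#' convention for intensity data); log2FC follows the raw-scale ratio of
#' group means per [log2_fold_change()].
#'
#' @param fm a [feature_matrix()] whose `sample_metadata` holds `group_col`.
#' @param comparison character vector `c(test_group, reference_group)`.
#' @param method `"welch"`, `"student"` (equal-variance t) or `"anova"`.
#' @param alpha raw-p significance level for the direction call (default 0.05).
#' @param group_col name of the grouping column in the sample metadata.
#' @param min_n minimum non-missing values per compared group (default 2).
#' @return data.frame with columns `feature_id`, `log2FC`, `p`, `fdr`,
#'   `direction` in {up, down, null}, `n_used`; attribute `alpha` records
#'   the direction threshold.
#' @export
differential_table <- function(fm, comparison, method = c("welch", "student", "anova"),
                               alpha = 0.05, group_col = "group", min_n = 2) {
  method <- match.arg(method)
  stopifnot(inherits(fm, "feature_matrix"))
  if (!group_col %in% colnames(fm$sample_metadata))
    stop("sample metadata has no column '", group_col, "'")
  grp <- as.character(fm$sample_metadata[[group_col]])
  if (length(comparison) != 2) stop("`comparison` must name exactly two groups")
  unknown <- setdiff(comparison, unique(grp))
  if (length(unknown) > 0) stop("unknown group label: ", unknown[1])

  v <- fm$values
  test_v <- if (fm$unit == "raw") {
    if (any(v <= 0, na.rm = TRUE)) stop("nonpositive intensity in raw matrix")
    log2(v)
  } else v
  levels_all <- unique(grp)
  ia <- grp == comparison[1]
  ib <- grp == comparison[2]

  one_feature <- function(j) {
    xa <- v[ia, j]; xb <- v[ib, j]
    ta <- test_v[ia, j]; tb <- test_v[ib, j]
    if (method == "anova") {
      gl <- lapply(levels_all, function(l) test_v[grp == l, j])
      ns <- vapply(gl, function(g) sum(!is.na(g)), 1L)
      if (any(ns < min_n) || sum(!is.na(xa)) < 1 || sum(!is.na(xb)) < 1)
        return(c(NA_real_, NA_real_, NA_real_))
      p <- one_way_anova(gl)$p
    } else {
      na <- sum(!is.na(ta)); nb <- sum(!is.na(tb))
      if (na < min_n || nb < min_n) return(c(NA_real_, NA_real_, NA_real_))
      p <- if (method == "welch") {
        welch_t(ta, tb)$p
      } else {
        sa <- ta[!is.na(ta)]; sb <- tb[!is.na(tb)]
        if (stats::var(sa) == 0 && stats::var(sb) == 0) {
          if (mean(sa) == mean(sb)) 1 else 0
        } else stats::t.test(sa, sb, var.equal = TRUE)$p.value
      }
    }
    fc <- log2_fold_change(xa, xb, scale = fm$unit)
    c(fc, p, sum(!is.na(xa)) + sum(!is.na(xb)))
  }

  res <- vapply(seq_len(ncol(v)), one_feature, numeric(3))
  out <- data.frame(
    feature_id = colnames(v),
    log2FC = res[1, ],
    p = res[2, ],
    fdr = bh_adjust(res[2, ]),
    n_used = res[3, ],
    stringsAsFactors = FALSE
  )
  out$direction <- ifelse(
    is.na(out$p) | out$p > alpha, "null",
    ifelse(out$log2FC > 0, "up", ifelse(out$log2FC < 0, "down", "null"))
  )
  attr(out, "alpha") <- alpha
  out
}
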