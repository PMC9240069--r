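#' Subpathway differential-abundance (DA) score
#'
#' For each subpathway, the DA score is
#' `(# significantly increased - # significantly decreased) / # measured x 100`,
#' where significance is raw p <= `alpha` and the sign comes from log2FC.
#' A score of 100 (-100) means every measured metabolite in the subpathway
#' is significantly up (down). Subpathways are included when they contain at
#' least `min_altered` differentially altered metabolites
#' (`rule = "altered"`, the default) or at least `min_altered` measured
#' metabolites (`rule = "measured"`).
#'
#' Each score row also carries the hypergeometric over-representation p and
#' BH FDR across included subpathways, and a star flag at
#' `ora_fdr < star_threshold`.
#'
#' @param diff a [differential_table()] result.
#' @param annotation a [pathway_annotation()]; unannotated features are
#'   excluded (recorded in the `unannotated` attribute).
#' @param alpha raw-p significance threshold (default 0.05).
#' @param min_altered inclusion count for the chosen rule (default 3).
#' @param rule `"altered"` or `"measured"`.
#' @param star_threshold ORA FDR threshold for the star designation (default 0.25).
#' @return data.frame with columns `sub_pathway`, `n_measured`, `n_up`,
#'   `n_down`, `da_score`, `ora_p`, `ora_fdr`, `star`; attribute `excluded`
#'   lists subpathways failing the inclusion rule.
#' @export
differential_abundance_score <- function(diff, annotation, alpha = 0.05,
                                         min_altered = 3,
                                         rule = c("altered", "measured"),
                                         star_threshold = 0.25) {
  rule <- match.arg(rule)
  if (!inherits(annotation, "pathway_annotation") || nrow(annotation) == 0)
    stop("empty or invalid pathway annotation")
  idx <- match(diff$feature_id, annotation$feature_id)
  unannotated <- diff$feature_id[is.na(idx)]
  d <- diff[!is.na(idx), , drop = FALSE]
  d$sub_pathway <- annotation$sub_pathway[idx[!is.na(idx)]]
  d <- d[!is.na(d$p), , drop = FALSE]

  sig_up <- d$p <= alpha & d$log2FC > 0
  sig_down <- d$p <= alpha & d$log2FC < 0
  tab <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$sub_pathway), function(i) {
    data.frame(
      sub_pathway = d$sub_pathway[i[1]],
      n_measured = length(i),
      n_up = sum(sig_up[i]),
      n_down = sum(sig_down[i]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  tab$da_score <- (tab$n_up - tab$n_down) / tab$n_measured * 100

  keep <- if (rule == "altered") (tab$n_up + tab$n_down) >= min_altered
          else tab$n_measured >= min_altered
  excluded <- tab$sub_pathway[!keep]
  tab <- tab[keep, , drop = FALSE]

  # over-representation of significant metabolites within each subpathway
  N <- nrow(d); K <- sum(sig_up | sig_down)
  tab$ora_p <- vapply(seq_len(nrow(tab)), function(i) {
    hypergeom_upper_tail(k = tab$n_up[i] + tab$n_down[i], K = K,
                         n = tab$n_measured[i], N = N)
  }, 1)
  tab$ora_fdr <- bh_adjust(tab$ora_p)
  tab$star <- !is.na(tab$ora_fdr) & tab$ora_fdr < star_threshold
  tab <- tab[order(tab$sub_pathway), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "excluded") <- excluded
  attr(tab, "unannotated") <- unannotated
  attr(tab, "alpha") <- alpha
  tab
}

hypergeom_upper_tail <- function(k, K, n, N) {
  if (N <= 0) stop("empty universe")
  if (k <= 0) return(1)
  # P(X >= k) for X ~ Hypergeom(N, K, n)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests whether significant features (raw p <= `alpha` in `diff`) are
#' over-represented in each metabolite set: upper-tail hypergeometric
#' p = P(X >= k) with universe N = measured features, K = significant
#' features, n = set size within the universe, k = significant members.
#' P-values are BH-adjusted across sets. Set members outside the measured
#' universe are dropped (set size reduced) with a warning.
#'
#' @param diff a [differential_table()] result.
#' @param sets named list: set name -> member feature ids.
#' @param alpha raw-p significance threshold (default 0.05).
#' @return data.frame with columns `set`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @export
ora_hypergeometric <- function(diff, sets, alpha = 0.05) {
  d <- diff[!is.na(diff$p), , drop = FALSE]
  universe <- d$feature_id
  if (length(universe) == 0) stop("empty measured universe")
  sig <- d$feature_id[d$p <= alpha]
  N <- length(universe); K <- length(sig)
  rows <- lapply(names(sets), function(nm) {
    members <- unique(sets[[nm]])
    inside <- intersect(members, universe)
    if (length(inside) < length(members))
      warning(length(members) - length(inside), " member(s) of set '", nm,
              "' not in the measured universe; dropped")
    k <- length(intersect(inside, sig))
    data.frame(set = nm, k = k, K = K, n = length(inside), N = N,
               p = hypergeom_upper_tail(k, K, length(inside), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Rank subpathways across comparisons by star count
#'
#' Combines per-comparison DA score tables: the primary sort key is the
#' number of star designations (ORA FDR below threshold) across comparisons,
#' descending; ties break on the mean absolute DA score across the
#' comparisons where the subpathway was scored, descending; residual ties
#' break lexicographically by name. The subpathway universe is the outer
#' union; a missing score contributes no star and is excluded from the mean.
#'
#' @param score_tables named list of [differential_abundance_score()] tables,
#'   one per comparison.
#' @return data.frame with columns `sub_pathway`, `n_star`, `mean_abs_da`,
#'   `rank`, plus per-comparison `da_score.<name>` columns.
#' @export
rank_subpathways <- function(score_tables) {
  if (is.null(names(score_tables)) || any(!nzchar(names(score_tables))))
    names(score_tables) <- paste0("comparison", seq_along(score_tables))
  all_sp <- sort(unique(unlist(lapply(score_tables, `[[`, "sub_pathway"))))
  da <- sapply(score_tables, function(tab)
    tab$da_score[match(all_sp, tab$sub_pathway)])
  st <- sapply(score_tables, function(tab) {
    s <- tab$star[match(all_sp, tab$sub_pathway)]
    ifelse(is.na(s), FALSE, s)
  })
  da <- matrix(da, nrow = length(all_sp)); st <- matrix(st, nrow = length(all_sp))
  out <- data.frame(
    sub_pathway = all_sp,
    n_star = rowSums(st),
    mean_abs_da = rowMeans(abs(da), na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(score_tables))
    out[[paste0("da_score.", names(score_tables)[i])]] <- da[, i]
  ord <- order(-out$n_star, -out$mean_abs_da, out$sub_pathway)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Signal-to-noise ranking between two phenotypes
#'
#' The ranking metric is `(mu1 - mu2) / (s1 + s2)` per feature, with each
#' group standard deviation floored at `max(0.2 * |mu|, 1e-8)` (the usual
#' convention protecting low-variance features). Features are ordered by
#' descending metric; ties break by feature id.
#'
#' @param fm a [feature_matrix()].
#' @param phenotype character vector `c(group1, group2)` naming levels of
#'   `group_col`.
#' @param group_col grouping column in the sample metadata (default "group").
#' @return data.frame with columns `feature_id`, `metric`, ordered.
#' @export
signal_to_noise_ranking <- function(fm, phenotype, group_col = "group") {
  stopifnot(inherits(fm, "feature_matrix"))
  grp <- as.character(fm$sample_metadata[[group_col]])
  if (length(phenotype) != 2 || !all(phenotype %in% grp))
    stop("`phenotype` must name two groups present in the metadata")
  a <- fm$values[grp == phenotype[1], , drop = FALSE]
  b <- fm$values[grp == phenotype[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("signal-to-noise needs at least 2 samples per phenotype")
  s2n <- function(x) {
    mu <- colMeans(x, na.rm = TRUE)
    sd_ <- apply(x, 2, stats::sd, na.rm = TRUE)
    list(mu = mu, sd = pmax(sd_, 0.2 * abs(mu), 1e-8))
  }
  ga <- s2n(a); gb <- s2n(b)
  metric <- (ga$mu - gb$mu) / (ga$sd + gb$sd)
  out <- data.frame(feature_id = colnames(fm$values), metric = unname(metric),
                    stringsAsFactors = FALSE)
  out[order(-out$metric, out$feature_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Weighted running-sum enrichment score from hit positions in a ranked list.
# pos: ordered hit indices; w: |metric|^weight at those indices; N: list length.
# Hit increments are w / sum(w); miss decrements 1/(N - n). ES is the running
# sum's maximum deviation from zero.
es_from_positions <- function(pos, w, N) {
  n <- length(pos)
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else rep(1 / n, n)
  miss <- 1 / (N - n)
  cum_inc <- cumsum(inc)
  after_hit <- cum_inc - (pos - seq_len(n)) * miss          # value just after hit i
  before_hit <- c(0, cum_inc[-n]) - (pos - 1 - (seq_len(n) - 1)) * miss
  hi <- max(after_hit)
  lo <- min(before_hit)
  # maximum deviation from zero; near-exact ties resolve to the positive side
  if (hi >= -lo - 1e-12) hi else lo
}

#' GSEA-style set enrichment with a random-metabolite-set null
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment against a ranked
#' metabolite list. Unlike phenotype-permutation GSEA, the null distribution
#' is built from `n_perm` random same-size metabolite sets drawn from the
#' ranked universe — matching the randomized-set procedure used for
#' subpathway enrichment in this workflow. Sets overlapping the universe in
#' fewer than `min_set` members are skipped (recorded in the `skipped`
#' attribute).
#'
#' The empirical p-value is
#' `(1 + #{same-sign |ES_null| >= |ES|}) / (#same-sign nulls + 1)`, the
#' usual same-sign normalization (it keeps null p-values uniform and never
#' drops below `1 / (n_perm + 1)`); NES is ES divided
#' by the mean |null ES| of the same sign; FDR is BH across tested sets.
#'
#' @param ranked a [signal_to_noise_ranking()] result (or any data.frame
#'   with ordered `feature_id` and `metric` columns).
#' @param sets named list of member feature ids.
#' @param n_perm number of random null sets (default 10000).
#' @param weight metric exponent for hit increments (1 = weighted, 0 = classic).
#' @param min_set minimum set overlap with the universe (default 3).
#' @param seed integer seed for the null draws.
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `p_perm`,
#'   `fdr`, `n_perm`.
#' @export
gsea_enrichment <- function(ranked, sets, n_perm = 10000, weight = 1,
                            min_set = 3, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  universe <- ranked$feature_id
  N <- length(universe)
  wvec <- abs(ranked$metric)^weight

  sizes <- integer(0)
  rows <- list(); skipped <- character(0)
  for (nm in names(sets)) {
    hits <- which(universe %in% sets[[nm]])
    if (length(hits) < min_set || length(hits) >= N) {
      skipped <- c(skipped, nm)
      next
    }
    rows[[nm]] <- hits
    sizes <- c(sizes, length(hits))
  }
  if (length(rows) == 0) {
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_perm = numeric(0), fdr = numeric(0),
                      n_perm = integer(0))
    attr(out, "skipped") <- skipped
    return(out)
  }

  res <- withr::with_seed(seed, {
    # one shared null per set size, so equal-size sets reuse draws
    null_by_size <- new.env(parent = emptyenv())
    lapply(names(rows), function(nm) {
      hits <- rows[[nm]]
      n <- length(hits)
      es <- es_from_positions(hits, wvec[hits], N)
      key <- as.character(n)
      if (is.null(null_by_size[[key]])) {
        null_by_size[[key]] <- vapply(seq_len(n_perm), function(i) {
          p <- sample.int(N, n)
          es_from_positions(p, wvec[p], N)
        }, 1)
      }
      null_es <- null_by_size[[key]]
      same_sign <- null_es[sign(null_es) == sign(es) | es == 0]
      # empirical p against the same-sign side of the null, so that null
      # p-values stay uniform on (0, 1]
      p_perm <- (1 + sum(abs(same_sign) >= abs(es))) / (length(same_sign) + 1)
      denom <- mean(abs(same_sign))
      nes <- if (length(same_sign) > 0 && denom > 0) es / denom else NA_real_
      data.frame(set = nm, size = n, es = es, nes = nes, p_perm = p_perm,
                 n_perm = n_perm, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p_perm)
  out <- out[, c("set", "size", "es", "nes", "p_perm", "fdr", "n_perm")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Build the subpathway classification network
#'
#' A bipartite network with subpathways as source nodes and metabolites as
#' target nodes. Target node size is |log2FC| in the named comparison;
#' direction class is up/down when raw p <= `alpha` with the matching sign,
#' otherwise ns.
#'
#' @param diff a [differential_table()] for the comparison of interest.
#' @param annotation a [pathway_annotation()].
#' @param alpha significance threshold for the direction class (default 0.05).
#' @return a `classification_network`: list with `nodes` (id, type, size,
#'   direction_class) and `edges` (sub_pathway, feature_id).
#' @export
build_classification_network <- function(diff, annotation, alpha = 0.05) {
  if (!inherits(annotation, "pathway_annotation") || nrow(annotation) == 0)
    stop("empty or invalid pathway annotation")
  idx <- match(diff$feature_id, annotation$feature_id)
  d <- diff[!is.na(idx), , drop = FALSE]
  d$sub_pathway <- annotation$sub_pathway[idx[!is.na(idx)]]
  dir_class <- ifelse(
    is.na(d$p) | d$p > alpha, "ns",
    ifelse(d$log2FC > 0, "up", ifelse(d$log2FC < 0, "down", "ns"))
  )
  met_nodes <- data.frame(
    id = d$feature_id, type = "metabolite",
    size = abs(d$log2FC), direction_class = dir_class,
    stringsAsFactors = FALSE
  )
  sp <- unique(d$sub_pathway)
  sp_nodes <- data.frame(id = sp, type = "subpathway", size = NA_real_,
                         direction_class = NA_character_, stringsAsFactors = FALSE)
  structure(
    list(
      nodes = rbind(sp_nodes, met_nodes),
      edges = data.frame(sub_pathway = d$sub_pathway, feature_id = d$feature_id,
                         stringsAsFactors = FALSE)
    ),
    class = "classification_network"
  )
}

#' @export
print.classification_network <- function(x, ...) {
  cat(sprintf("classification_network: %d subpathways, %d metabolites, %d edges\n",
              sum(x$nodes$type == "subpathway"),
              sum(x$nodes$type == "metabolite"),
              nrow(x$edges)))
  invisible(x)
}
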