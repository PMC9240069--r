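#' Inhibition from viability
#'
#' `inhibition% = 100% - viability%`, clipped to `[0, 100]`. Clipping (from
#' viabilities above 100% of control) is flagged, never silent.
#'
#' @param viability percent of untreated control, >= 0 (vectorized).
#' @return inhibition percent in `[0, 100]`; attribute `clipped` marks
#'   clipped entries when any occurred.
#' @export
inhibition_from_viability <- function(viability) {
  if (any(viability < 0, na.rm = TRUE)) stop("viability must be non-negative")
  raw <- 100 - viability
  out <- pmin(pmax(raw, 0), 100)
  clipped <- raw != out & !is.na(raw)
  if (any(clipped)) attr(out, "clipped") <- clipped
  out
}

#' Bliss synergy score for a two-drug dose grid
#'
#' Converts viabilities to inhibition fractions, averages replicates per
#' dose cell, and compares each combination cell with the Bliss
#' independence expectation `e = iA + iB - iA*iB` computed from the
#' matching single-agent cells. The per-cell excess is
#' `(observed - expected) * 100` percentage points; the summary score is
#' the mean excess over combination cells. Calls follow the strict
#' thresholds: synergy when the mean score > 10, antagonism when < -10,
#' additive otherwise.
#'
#' @param grid data.frame in long format with columns `dose_a`, `dose_b`,
#'   `replicate`, `viability` (percent of control); must contain the
#'   single-agent margins (dose 0 rows/columns) for every combination cell.
#' @param replicate_handling `"average_viability"` (default: average
#'   replicate viabilities per cell, then score) or `"average_scores"`
#'   (score each replicate's complete grid, then average the scores).
#' @return list with `cells` (per-combination-cell data.frame: doses,
#'   observed, expected, excess), `score`, `call`.
#' @export
bliss_synergy <- function(grid, replicate_handling = c("average_viability", "average_scores")) {
  replicate_handling <- match.arg(replicate_handling)
  req <- c("dose_a", "dose_b", "viability")
  if (!all(req %in% colnames(grid)))
    stop("grid needs columns dose_a, dose_b, viability (long format)")
  if (!"replicate" %in% colnames(grid)) grid$replicate <- 1L

  score_one <- function(g) {
    # mean viability per cell -> inhibition fraction
    key <- interaction(g$dose_a, g$dose_b, drop = TRUE)
    cells <- do.call(rbind, lapply(split(g, key), function(cc) {
      data.frame(dose_a = cc$dose_a[1], dose_b = cc$dose_b[1],
                 viability = mean(cc$viability))
    }))
    cells$inhibition <- as.numeric(inhibition_from_viability(cells$viability)) / 100
    single_a <- cells[cells$dose_b == 0 & cells$dose_a > 0, ]
    single_b <- cells[cells$dose_a == 0 & cells$dose_b > 0, ]
    combo <- cells[cells$dose_a > 0 & cells$dose_b > 0, , drop = FALSE]
    if (nrow(combo) == 0) stop("grid has no combination cells")
    ia <- single_a$inhibition[match(combo$dose_a, single_a$dose_a)]
    ib <- single_b$inhibition[match(combo$dose_b, single_b$dose_b)]
    bad <- which(is.na(ia) | is.na(ib))
    if (length(bad) > 0)
      stop(sprintf("missing single-agent margin for cell (dose_a=%g, dose_b=%g)",
                   combo$dose_a[bad[1]], combo$dose_b[bad[1]]))
    combo$expected <- ia + ib - ia * ib
    combo$excess <- (combo$inhibition - combo$expected) * 100
    rownames(combo) <- NULL
    combo
  }

  if (replicate_handling == "average_viability") {
    cells <- score_one(grid)
    score <- mean(cells$excess)
  } else {
    reps <- split(grid, grid$replicate)
    per_rep <- lapply(reps, score_one)
    score <- mean(vapply(per_rep, function(cc) mean(cc$excess), 1))
    cells <- per_rep[[1]]
    cells$excess <- rowMeans(vapply(per_rep, `[[`, numeric(nrow(cells)), "excess"))
    cells$inhibition <- rowMeans(vapply(per_rep, `[[`, numeric(nrow(cells)), "inhibition"))
    cells$expected <- rowMeans(vapply(per_rep, `[[`, numeric(nrow(cells)), "expected"))
  }
  # strict thresholds, with a guard so a score numerically at the boundary
  # (e.g. 10 up to rounding) is not promoted by floating-point error
  call <- if (score - 10 > 1e-9) "synergy" else if (score + 10 < -1e-9) "antagonism" else "additive"
  list(cells = cells, score = score, call = call)
}

#' Corrected total cell fluorescence (CTCF)
#'
#' `CTCF = integrated density - area x mean background fluorescence`, the
#' ImageJ quantification of per-cell fluorescence. A negative CTCF is
#' returned with a flag.
#'
#' @param integrated_density,area,background_mean non-negative numerics.
#' @return CTCF in the input's arbitrary units; attribute `negative` when
#'   below zero.
#' @export
ctcf <- function(integrated_density, area, background_mean) {
  if (any(c(integrated_density, area, background_mean) < 0))
    stop("ctcf inputs must be non-negative")
  val <- integrated_density - area * background_mean
  if (any(val < 0)) attr(val, "negative") <- val < 0
  val
}

#' ChIP-qPCR fold enrichment (2^-ddCt)
#'
#' Per region: `dCt = Ct(IP) - Ct(input)`; `ddCt = dCt(region) -
#' dCt(negative control region)`; `fold = 2^-ddCt`. The negative-control
#' region's fold is 1 by construction.
#'
#' @param ct data.frame with columns `region`, `ct_ip`, `ct_input`.
#' @param negative_control_region region label used as the reference.
#' @return data.frame `region`, `dct`, `ddct`, `fold`.
#' @export
chip_fold_enrichment <- function(ct, negative_control_region) {
  req <- c("region", "ct_ip", "ct_input")
  if (!all(req %in% colnames(ct)))
    stop("ct table needs columns region, ct_ip, ct_input")
  if (!negative_control_region %in% ct$region)
    stop("negative control region missing: ", negative_control_region)
  dct <- ct$ct_ip - ct$ct_input
  ref <- dct[match(negative_control_region, ct$region)]
  ddct <- dct - ref
  data.frame(region = ct$region, dct = dct, ddct = ddct, fold = 2^(-ddct),
             stringsAsFactors = FALSE)
}
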