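#' Samples-by-features intensity matrix
#'
#' The shared container for metabolomics, lipidomics and expression data:
#' a numeric samples x features matrix plus per-sample metadata (group,
#' time point, condition) and a unit flag recording whether values are raw
#' intensities or log2-transformed.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_metadata data.frame with one row per sample (may be empty);
#'   typically contains a `group` column.
#' @param unit `"raw"` or `"log2"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, sample_metadata = NULL, unit = c("raw", "log2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (is.null(rownames(values))) stop("`values` must have sample ids as rownames")
  if (is.null(colnames(values))) stop("`values` must have feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature id: ", colnames(values)[duplicated(colnames(values))][1])
  if (is.null(sample_metadata))
    sample_metadata <- data.frame(row.names = rownames(values))
  if (nrow(sample_metadata) != nrow(values))
    stop("`sample_metadata` must have one row per sample")
  rownames(sample_metadata) <- rownames(values)
  structure(
    list(values = values, sample_metadata = sample_metadata, unit = unit),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d samples x %d features (unit: %s)\n",
    nrow(x$values), ncol(x$values), x$unit
  ))
  if (ncol(x$sample_metadata) > 0)
    cat("sample metadata:", paste(colnames(x$sample_metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

sample_ids <- function(fm) rownames(fm$values)
feature_ids <- function(fm) colnames(fm$values)

#' Feature-to-pathway annotation
#'
#' Maps each feature to a two-level classification: a super-pathway (e.g.
#' "Lipid") and a subpathway (e.g. "Diacylglycerol"). Each feature is
#' annotated at most once.
#'
#' @param feature_id,super_pathway,sub_pathway character vectors of equal length.
#' @return A `pathway_annotation` data.frame.
#' @export
pathway_annotation <- function(feature_id, super_pathway, sub_pathway) {
  if (length(feature_id) == 0) stop("empty annotation")
  if (anyDuplicated(feature_id))
    stop("feature annotated more than once: ", feature_id[duplicated(feature_id)][1])
  if (any(!nzchar(super_pathway)) || any(!nzchar(sub_pathway)))
    stop("pathway labels must be non-empty")
  ann <- data.frame(
    feature_id = as.character(feature_id),
    super_pathway = as.character(super_pathway),
    sub_pathway = as.character(sub_pathway),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("pathway_annotation", "data.frame")
  ann
}

#' Convert a pathway annotation to a named set collection
#'
#' Groups features by subpathway, yielding the metabolite-set collection
#' used by over-representation and set-enrichment analysis.
#'
#' @param annotation a [pathway_annotation()].
#' @return Named list: subpathway -> character vector of feature ids.
#' @export
annotation_to_sets <- function(annotation) {
  sets <- split(annotation$feature_id, annotation$sub_pathway)
  lapply(sets, unique)
}
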