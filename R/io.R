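#' Read a delimited samples-by-features table
#'
#' Reads a TSV/CSV intensity table into a [feature_matrix()]. The file must
#' carry one header row and one leading identifier column. Orientation is
#' never guessed: state explicitly whether rows are samples or features.
#' Non-numeric cells (including "NA" and empty cells) become missing values.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` -> comma, anything else -> tab) unless `sep` is given.
#' @param orientation `"samples_rows"` (default) or `"features_rows"`.
#' @param unit `"raw"` or `"log2"` unit flag to record.
#' @param sep optional delimiter override.
#' @return A [feature_matrix()] (without sample metadata).
#' @export
read_feature_matrix <- function(path, orientation = c("samples_rows", "features_rows"),
                                unit = c("raw", "log2"), sep = NULL) {
  orientation <- match.arg(orientation)
  unit <- match.arg(unit)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("table must have a header and at least one data row: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(vapply(fields, length, 1L) != width)
  if (length(ragged) > 0)
    stop("ragged row ", ragged[1], " in ", path, ": expected ", width, " fields")
  header <- fields[[1]][-1]
  row_ids <- vapply(fields[-1], `[[`, "", 1L)
  if (anyDuplicated(row_ids)) stop("duplicate row id: ", row_ids[duplicated(row_ids)][1])
  if (anyDuplicated(header)) stop("duplicate column id: ", header[duplicated(header)][1])
  vals <- vapply(fields[-1], function(f) suppressWarnings(as.numeric(f[-1])),
                 numeric(width - 1L))
  m <- if (width == 2L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(m) <- list(row_ids, header)
  if (orientation == "features_rows") m <- t(m)
  feature_matrix(m, unit = unit)
}

#' Write a feature matrix as a delimited table
#'
#' @param fm a [feature_matrix()].
#' @param path output path; delimiter from extension as in [read_feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- fm$values
  header <- paste(c("sample_id", colnames(m)), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], ifelse(is.na(m[i, ]), "NA", format(m[i, ], digits = 15, trim = TRUE))),
          collapse = sep)
  }, "")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read metabolite sets in GMT format
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a line are dropped.
#'
#' @param path GMT file path.
#' @return Named list: set name -> character vector of member feature ids.
#' @export
read_metabolite_sets_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), names = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  empty <- !vapply(sets, length, 1L) > 0
  if (any(empty)) stop("GMT set with no members: ", names(sets)[empty][1])
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1])
  sets
}

#' Write metabolite sets in GMT format
#'
#' @param sets named list of member vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_metabolite_sets_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a subpathway classification network
#'
#' Exports the bipartite subpathway -> metabolite network built by
#' [build_classification_network()]. SIF rows are
#' `subpathway contains metabolite`; GraphML (via igraph) carries the node
#' attributes `size` (|log2FC|) and `direction_class`.
#'
#' @param network a `classification_network`.
#' @param path output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @export
write_network <- function(network, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (!inherits(network, "classification_network"))
    stop("`network` must come from build_classification_network()")
  if (format == "SIF") {
    if (nrow(network$edges) == 0) {
      writeLines(character(0), path)
    } else {
      writeLines(paste(network$edges$sub_pathway, "contains", network$edges$feature_id),
                 path, useBytes = TRUE)
    }
    return(invisible(path))
  }
  g <- classification_network_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

classification_network_igraph <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    edges[, c("sub_pathway", "feature_id")],
    directed = TRUE,
    vertices = data.frame(
      name = nodes$id,
      type = nodes$type,
      # GraphML attributes cannot carry NA: source nodes export as size 0
      # with an empty direction class
      size = ifelse(is.na(nodes$size), 0, nodes$size),
      direction_class = ifelse(is.na(nodes$direction_class), "",
                               nodes$direction_class),
      stringsAsFactors = FALSE
    )
  )
  g
}

#' Read a survival table
#'
#' Expects a delimited table with columns `subject_id`, `time`, `event`
#' and optionally `endpoint` (OS/EFS). Validates `time > 0` and
#' `event` in {0, 1}.
#'
#' @param path file path (TSV/CSV by extension).
#' @return data.frame with validated survival columns.
#' @export
read_survival_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_survival_table(df)
}

#' Directory for manually downloaded external datasets
#'
#' The package does not download public datasets (expression cohorts,
#' CRISPR screens, supplementary study tables). Analyses that need them
#' look for manually placed TSV files in this per-user data directory;
#' the expected file names and layouts are described in the methods
#' vignette. The directory is not created automatically.
#'
#' @return path of the external-data directory.
#' @export
external_data_dir <- function() {
  tools::R_user_dir("nbmet", which = "data")
}

validate_survival_table <- function(df) {
  req <- c("subject_id", "time", "event")
  miss <- setdiff(req, colnames(df))
  if (length(miss) > 0) stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$time)) || any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  df
}
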