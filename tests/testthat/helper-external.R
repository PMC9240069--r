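# External public datasets (study supplementary tables, expression cohorts,
# the CRISPR gene-effect release) are not bundled and are never downloaded
# by the package. When present, they are read from external_data_dir() with
# the file layouts described in the methods vignette.

external_file <- function(name) file.path(external_data_dir(), name)

require_external <- function(names) {
  paths <- vapply(names, external_file, "")
  missing <- names[!file.exists(paths)]
  if (length(missing) > 0) {
    fail(paste0(
      "external dataset not available: ", paste(missing, collapse = ", "),
      " (expected under ", external_data_dir(),
      "; see the methods vignette for the manual download layout)"))
    return(NULL)
  }
  as.list(paths)
}

# Differential table for one comparison of an externally supplied
# metabolomics dataset, then the diacylglycerol DA score.
dg_da_score <- function(matrix_file, groups_file, annotation_file,
                        comparison, method) {
  fm <- read_feature_matrix(external_file(matrix_file))
  grp <- utils::read.table(external_file(groups_file), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  fm$sample_metadata$group <- grp$group[match(rownames(fm$values), grp$sample_id)]
  ann_df <- utils::read.table(external_file(annotation_file), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  ann <- pathway_annotation(ann_df$feature_id, ann_df$super_pathway,
                            ann_df$sub_pathway)
  dt <- differential_table(fm, comparison, method = method)
  da <- differential_abundance_score(dt, ann)
  da$da_score[grepl("diacylglycerol", tolower(da$sub_pathway))][1]
}
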