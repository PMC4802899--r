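#' Omics abundance matrix with sample metadata
#'
#' The common container for metabolite concentrations and normalized
#' transcript abundances: a features x samples matrix of strictly positive
#' values plus per-sample metadata (irrigation treatment `C`/`D`,
#' developmental stage in days after anthesis, replicate index).
#'
#' @param values numeric matrix, features in rows, samples in columns; all
#'   values finite and > 0; row and column names must be unique.
#' @param metadata data.frame with columns `sample_id`, `treatment`
#'   (`"C"` or `"D"`), `stage_daa` (integer), `replicate` (integer), one row
#'   per column of `values`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (!all(is.finite(values)) || any(values <= 0))
    stop("all abundances must be finite and strictly positive")
  req <- c("sample_id", "treatment", "stage_daa", "replicate")
  if (!is.data.frame(metadata) || !all(req %in% names(metadata)))
    stop("`metadata` must contain columns: ", paste(req, collapse = ", "))
  if (!setequal(metadata$sample_id, colnames(values)) ||
      nrow(metadata) != ncol(values))
    stop("metadata must cover every sample exactly once")
  if (!all(metadata$treatment %in% c("C", "D")))
    stop("treatment must be 'C' or 'D'")
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "omics_matrix: %d features x %d samples (%d treatments, %d stages, %d replicates)\n",
    nrow(x$values), ncol(x$values), length(unique(md$treatment)),
    length(unique(md$stage_daa)), max(md$replicate)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Subset an omics matrix to the samples of one condition
#' @keywords internal
condition_samples <- function(x, condition) {
  if (!condition %in% x$metadata$treatment)
    stop(sprintf("condition '%s' not present in sample metadata", condition))
  keep <- x$metadata$treatment == condition
  x$values[, x$metadata$sample_id[keep], drop = FALSE]
}

#' Write / read an omics matrix as TSV
#'
#' The matrix is written as a TSV with a `feature_id` first column and sample
#' IDs in the header; metadata as a second TSV (`sample_id`, `treatment`,
#' `stage_daa`, `replicate`). `read_omics_tsv()` round-trips these files.
#'
#' @param x an `omics_matrix`.
#' @param values_path,metadata_path output/input TSV paths.
#' @return `write_omics_tsv()` the paths, invisibly; `read_omics_tsv()` an
#'   `omics_matrix`.
#' @export
write_omics_tsv <- function(x, values_path, metadata_path) {
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values_path, metadata_path))
}

#' @rdname write_omics_tsv
#' @export
read_omics_tsv <- function(values_path, metadata_path) {
  df <- utils::read.table(values_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$feature_id
  metadata <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                                check.names = FALSE, stringsAsFactors = FALSE)
  omics_matrix(values, metadata)
}
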