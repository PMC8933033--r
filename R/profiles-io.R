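# Reading, writing and joining the three table kinds the pipeline consumes.
# All files are plain TSV, UTF-8, '.' decimal: first column sample ids, header
# row feature ids.

read_tsv_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path))
    hrt_stop("hrt_parse_error", "file not found: ", path)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    hrt_stop("hrt_parse_error", "expected sample-id column plus at least one feature column in ", path)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1))
  if (any(non_num))
    hrt_stop("hrt_parse_error", "non-numeric cell(s) in column(s): ",
             paste(names(body)[non_num], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

#' Load a species-level relative-abundance table from TSV
#'
#' Expects samples in rows (first column sample ids) and taxa in columns.
#' Tables written in percentages are detected (any value > 1.5 when
#' `percent = NULL`) and rescaled to fractions; set `percent = TRUE/FALSE` to
#' override the autodetection.
#'
#' @param path TSV file path.
#' @param delimiter field separator, default tab.
#' @param percent `NULL` (autodetect), `TRUE` (values are percentages) or
#'   `FALSE` (values are fractions).
#' @return [abundance_table()].
#' @export
load_abundance_table <- function(path, delimiter = "\t", percent = NULL) {
  m <- read_tsv_matrix(path, delimiter)
  if (anyNA(m))
    hrt_stop("hrt_validation_error", "missing values in abundance table ", path)
  if (is.null(percent)) percent <- any(m > 1.5)
  if (percent) m <- m / 100
  abundance_table(m)
}

#' Write an abundance table as TSV (fractions)
#' @param table an [abundance_table()].
#' @param path output file.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load per-sample metadata from TSV
#'
#' Required columns: `sample_id`, `bioproject`, `sampling_method`; optional:
#' `country`, `health_status` (missing entries become `"unknown"`). The
#' anatomical `compartment` is derived from `sampling_method` via
#' [compartment_of()].
#'
#' @param path TSV file path.
#' @return [sample_metadata()] data.frame.
#' @export
load_metadata <- function(path) {
  if (!file.exists(path))
    hrt_stop("hrt_parse_error", "file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Write metadata as TSV
#' @param meta a [sample_metadata()] table.
#' @param path output file.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load an EC-number or pathway table from TSV
#' @param path TSV file path.
#' @return [ec_table()].
#' @export
load_ec_table <- function(path) {
  m <- read_tsv_matrix(path)
  ec_table(m)
}

#' @rdname load_ec_table
#' @export
load_pathway_table <- function(path) {
  m <- read_tsv_matrix(path)
  pathway_table(m)
}

#' Write an EC or pathway table as TSV
#' @param table an [ec_table()] or [pathway_table()].
#' @param path output file.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an abundance table with its metadata
#'
#' Restricts both objects to their common samples (identical ordering in both
#' outputs) and removes samples whose compartment falls in `drop_groups`; by
#' default biopsy/undefined-swab samples (`compartment == "other"`) are
#' excluded, mirroring standard practice of dropping low-yield biopsy data.
#' Samples present in only one of the two inputs are dropped with a warning.
#'
#' @param table an [abundance_table()].
#' @param meta a [sample_metadata()] table.
#' @param drop_groups character vector of compartments to exclude.
#' @return list with elements `table` and `meta`, aligned.
#' @export
align_dataset <- function(table, meta, drop_groups = "other") {
  common <- intersect(rownames(table), meta$sample_id)
  if (length(common) == 0)
    hrt_stop("hrt_empty_dataset_error",
             "no samples are shared between abundance table and metadata")
  lost <- setdiff(union(rownames(table), meta$sample_id), common)
  if (length(lost))
    hrt_warn(length(lost), " sample(s) present in only one input were dropped: ",
             paste(utils::head(lost, 5), collapse = ", "),
             if (length(lost) > 5) ", ..." else "")
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  keep <- !(meta$compartment %in% drop_groups)
  if (!any(keep))
    hrt_stop("hrt_empty_dataset_error", "all samples fall in drop_groups")
  ids <- common[keep]
  out_meta <- meta[keep, , drop = FALSE]
  class(out_meta) <- c("sample_metadata", "data.frame")
  list(table = abundance_table(unclass(table)[ids, , drop = FALSE],
                               attr(table, "species_resolved")),
       meta = out_meta)
}
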