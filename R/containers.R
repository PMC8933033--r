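#' Species-level relative-abundance table
#'
#' The central container of the package: a samples x taxa matrix of relative
#' abundances expressed as fractions of classified reads. Rows may sum to less
#' than 1 (the residual is reads not classified at species level) but never to
#' more than 1. Taxa whose name does not resolve to a defined species (e.g.
#' `"Pasteurella sp."` or names containing `"unclassified"`) are flagged so the
#' CST caller can mark clusters they define as putative.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   taxa in columns (colnames = species names).
#' @param species_resolved optional logical vector, one per taxon; defaults to
#'   pattern-based detection via [is_species_resolved()].
#' @return An object of class `abundance_table`: the validated matrix with a
#'   `species_resolved` attribute.
#' @export
#' @examples
#' m <- matrix(c(0.6, 0.2, 0.1, 0.4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("Rothia mucilaginosa", "Neisseria sp.")))
#' at <- abundance_table(m)
#' attr(at, "species_resolved")
abundance_table <- function(values, species_resolved = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    hrt_stop("hrt_parse_error", "abundance values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    hrt_stop("hrt_identifier_error", "abundance matrix needs sample rownames and taxon colnames")
  if (anyDuplicated(rownames(values)))
    hrt_stop("hrt_identifier_error", "duplicated sample ids: ",
             paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    hrt_stop("hrt_identifier_error", "duplicated taxon ids: ",
             paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    hrt_stop("hrt_validation_error", "missing values are not allowed in abundance tables")
  if (any(values < 0))
    hrt_stop("hrt_validation_error", "negative abundance values found")
  rs <- rowSums(values)
  if (any(rs > 1 + 1e-9))
    hrt_stop("hrt_validation_error", "sample rows must sum to <= 1 (fractions); worst offender ",
             rownames(values)[which.max(rs)], " sums to ", format(max(rs)))
  if (is.null(species_resolved)) {
    species_resolved <- is_species_resolved(colnames(values))
  } else {
    stopifnot(length(species_resolved) == ncol(values))
  }
  names(species_resolved) <- colnames(values)
  structure(values, species_resolved = species_resolved,
            class = c("abundance_table", class(values)))
}

#' Is a taxon name resolved at species level?
#'
#' A name is unresolved when it contains the `" sp."` placeholder or the token
#' `"unclassified"` (case-insensitive).
#' @param taxa character vector of taxon names.
#' @return logical vector.
#' @export
is_species_resolved <- function(taxa) {
  !(grepl(" sp\\.", taxa, ignore.case = TRUE) |
      grepl("\\bunclassified\\b", taxa, ignore.case = TRUE))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%d unresolved at species level)\n",
              nrow(x), ncol(x), sum(!attr(x, "species_resolved"))))
  cat(sprintf("  row sums in [%.3f, %.3f]\n", min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

# Vocabulary shared by metadata loading/derivation ---------------------------

SAMPLING_METHODS <- c("nasal_lavage", "nasopharynx_swab", "sputum", "cough_swab",
                      "oropharynx_swab", "lung_lavage", "biopsy", "undefined_swab")

COMPARTMENTS <- c("nasal", "throat", "sputum", "lung", "other")

HEALTH_STATUSES <- c("healthy", "diseased", "unknown")

#' Map a sampling method to its anatomical compartment
#'
#' Fixed mapping: nasal lavage and nasopharynx swab sample the nasal cavity;
#' oropharynx and cough swabs sample the throat; sputum stays its own
#' compartment (an oral/lower-tract surrogate rather than a site); lung lavage
#' samples the lung; biopsies and undefined swabs fall into `other` and are
#' dropped by default downstream.
#'
#' @param sampling_method character vector of tokens from [SAMPLING_METHODS].
#' @return character vector of compartments.
#' @export
compartment_of <- function(sampling_method) {
  bad <- setdiff(unique(sampling_method), SAMPLING_METHODS)
  if (length(bad))
    hrt_stop("hrt_vocabulary_error", "unknown sampling_method token(s): ",
             paste(bad, collapse = ", "), "; accepted: ",
             paste(SAMPLING_METHODS, collapse = ", "))
  map <- c(nasal_lavage = "nasal", nasopharynx_swab = "nasal",
           oropharynx_swab = "throat", cough_swab = "throat",
           sputum = "sputum", lung_lavage = "lung",
           biopsy = "other", undefined_swab = "other")
  unname(map[sampling_method])
}

#' Per-sample metadata table
#'
#' @param df data.frame with columns `sample_id`, `bioproject`,
#'   `sampling_method` and optionally `country`, `health_status`. The
#'   `compartment` column is always (re)derived from `sampling_method`.
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "bioproject", "sampling_method")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    hrt_stop("hrt_parse_error", "metadata is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    hrt_stop("hrt_identifier_error", "duplicated sample ids in metadata: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$bioproject <- as.character(df$bioproject)
  df$sampling_method <- as.character(df$sampling_method)
  if (is.null(df$country)) df$country <- NA_character_
  df$compartment <- compartment_of(df$sampling_method)
  hs <- as.character(df$health_status %||% rep(NA_character_, nrow(df)))
  hs[is.na(hs) | hs == ""] <- "unknown"
  bad <- setdiff(unique(hs), HEALTH_STATUSES)
  if (length(bad))
    hrt_stop("hrt_vocabulary_error", "unknown health_status token(s): ",
             paste(bad, collapse = ", "), "; accepted: ",
             paste(HEALTH_STATUSES, collapse = ", "))
  df$health_status <- hs
  df <- df[, c("sample_id", "bioproject", "country", "sampling_method",
               "compartment", "health_status")]
  rownames(df) <- df$sample_id
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Samples x EC-number relative-abundance table
#'
#' @param values numeric matrix, samples in rows, EC numbers (e.g. "1.1.1.27",
#'   partial forms like "2.4" allowed) in columns.
#' @return matrix of class `ec_table`.
#' @export
ec_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    hrt_stop("hrt_parse_error", "EC values must be a numeric matrix")
  ecs <- colnames(values)
  ok <- grepl("^[0-9]+(\\.[0-9]+){0,3}$", ecs)
  if (!all(ok))
    hrt_stop("hrt_parse_error", "malformed EC number(s): ",
             paste(ecs[!ok], collapse = ", "))
  if (any(values < 0) || anyNA(values))
    hrt_stop("hrt_validation_error", "EC abundances must be non-negative and complete")
  if (any(rowSums(values) > 1 + 1e-9))
    hrt_stop("hrt_validation_error", "EC rows must sum to <= 1")
  structure(values, class = c("ec_table", class(values)))
}

#' Samples x pathway relative-abundance table
#' @param values numeric matrix, samples in rows, pathway ids in columns.
#' @return matrix of class `pathway_table`.
#' @export
pathway_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    hrt_stop("hrt_parse_error", "pathway values must be a numeric matrix")
  if (any(values < 0) || anyNA(values))
    hrt_stop("hrt_validation_error", "pathway abundances must be non-negative and complete")
  structure(values, class = c("pathway_table", class(values)))
}
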