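# Community State Type (CST) calling: Pearson-correlation distance,
# average-linkage (UPGMA) hierarchical clustering, silhouette-guided choice of
# the cluster number, retention filters and core-taxon characterization.

validate_distance_matrix <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    hrt_stop("hrt_validation_error", "distance matrix must be square")
  if (max(abs(dist - t(dist))) > 1e-12)
    hrt_stop("hrt_validation_error", "distance matrix must be symmetric")
  if (any(diag(dist) != 0))
    hrt_stop("hrt_validation_error", "distance matrix must have a zero diagonal")
  if (any(dist < 0))
    hrt_stop("hrt_validation_error", "distances must be non-negative")
  invisible(dist)
}

#' Pearson-correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of the two
#' samples' species-abundance vectors, so `d` lies in `[0, 2]`: identical or
#' proportionally scaled profiles are at distance 0, anticorrelated profiles
#' approach 2. This is the distance the CST clustering runs on.
#'
#' @param table an [abundance_table()] (or plain samples x taxa matrix).
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
pearson_distance <- function(table) {
  x <- unclass(table)
  if (nrow(x) < 2)
    hrt_stop("hrt_size_error", "need at least 2 samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    hrt_stop("hrt_degenerate_sample_error",
             "zero-variance sample(s) have no defined correlation: ",
             paste(rownames(x)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(t(x))
  d[d < 0] <- 0            # guard rounding: r can exceed 1 by ~1e-16
  diag(d) <- 0
  d <- (d + t(d)) / 2
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerates with average linkage (UPGMA) by default: the distance between
#' two clusters is the unweighted mean of all pairwise leaf distances, which
#' guarantees monotone merge heights. `"complete"` and `"ward"`
#' (Ward-on-distances, `hclust`'s `ward.D`) are exposed as alternatives.
#'
#' @param dist symmetric distance matrix with sample-id dimnames.
#' @param method linkage flavor.
#' @return object of class `hrt_dendrogram` wrapping the merge table: fields
#'   `merge`, `height`, `labels` (as in [stats::hclust()]).
#' @export
upgma_linkage <- function(dist, method = c("average", "complete", "ward")) {
  method <- match.arg(method)
  validate_distance_matrix(dist)
  if (nrow(dist) < 2)
    hrt_stop("hrt_size_error", "need at least 2 samples to build a dendrogram")
  hc <- stats::hclust(stats::as.dist(dist),
                      method = c(average = "average", complete = "complete",
                                 ward = "ward.D")[[method]])
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, method = method, hclust = hc),
            class = "hrt_dendrogram")
}

#' @export
print.hrt_dendrogram <- function(x, ...) {
  cat(sprintf("hrt_dendrogram: %d leaves, %s linkage, merge heights [%.4g, %.4g]\n",
              length(x$labels), x$method, min(x$height), max(x$height)))
  invisible(x)
}

#' Export a dendrogram as Newick
#' @param tree an `hrt_dendrogram`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges (later merges first on ties) and labels
#' the connected components `1..k` in order of first appearance.
#'
#' @param tree an `hrt_dendrogram`.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector sample id -> cluster label in `1..k`.
#' @export
cut_dendrogram <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n)
    hrt_stop("hrt_parameter_error", "k must be in [1, ", n, "], got ", k)
  cl <- stats::cutree(tree$hclust, k = k)
  storage.mode(cl) <- "integer"
  cl
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette: for sample `i` with intra-cluster mean distance `a(i)`
#' (self excluded) and nearest-other-cluster mean distance `b(i)`,
#' `s(i) = (b - a) / max(a, b)`. Samples in singleton clusters score 0, as
#' does the fully degenerate `a = b = 0` case (all points identical).
#'
#' @param dist symmetric distance matrix.
#' @param assignment named integer vector of cluster labels (values `1..k`).
#' @return mean silhouette over all samples, in `[-1, 1]`.
#' @export
silhouette_mean <- function(dist, assignment) {
  validate_distance_matrix(dist)
  cl <- as.integer(assignment)
  n <- nrow(dist)
  stopifnot(length(cl) == n)
  k <- max(cl)
  if (k < 2)
    hrt_stop("hrt_undefined_score_error", "silhouette is undefined for k = 1")
  sizes <- tabulate(cl, k)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), cl)] <- 1
  sums <- dist %*% ind                      # sums[i, g] = sum_j in g d(i, j)
  own <- sums[cbind(seq_len(n), cl)]
  a <- own / pmax(sizes[cl] - 1, 1)
  other <- sweep(sums, 2, sizes, "/")
  other[cbind(seq_len(n), cl)] <- Inf
  b <- apply(other, 1, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0                     # a = b = 0 convention
  s[sizes[cl] == 1] <- 0                    # singleton convention
  mean(s)
}

#' Choose the number of clusters by mean silhouette
#'
#' Cuts the dendrogram at every `k` in `[k_min, k_max]`, scores each cut with
#' [silhouette_mean()] on the same distance the tree was built from, and
#' returns the `k` with the highest score (ties go to the smallest `k`).
#'
#' @param dist distance matrix used to build `tree`.
#' @param tree an `hrt_dendrogram`.
#' @param k_min,k_max inclusive search range, `2 <= k_min < k_max <= n - 1`.
#' @return list with `k` (the argmax) and `scores` (named numeric, one per k).
#' @export
select_k <- function(dist, tree, k_min = 2, k_max = 20) {
  n <- nrow(dist)
  k_max <- min(k_max, n - 1)
  if (!(2 <= k_min && k_min < k_max))
    hrt_stop("hrt_parameter_error", "need 2 <= k_min < k_max <= n - 1")
  ks <- k_min:k_max
  scores <- vapply(ks, function(k)
    silhouette_mean(dist, cut_dendrogram(tree, k)), numeric(1))
  names(scores) <- ks
  list(k = ks[which.max(scores)], scores = scores)
}

# ---------------------------------------------------------------------------

#' Two-letter label initials for a species name
#' @noRd
taxon_initials <- function(taxon) {
  words <- strsplit(trimws(taxon), "\\s+")[[1]]
  if (length(words) >= 2) {
    paste0(toupper(substr(words[1], 1, 1)), tolower(substr(words[2], 1, 1)))
  } else {
    paste0(toupper(substr(words[1], 1, 1)), tolower(substr(words[1], 2, 2)))
  }
}

#' Call Community State Types from a clustering
#'
#' Applies the CST retention and characterization rules to a cluster
#' assignment:
#' * clusters smaller than `max(2, round(min_fraction * n))` samples, or drawn
#'   from fewer than `min_datasets` bioprojects, are dissolved and their
#'   samples reported as unassigned (with 849 samples and the default 1%
#'   fraction the size cut-off is 8 samples);
#' * within each retained cluster, a taxon's prevalence is the fraction of
#'   member samples where its abundance exceeds `presence_threshold`;
#'   taxa with prevalence above `core_prevalence` are the cluster's core;
#' * the defining taxon is the core taxon with the highest mean abundance
#'   (ties broken alphabetically) and names the CST (`"CST-"` + initials);
#' * clusters whose defining taxon is not resolved at species level, that have
#'   no core taxon at all, or (when `single_project_exclude`) whose members
#'   all come from one bioproject are kept in the catalog but flagged
#'   `putative_excluded` rather than `cst`.
#'
#' @param table an [abundance_table()].
#' @param meta aligned [sample_metadata()].
#' @param assignment named integer vector from [cut_dendrogram()].
#' @param min_fraction minimum cluster size as a fraction of all samples.
#' @param min_datasets minimum number of distinct bioprojects per cluster.
#' @param core_prevalence within-cluster prevalence a core taxon must exceed.
#' @param presence_threshold abundance above which a taxon counts as present.
#' @param single_project_exclude flag single-bioproject clusters as putative.
#' @return object of class `cst_catalog`: list of CST definitions (label,
#'   member_samples, prevalence_over_total, core_taxa, defining_taxon,
#'   centroid, status), plus `unassigned_samples` and `parameters`.
#' @export
call_csts <- function(table, meta, assignment,
                      min_fraction = 0.01, min_datasets = 2,
                      core_prevalence = 0.85, presence_threshold = 0,
                      single_project_exclude = TRUE) {
  x <- unclass(table)
  stopifnot(all(names(assignment) == rownames(x)))
  resolved <- attr(table, "species_resolved")
  n_total <- nrow(x)
  min_size <- max(2, round(min_fraction * n_total))
  projects <- meta$bioproject[match(rownames(x), meta$sample_id)]

  defs <- list()
  unassigned <- character(0)
  for (g in sort(unique(assignment))) {
    members <- names(assignment)[assignment == g]
    n_proj <- length(unique(projects[assignment == g]))
    if (length(members) < min_size || n_proj < min_datasets) {
      unassigned <- c(unassigned, members)
      next
    }
    sub <- x[members, , drop = FALSE]
    prev <- colMeans(sub > presence_threshold)
    avg <- colMeans(sub)
    core <- names(prev)[prev > core_prevalence]
    if (length(core) == 0) {
      defining <- NA_character_
      status <- "putative_excluded"
    } else {
      core <- core[order(-avg[core], core)]
      defining <- core[[1]]
      status <- if (!resolved[[defining]]) "putative_excluded"
      else if (single_project_exclude && n_proj == 1) "putative_excluded"
      else "cst"
    }
    lab <- if (is.na(defining)) sprintf("Cluster-%d", g)
    else if (!resolved[[defining]])     # putative cluster, named by genus only
      paste0("Cluster-", toupper(substr(defining, 1, 1)))
    else paste0("CST-", taxon_initials(defining))
    defs[[length(defs) + 1L]] <- list(
      cluster = g,
      label = lab,
      member_samples = members,
      prevalence_over_total = length(members) / n_total,
      core_taxa = if (length(core)) data.frame(
        taxon = core, mean_abundance = unname(avg[core]),
        prevalence = unname(prev[core])) else
          data.frame(taxon = character(0), mean_abundance = numeric(0),
                     prevalence = numeric(0)),
      defining_taxon = defining,
      centroid = avg,
      n_bioprojects = n_proj,
      status = status)
  }
  if (!any(vapply(defs, function(d) d$status == "cst", logical(1))))
    hrt_stop("hrt_no_cst_error",
             "no cluster survived the retention filters; review min_fraction/",
             "min_datasets or the clustering k")

  # order by prevalence, deduplicate labels
  defs <- defs[order(-vapply(defs, `[[`, numeric(1), "prevalence_over_total"))]
  labs <- vapply(defs, `[[`, character(1), "label")
  for (l in unique(labs[duplicated(labs)])) {
    idx <- which(labs == l)
    for (j in seq_along(idx)[-1])
      defs[[idx[j]]]$label <- paste0(l, ".", j)
  }
  structure(list(
    csts = defs,
    unassigned_samples = unassigned,
    parameters = list(min_fraction = min_fraction, min_datasets = min_datasets,
                      core_prevalence = core_prevalence,
                      presence_threshold = presence_threshold,
                      single_project_exclude = single_project_exclude,
                      n_total = n_total, min_size = min_size)),
    class = "cst_catalog")
}

#' @export
print.cst_catalog <- function(x, ...) {
  cat(sprintf("cst_catalog: %d entries (%d retained CSTs, %d putative), %d unassigned samples\n",
              length(x$csts),
              sum(vapply(x$csts, function(d) d$status == "cst", logical(1))),
              sum(vapply(x$csts, function(d) d$status != "cst", logical(1))),
              length(x$unassigned_samples)))
  for (d in x$csts)
    cat(sprintf("  %-12s %5.1f%%  %-32s %s\n", d$label,
                100 * d$prevalence_over_total,
                ifelse(is.na(d$defining_taxon), "-", d$defining_taxon), d$status))
  invisible(x)
}

#' Apply the core-taxon rule to a printed CST summary row
#'
#' Given per-taxon average abundances and prevalences (both in percent, as
#' published summary tables print them), selects the core taxa
#' (prevalence > `core_prevalence * 100`) and returns the most abundant one.
#' Used to reproduce worked examples from printed tables without re-running
#' the clustering.
#'
#' @param avg_abundances named numeric, percent average abundance per taxon.
#' @param prevalences named numeric, percent prevalence per taxon (same names).
#' @param core_prevalence prevalence threshold as a fraction, default 0.85.
#' @return list with `defining_taxon` and `average_abundance` (percent); both
#'   `NA` when no taxon passes the prevalence cut.
#' @export
characterize_cst_from_summary <- function(avg_abundances, prevalences,
                                          core_prevalence = 0.85) {
  if (!setequal(names(avg_abundances), names(prevalences)))
    hrt_stop("hrt_validation_error",
             "abundance and prevalence vectors must cover the same taxa")
  prevalences <- prevalences[names(avg_abundances)]
  core <- names(avg_abundances)[prevalences > core_prevalence * 100]
  if (length(core) == 0)
    return(list(defining_taxon = NA_character_, average_abundance = NA_real_))
  core <- core[order(-avg_abundances[core], core)]
  list(defining_taxon = core[[1]],
       average_abundance = unname(avg_abundances[[core[[1]]]]))
}

#' Assign a sample to its nearest CST
#'
#' Correlates the sample's abundance vector with the centroid (mean abundance
#' vector) of every retained CST and returns the best match.
#'
#' @param catalog a [call_csts()] catalog.
#' @param table abundance table containing the sample.
#' @param sample_id sample to assign.
#' @return list with `label` and `similarity` (Pearson r).
#' @export
assign_to_cst <- function(catalog, table, sample_id) {
  kept <- Filter(function(d) d$status == "cst", catalog$csts)
  if (length(kept) == 0)
    hrt_stop("hrt_no_cst_error", "catalog has no retained CSTs")
  x <- unclass(table)[sample_id, ]
  if (stats::sd(x) == 0)
    hrt_stop("hrt_degenerate_sample_error", "sample ", sample_id,
             " has zero variance across taxa")
  taxa <- names(kept[[1]]$centroid)
  r <- vapply(kept, function(d) stats::cor(x[taxa], d$centroid), numeric(1))
  best <- which.max(r)
  list(label = kept[[best]]$label, similarity = r[[best]])
}

#' Serialize a CST catalog to JSON and a per-sample TSV
#'
#' @param catalog a `cst_catalog`.
#' @param json_path,tsv_path output files (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_catalog <- function(catalog, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    out <- list(
      parameters = catalog$parameters,
      unassigned_samples = catalog$unassigned_samples,
      csts = lapply(catalog$csts, function(d)
        list(label = d$label, status = d$status,
             defining_taxon = d$defining_taxon,
             prevalence_over_total = d$prevalence_over_total,
             n_bioprojects = d$n_bioprojects,
             core_taxa = d$core_taxa,
             member_samples = d$member_samples)))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(catalog$csts, function(d)
      data.frame(sample_id = d$member_samples, cst_label = d$label,
                 status = d$status)))
    if (length(catalog$unassigned_samples))
      rows <- rbind(rows, data.frame(sample_id = catalog$unassigned_samples,
                                     cst_label = "unassigned",
                                     status = "unassigned"))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}

#' Per-sample CST labels from a catalog
#'
#' @param catalog a `cst_catalog`.
#' @param include_putative keep `putative_excluded` entries' labels (default)
#'   or fold their members into `"unassigned"`.
#' @return named character vector sample id -> label (`"unassigned"` for
#'   dissolved clusters).
#' @export
catalog_labels <- function(catalog, include_putative = TRUE) {
  out <- character(0)
  for (d in catalog$csts) {
    lab <- if (d$status == "cst" || include_putative) d$label else "unassigned"
    out[d$member_samples] <- lab
  }
  out[catalog$unassigned_samples] <- "unassigned"
  out
}
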