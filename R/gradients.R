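# Compartment-level reporting: CST prevalence by group, shared-species sets,
# and distance-ordered abundance gradients.

#' CST prevalence within sample groups
#'
#' For every CST row and group column (sampling method, compartment or health
#' status), the fraction of the group's samples assigned to that CST.
#' Unassigned samples count in the denominator but belong to no CST row, so
#' columns sum to at most 1. Cells above `highlight` are flagged.
#'
#' @param catalog a [call_csts()] catalog.
#' @param meta aligned [sample_metadata()].
#' @param group_key `"sampling_method"`, `"compartment"` or `"health_status"`.
#' @param highlight flag threshold, default 0.15.
#' @param include_putative include `putative_excluded` catalog rows.
#' @return list of class `hrt_prevalence`: `values` (CST x group matrix),
#'   `highlighted` (logical matrix), `unassigned_fraction` (per group),
#'   `highlight`.
#' @export
cst_prevalence_by_group <- function(catalog, meta,
                                    group_key = c("compartment", "sampling_method",
                                                  "health_status"),
                                    highlight = 0.15, include_putative = FALSE) {
  group_key <- match.arg(group_key)
  labels <- catalog_labels(catalog, include_putative = include_putative)
  if (!include_putative) {
    put <- vapply(catalog$csts, function(d) d$status != "cst", logical(1))
    for (d in catalog$csts[put]) labels[d$member_samples] <- "unassigned"
  }
  meta <- meta[meta$sample_id %in% names(labels), , drop = FALSE]
  grp <- meta[[group_key]]
  tab_groups <- sort(unique(grp))
  empty <- setdiff(tab_groups, unique(grp[!is.na(grp)]))
  if (length(empty)) hrt_warn("dropping empty group(s): ", paste(empty, collapse = ", "))
  cst_rows <- vapply(
    Filter(function(d) include_putative || d$status == "cst", catalog$csts),
    `[[`, character(1), "label")
  values <- matrix(0, length(cst_rows), length(tab_groups),
                   dimnames = list(cst_rows, tab_groups))
  for (g in tab_groups) {
    ids <- meta$sample_id[grp == g]
    if (!length(ids)) next
    lab <- labels[ids]
    for (cst in cst_rows) values[cst, g] <- mean(lab == cst)
  }
  unassigned <- 1 - colSums(values)
  structure(list(values = values, highlighted = values > highlight,
                 unassigned_fraction = unassigned, highlight = highlight,
                 group_key = group_key),
            class = "hrt_prevalence")
}

#' Species shared across compartment groups
#'
#' A species enters a group's set when its mean relative abundance within the
#' group exceeds `abundance_cut` (default 1%). Returns the per-group sets,
#' their union (the candidate set) and the all-group intersection (species
#' common to every compartment).
#'
#' @param table an [abundance_table()].
#' @param meta aligned [sample_metadata()].
#' @param abundance_cut mean-abundance threshold (fraction), default 0.01.
#' @param groups ordered compartments to consider.
#' @return list: `per_group` (named list of character vectors), `union`,
#'   `intersection`.
#' @export
shared_species <- function(table, meta, abundance_cut = 0.01,
                           groups = c("nasal", "throat", "sputum", "lung")) {
  bad <- setdiff(groups, COMPARTMENTS)
  if (length(bad))
    hrt_stop("hrt_vocabulary_error", "unknown compartment(s): ",
             paste(bad, collapse = ", "))
  x <- unclass(table)
  comp <- meta$compartment[match(rownames(x), meta$sample_id)]
  per_group <- lapply(groups, function(g) {
    ids <- which(comp == g)
    if (!length(ids)) return(character(0))
    means <- colMeans(x[ids, , drop = FALSE])
    names(means)[means > abundance_cut]
  })
  names(per_group) <- groups
  list(per_group = per_group,
       union = sort(Reduce(union, per_group)),
       intersection = sort(Reduce(intersect, per_group)))
}

# Jonckheere-Terpstra statistic for an ordered alternative: sum over ordered
# group pairs (u < v) of the Mann-Whitney count #{x_u < x_v} + 0.5 #{ties}.
jt_statistic <- function(values, group_index, n_groups) {
  s <- 0
  for (u in seq_len(n_groups - 1)) {
    xu <- values[group_index == u]
    for (v in (u + 1):n_groups) {
      xv <- values[group_index == v]
      s <- s + sum(outer(xu, xv, "<")) + 0.5 * sum(outer(xu, xv, "=="))
    }
  }
  s
}

#' Detect an ordered abundance gradient for one taxon
#'
#' Computes the taxon's mean abundance in each group of `group_order` (an
#' anatomical ordering, e.g. distance from the nasal cavity), flags strict
#' monotonicity of those means, and tests the ordered alternative with a
#' Jonckheere-Terpstra permutation test (two-sided; the reported direction is
#' the sign of the observed trend). With two groups the statistic reduces to
#' the Mann-Whitney U count.
#'
#' @param table an [abundance_table()].
#' @param meta aligned [sample_metadata()].
#' @param taxon taxon name.
#' @param group_order ordered compartments defining the gradient axis.
#' @param n_permutations permutations for the trend p-value.
#' @param seed RNG seed.
#' @return list of class `hrt_gradient`: `taxon`, `groups`, `means`,
#'   `direction` (`"increasing"`, `"decreasing"` or `"none"`), `monotone`,
#'   `p_value`, `statistic`.
#' @export
detect_gradient <- function(table, meta, taxon,
                            group_order = c("nasal", "throat", "lung"),
                            n_permutations = 1000, seed = 1) {
  x <- unclass(table)
  if (!(taxon %in% colnames(x)))
    hrt_stop("hrt_unknown_taxon_error", "taxon not in table: ", taxon)
  comp <- meta$compartment[match(rownames(x), meta$sample_id)]
  keep <- comp %in% group_order
  if (length(unique(comp[keep])) < length(group_order))
    hrt_stop("hrt_group_size_error", "every group in group_order must be non-empty")
  vals <- x[keep, taxon]
  gi <- match(comp[keep], group_order)
  ng <- length(group_order)
  means <- vapply(seq_len(ng), function(u) mean(vals[gi == u]), numeric(1))
  names(means) <- group_order

  obs <- jt_statistic(vals, gi, ng)
  # center: expected value under exchangeability
  ns <- tabulate(gi, ng)
  e0 <- sum(utils::combn(ns, 2, FUN = prod)) / 2
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i)
    jt_statistic(vals, sample(gi), ng), numeric(1))
  p <- (sum(abs(perm - e0) >= abs(obs - e0)) + 1) / (n_permutations + 1)

  monotone_inc <- all(diff(means) > 0)
  monotone_dec <- all(diff(means) < 0)
  direction <- if (monotone_inc) "increasing" else if (monotone_dec) "decreasing"
  else if (all(diff(means) == 0)) "none"
  else if (obs > e0) "increasing" else if (obs < e0) "decreasing" else "none"
  structure(list(taxon = taxon, groups = group_order, means = means,
                 direction = direction, monotone = monotone_inc || monotone_dec,
                 p_value = p, statistic = obs, expected = e0),
            class = "hrt_gradient")
}

#' Write a prevalence table as TSV
#' @param prevalence an `hrt_prevalence`.
#' @param path output file.
#' @export
write_prevalence <- function(prevalence, path) {
  df <- data.frame(cst = rownames(prevalence$values), prevalence$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
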