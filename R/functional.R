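# EC-class functional profiling: aggregate EC numbers to the seven top-level
# Enzyme Commission classes, compare classes across groups, count
# compartment-unique pathways.

#' The seven top-level EC classes
#' @export
EC_CLASSES <- c("1" = "oxidoreductases", "2" = "transferases",
                "3" = "hydrolases", "4" = "lyases", "5" = "isomerases",
                "6" = "ligases", "7" = "translocases")

#' Aggregate an EC table to top-level enzyme classes
#'
#' The class of an EC number is its first field; per-sample class abundances
#' are renormalized to sum to 1 over annotated reads (samples with no
#' annotated reads keep an all-zero row and are reported with a warning).
#'
#' @param ec an [ec_table()].
#' @return matrix of class `ec_class_profile`: samples x 7 classes, rows
#'   summing to 1.
#' @export
ec_class_profile <- function(ec) {
  x <- unclass(ec)
  first <- sub("\\..*$", "", colnames(x))
  bad <- setdiff(unique(first), names(EC_CLASSES))
  if (length(bad))
    hrt_stop("hrt_parse_error", "EC top-level class out of range 1-7 for: ",
             paste(colnames(x)[first %in% bad], collapse = ", "))
  prof <- matrix(0, nrow(x), 7,
                 dimnames = list(rownames(x), unname(EC_CLASSES)))
  for (cls in names(EC_CLASSES))
    prof[, EC_CLASSES[[cls]]] <- rowSums(x[, first == cls, drop = FALSE])
  tot <- rowSums(prof)
  zero <- tot == 0
  if (any(zero))
    hrt_warn(sum(zero), " sample(s) have no annotated reads; rows left at zero")
  prof[!zero, ] <- prof[!zero, , drop = FALSE] / tot[!zero]
  structure(prof, class = c("ec_class_profile", class(prof)))
}

#' Compare EC-class abundances across sample groups
#'
#' Runs [anova_tukey()] for each of the seven classes across >= 3 groups and
#' adjusts the per-class ANOVA p-values with BH-FDR.
#'
#' @param profile an [ec_class_profile()].
#' @param meta aligned [sample_metadata()].
#' @param group_key metadata column defining the groups.
#' @param alpha significance level for the Tukey `significant` flags.
#' @return list: `anova` (data.frame class, F, p, q) and `pairwise`
#'   (data.frame with a `class` column prepended to the Tukey table).
#' @export
compare_ec_classes <- function(profile, meta, group_key = "compartment",
                               alpha = 0.05) {
  x <- unclass(profile)
  grp <- meta[[group_key]][match(rownames(x), meta$sample_id)]
  if (length(unique(grp)) < 3)
    hrt_stop("hrt_group_size_error",
             "need >= 3 groups; use two_group_test() for two groups")
  res <- lapply(colnames(x), function(cls) anova_tukey(x[, cls], grp, alpha))
  an <- data.frame(class = colnames(x),
                   F = vapply(res, function(r) r$anova$statistic, numeric(1)),
                   p = vapply(res, function(r) r$anova$p_value, numeric(1)))
  an$q <- bh_fdr(an$p)
  pw <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(class = colnames(x)[i], res[[i]]$pairwise)))
  list(anova = an, pairwise = pw)
}

#' Count pathways unique to one compartment
#'
#' A pathway is "present" in a compartment when it is detected (abundance
#' > 0) in at least `presence_min_prevalence` of the compartment's samples;
#' it is "unique" when present in exactly one compartment.
#'
#' @param pw a [pathway_table()].
#' @param meta aligned [sample_metadata()].
#' @param presence_min_prevalence within-compartment detection fraction
#'   required for presence, default 0.25.
#' @param groups compartments to consider.
#' @return list of class `hrt_unique_pathways`: `present` (named list of
#'   per-compartment pathway sets), `unique` (named list of unique sets),
#'   `counts` (named integer), `presence_min_prevalence`.
#' @export
unique_pathways <- function(pw, meta, presence_min_prevalence = 0.25,
                            groups = c("nasal", "throat", "sputum", "lung")) {
  if (presence_min_prevalence < 0 || presence_min_prevalence > 1)
    hrt_stop("hrt_parameter_error", "presence_min_prevalence must be in [0, 1]")
  x <- unclass(pw)
  comp <- meta$compartment[match(rownames(x), meta$sample_id)]
  present <- lapply(groups, function(g) {
    ids <- which(comp == g)
    if (!length(ids)) return(character(0))
    det <- colMeans(x[ids, , drop = FALSE] > 0)
    names(det)[det >= presence_min_prevalence]
  })
  names(present) <- groups
  n_in <- table(unlist(present))
  uniq <- lapply(groups, function(g)
    present[[g]][n_in[present[[g]]] == 1])
  names(uniq) <- groups
  counts <- vapply(uniq, length, integer(1))
  structure(list(present = present, unique = uniq, counts = counts,
                 presence_min_prevalence = presence_min_prevalence),
            class = "hrt_unique_pathways")
}

#' @export
print.hrt_unique_pathways <- function(x, ...) {
  cat("unique pathways per compartment (presence rule: detected in >= ",
      100 * x$presence_min_prevalence, "% of the group's samples)\n", sep = "")
  print(x$counts)
  invisible(x)
}
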