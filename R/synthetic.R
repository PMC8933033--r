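# Synthetic dataset generator: plants CST structure, compartment-linked CST
# prevalences, abundance gradients, a health-linked richness gap, EC-class
# shifts and compartment-unique pathways, so the whole pipeline is testable
# without external downloads. The planted truth is returned alongside.

#' Packaged reference summary of 13 respiratory-tract CSTs
#'
#' Average abundance and within-CST prevalence (both percent) of the 13
#' defining species across 13 published community state types from a
#' meta-analysis of 849 respiratory-tract shotgun metagenomes, plus each
#' CST's share of all samples. Used as the default template for the
#' synthetic-data generator and for worked-example checks of the core-taxon
#' rule.
#'
#' @param path TSV location; defaults to the copy shipped with the package.
#' @return list: `avg` (CST x taxon percent means), `prev` (CST x taxon
#'   percent prevalences), `prevalence_total` (named percent vector).
#' @export
cst_reference_summary <- function(path = system.file("extdata",
                                                     "cst_reference_summary.tsv",
                                                     package = "hrtcst")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  csts <- unique(df$cst)
  taxa <- unique(df$taxon)
  avg <- prev <- matrix(NA_real_, length(csts), length(taxa),
                        dimnames = list(csts, taxa))
  for (i in seq_len(nrow(df))) {
    avg[df$cst[i], df$taxon[i]] <- df$mean_abundance_pct[i]
    prev[df$cst[i], df$taxon[i]] <- df$prevalence_pct[i]
  }
  tot <- df$prevalence_total_pct[!duplicated(df$cst)]
  names(tot) <- csts
  list(avg = avg, prev = prev, prevalence_total = tot)
}

#' Specification of one planted CST
#'
#' @param label CST label in the truth record.
#' @param defining_taxon species planted at `dominant_mean` in every member.
#' @param dominant_mean its mean relative abundance (fraction, `[0.09, 0.6]`
#'   is the realistic dominance range).
#' @param core named vector of additional planted taxon means (fractions).
#' @param prevalence named vector of within-CST prevalence targets (fractions)
#'   for the planted taxa; the defining taxon defaults to 1.
#' @param weight mixing weight of this CST (normalized across the spec).
#' @param single_bioproject force all members into one dedicated bioproject
#'   (to exercise the single-study exclusion rule).
#' @return list of class `cst_spec`.
#' @export
cst_spec <- function(label, defining_taxon, dominant_mean, core = NULL,
                     prevalence = NULL, weight = 1, single_bioproject = FALSE) {
  means <- c(stats::setNames(dominant_mean, defining_taxon), core)
  prev <- stats::setNames(rep(1, length(means)), names(means))
  if (!is.null(prevalence)) prev[names(prevalence)] <- prevalence
  keep <- means > 0 & prev > 0
  structure(list(label = label, defining_taxon = defining_taxon,
                 means = means[keep], prevalence = prev[keep],
                 weight = weight, single_bioproject = single_bioproject),
            class = "cst_spec")
}

reference_cst_specs <- function(csts = NULL) {
  ref <- cst_reference_summary()
  use <- csts %||% rownames(ref$avg)
  lapply(use, function(l) {
    means <- ref$avg[l, ] / 100
    prev <- ref$prev[l, ] / 100
    def <- names(which.max(ifelse(prev > 0.85, means, -Inf)))
    cst_spec(label = l, defining_taxon = def, dominant_mean = means[[def]],
             core = means[setdiff(names(means)[means > 0], def)],
             prevalence = prev[means > 0],
             weight = ref$prevalence_total[[l]])
  })
}

FILLER_SPECIES <- c(
  "Streptococcus parasanguinis", "Streptococcus oralis", "Streptococcus pyogenes",
  "Rothia dentocariosa", "Rothia aeria", "Veillonella atypica",
  "Veillonella dispar", "Prevotella salivae", "Prevotella nanceiensis",
  "Neisseria flavescens", "Neisseria lactamica", "Haemophilus parainfluenzae",
  "Moraxella catarrhalis", "Dolosigranulum pigrum", "Corynebacterium accolens",
  "Corynebacterium pseudodiphtheriticum", "Fusobacterium nucleatum",
  "Fusobacterium periodonticum", "Leptotrichia buccalis", "Gemella haemolysans",
  "Granulicatella adiacens", "Actinomyces graevenitzii", "Atopobium parvulum",
  "Megasphaera micronuciformis", "Campylobacter concisus", "Capnocytophaga gingivalis",
  "Porphyromonas pasteri", "Alloprevotella rava", "Lautropia mirabilis",
  "Eikenella corrodens", "Kingella oralis", "Cardiobacterium hominis",
  "Abiotrophia defectiva", "Selenomonas sputigena", "Oribacterium sinus",
  "Stomatobaculum longum", "Solobacterium moorei", "Parvimonas micra",
  "Mogibacterium diversum", "Peptostreptococcus stomatis")

default_gradient_taxa <- function() {
  list(
    "Streptococcus pneumoniae" =
      c(nasal = 0.030, throat = 0.015, sputum = 0.008, lung = 0.004),
    "Veillonella parvula" =
      c(nasal = 0.003, throat = 0.015, sputum = 0.025, lung = 0.006))
}

default_ec_class_means <- function() {
  m <- rbind(
    nasal  = c(0.1960, 0.280, 0.270, 0.080, 0.050, 0.080, 0.0440),
    throat = c(0.1200, 0.310, 0.300, 0.090, 0.050, 0.090, 0.0400),
    sputum = c(0.1250, 0.310, 0.295, 0.090, 0.050, 0.090, 0.0400),
    lung   = c(0.1743, 0.290, 0.270, 0.085, 0.050, 0.085, 0.0457))
  colnames(m) <- unname(EC_CLASSES)
  m / rowSums(m)
}

default_ec_class_sd <- function() {
  m <- default_ec_class_means()
  s <- 0.08 * m                       # 8% relative spread by default
  s["nasal", "oxidoreductases"] <- 0.0162
  s["lung", "oxidoreductases"] <- 0.0365
  s
}

#' Build a synthetic-dataset specification
#'
#' The defaults state one fixed world modeled on the published meta-analysis:
#' 850 samples, the 13 reference CSTs (defining-species means 9-60%, template
#' core/accessory means and prevalences), four compartments with
#' compartment-tilted CST weights (nasal enriched for CST-Se, throat for
#' CST-Pj/Rm/Sm, lung for CST-Sa/Pa/Tj), 16 bioprojects pooled per
#' compartment, two planted abundance gradients, a 14-species richness gap
#' between diseased and healthy samples, compartment EC-class profiles with
#' oxidoreductases elevated in nasal (19.6% +/- 1.62%) and lung
#' (17.43% +/- 3.65%), and compartment-unique pathway counts
#' 86/101/237/95 (nasal/throat/sputum/lung).
#'
#' @param n_samples number of samples.
#' @param csts reference CST labels to plant (`NULL` = all 13), ignored when
#'   `cst_specs` is given.
#' @param cst_specs explicit list of [cst_spec()] objects.
#' @param seed mandatory RNG seed.
#' @param n_filler number of accessory background species.
#' @param filler_mass total expected abundance of the background species.
#' @param concentration Dirichlet concentration of each background species
#'   (values below 1 give the sparse accessory profiles seen in real data);
#'   the total concentration follows as
#'   `concentration * n_filler / filler_mass`.
#' @param zero_inflation per-sample dropout probability of each background
#'   species.
#' @param n_bioprojects number of dataset labels.
#' @param compartment_probs sampling probabilities of the four compartments.
#' @param compartment_cst_tilt named list compartment -> named enrichment
#'   multipliers on the joint compartment x CST weights; marginals are
#'   restored by iterative proportional fitting, so the global CST shares
#'   stay at their template values.
#' @param planted_taxa named list taxon -> named vector of per-compartment
#'   mean abundances, overlaid on every sample (gradients, ubiquitous or
#'   compartment-private plants).
#' @param diseased_fraction disease probability for CSTs without a bias entry.
#' @param cst_disease_bias named disease probabilities per CST label (`NULL`
#'   disables the disease-CST association).
#' @param richness_gap number of extra background species zeroed in each
#'   diseased sample.
#' @param ec_class_means,ec_class_sd 4 x 7 matrices (compartment x EC class)
#'   of class means and standard deviations.
#' @param pathway_plant list with `shared` (count of pathways present in all
#'   compartments) and `unique` (named per-compartment unique counts).
#' @param include_putative_clusters also plant two clusters defined by
#'   species-unresolved taxa (one restricted to a single bioproject) to
#'   exercise the putative-exclusion rules.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 850, csts = NULL, cst_specs = NULL,
                           seed = 1,
                           n_filler = 40, filler_mass = 0.20,
                           concentration = 0.8, zero_inflation = 0.5,
                           n_bioprojects = 16,
                           compartment_probs = c(nasal = 0.10, throat = 0.42,
                                                 sputum = 0.26, lung = 0.22),
                           compartment_cst_tilt = NULL,
                           planted_taxa = default_gradient_taxa(),
                           diseased_fraction = 0.5,
                           cst_disease_bias = c("CST-Hi" = 0.95, "CST-Tj" = 0.95,
                                                "CST-Se" = 0.95, "CST-Pa" = 0.95,
                                                "CST-Sa" = 0.95, "CST-Pj" = 0.07),
                           richness_gap = 14,
                           ec_class_means = default_ec_class_means(),
                           ec_class_sd = default_ec_class_sd(),
                           pathway_plant = list(shared = 150,
                                                unique = c(nasal = 86, throat = 101,
                                                           sputum = 237, lung = 95)),
                           include_putative_clusters = FALSE) {
  if (is.null(seed)) hrt_stop("hrt_parameter_error", "seed is mandatory")
  if (is.null(cst_specs)) cst_specs <- reference_cst_specs(csts)
  if (include_putative_clusters) {
    cst_specs <- c(cst_specs, list(
      cst_spec("Cluster-P", "Pasteurella sp.", 0.30,
               core = c("Haemophilus parainfluenzae" = 0.02), weight = 3),
      cst_spec("Cluster-S", "Schaalia sp.", 0.25, weight = 2,
               single_bioproject = TRUE)))
  }
  w <- vapply(cst_specs, `[[`, numeric(1), "weight")
  for (i in seq_along(cst_specs)) cst_specs[[i]]$weight <- w[i] / sum(w)
  if (is.null(compartment_cst_tilt) && is.null(csts) &&
      length(cst_specs) >= 13 &&
      all(c("CST-Se", "CST-Pj", "CST-Sa") %in%
            vapply(cst_specs, `[[`, character(1), "label"))) {
    compartment_cst_tilt <- list(
      nasal = c("CST-Se" = 8),
      throat = c("CST-Pj" = 3, "CST-Rm" = 2, "CST-Sm" = 2),
      lung = c("CST-Sa" = 3, "CST-Pa" = 3, "CST-Tj" = 3))
  }
  spec <- structure(
    list(n_samples = n_samples, cst_specs = cst_specs, seed = seed,
         n_filler = n_filler, filler_mass = filler_mass,
         concentration = concentration, zero_inflation = zero_inflation,
         n_bioprojects = n_bioprojects,
         compartment_probs = compartment_probs / sum(compartment_probs),
         compartment_cst_tilt = compartment_cst_tilt,
         planted_taxa = planted_taxa,
         diseased_fraction = diseased_fraction,
         cst_disease_bias = cst_disease_bias,
         richness_gap = richness_gap,
         ec_class_means = ec_class_means, ec_class_sd = ec_class_sd,
         pathway_plant = pathway_plant),
    class = "synthetic_spec")
  check_feasibility(spec)
  spec
}

check_feasibility <- function(spec) {
  # worst-case overlay load in any one compartment
  overlay_max <- if (length(spec$planted_taxa)) {
    comps <- names(spec$compartment_probs)
    max(vapply(comps, function(g)
      sum(vapply(spec$planted_taxa, function(v) v[g] %||% 0, numeric(1)),
          na.rm = TRUE), numeric(1)))
  } else 0
  for (cs in spec$cst_specs) {
    tot <- sum(cs$means) + spec$filler_mass + overlay_max
    if (tot > 0.98)
      hrt_stop("hrt_feasibility_error", "planted means of ", cs$label,
               " plus filler mass and overlays sum to ", round(tot, 3),
               " > 0.98; reduce dominant means or filler_mass")
  }
  invisible(spec)
}

#' Compartment-conditional CST weight matrix
#'
#' The tilt entries are enrichment multipliers on the joint
#' compartment x CST distribution; iterative proportional fitting then
#' restores both stated marginals (compartment probabilities and the global
#' CST shares), so enriching a CST in one compartment depletes it elsewhere
#' instead of inflating its overall prevalence.
#' @noRd
compartment_cst_weights <- function(spec) {
  labels <- vapply(spec$cst_specs, `[[`, character(1), "label")
  global <- vapply(spec$cst_specs, `[[`, numeric(1), "weight")
  names(global) <- labels
  comps <- names(spec$compartment_probs)
  J <- spec$compartment_probs %o% global
  for (comp in names(spec$compartment_cst_tilt %||% list())) {
    tilt <- spec$compartment_cst_tilt[[comp]]
    J[comp, names(tilt)] <- J[comp, names(tilt)] * tilt
  }
  for (it in seq_len(200)) {
    J <- J * (spec$compartment_probs / rowSums(J))
    J <- t(t(J) * (global / colSums(J)))
    if (max(abs(rowSums(J) - spec$compartment_probs)) < 1e-12) break
  }
  J / rowSums(J)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(0, n, k)
  pos <- alpha > 0
  x[, pos] <- matrix(stats::rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
                     n, sum(pos))
  x / rowSums(x)
}

#' Generate a complete synthetic dataset
#'
#' Per sample: draw a compartment, a CST (compartment-tilted weights), a
#' bioproject (compartment-specific pool), and a health status (CST-biased).
#' Abundances come from a Dirichlet whose mean vector holds the CST's planted
#' taxon means plus a uniform background and an unclassified residual;
#' within-CST prevalence targets are planted exactly (a fixed number of
#' members is zeroed per planted taxon), background species drop out
#' independently with probability `zero_inflation`, planted per-compartment
#' taxa (gradients, shared/private species) are overlaid, and diseased
#' samples lose `richness_gap` extra background species. EC class profiles
#' are drawn log-normally around compartment means and pathways are planted
#' per `pathway_plant`. The same spec (same seed) is byte-identical across
#' runs.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `hrt_dataset`: `table` ([abundance_table()]), `meta`
#'   ([sample_metadata()]), `ec` ([ec_table()]), `pathways`
#'   ([pathway_table()]), `truth` (planted labels and parameters).
#' @export
generate_dataset <- function(spec) {
  check_feasibility(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  comps <- names(spec$compartment_probs)
  compartment <- sample(comps, n, replace = TRUE, prob = spec$compartment_probs)
  W <- compartment_cst_weights(spec)
  labels <- colnames(W)
  cst <- character(n)
  for (comp in comps) {
    idx <- which(compartment == comp)
    cst[idx] <- sample(labels, length(idx), replace = TRUE, prob = W[comp, ])
  }

  # bioprojects: disjoint per-compartment pools (>= 2 each, weighted so the
  # two-dataset retention filter is exercised both ways)
  n_bp <- spec$n_bioprojects
  bp_names <- sprintf("PRJ%03d", seq_len(n_bp))
  pool_of <- split(bp_names, rep_len(seq_along(comps), n_bp))
  names(pool_of) <- comps
  bioproject <- character(n)
  for (comp in comps) {
    idx <- which(compartment == comp)
    pool <- pool_of[[comp]]
    pr <- rev(seq_along(pool))
    bioproject[idx] <- sample(pool, length(idx), replace = TRUE, prob = pr / sum(pr))
  }
  single_bp <- vapply(spec$cst_specs, `[[`, logical(1), "single_bioproject")
  for (cs in spec$cst_specs[single_bp])
    bioproject[cst == cs$label] <- bp_names[n_bp]

  p_dis <- rep(spec$diseased_fraction, n)
  if (!is.null(spec$cst_disease_bias)) {
    hit <- cst %in% names(spec$cst_disease_bias)
    p_dis[hit] <- spec$cst_disease_bias[cst[hit]]
  }
  health <- ifelse(stats::runif(n) < p_dis, "diseased", "healthy")

  # --- abundance matrix -----------------------------------------------------
  planted_names <- unique(unlist(lapply(spec$cst_specs, function(cs) names(cs$means))))
  overlay_names <- names(spec$planted_taxa %||% list())
  n_extra <- max(0, spec$n_filler - length(FILLER_SPECIES))
  filler <- c(utils::head(FILLER_SPECIES, spec$n_filler),
              if (n_extra) sprintf("Commensal bacterium%02d", seq_len(n_extra)))
  filler <- setdiff(filler, c(planted_names, overlay_names))
  taxa <- unique(c(planted_names, overlay_names, filler))
  x <- matrix(0, n, length(taxa), dimnames = list(ids, taxa))

  filler_mean <- spec$filler_mass / length(filler)
  for (cs in spec$cst_specs) {
    members <- which(cst == cs$label)
    if (!length(members)) next
    m_vec <- stats::setNames(numeric(length(taxa)), taxa)
    m_vec[names(cs$means)] <- cs$means
    m_vec[filler] <- filler_mean
    residual <- 1 - sum(m_vec)
    # total concentration anchored so each background species has alpha =
    # `concentration` (< 1 gives the sparse accessory profiles of real data)
    alpha0 <- if (length(filler) && spec$filler_mass > 0)
      spec$concentration * length(filler) / spec$filler_mass
    else spec$concentration * (length(m_vec) + 1)
    alpha <- alpha0 * c(m_vec, residual)
    draws <- rdirichlet(length(members), alpha)[, seq_along(m_vec), drop = FALSE]
    colnames(draws) <- taxa
    # plant within-CST prevalences exactly: zero a fixed member count per taxon
    for (t in names(cs$means)) {
      p <- cs$prevalence[[t]]
      n_zero <- round((1 - p) * length(members))
      if (n_zero > 0)
        draws[sample.int(length(members), n_zero), t] <- 0
    }
    drop <- matrix(stats::runif(length(members) * length(filler)) < spec$zero_inflation,
                   length(members), length(filler))
    draws[, filler][drop] <- 0
    x[members, ] <- draws
  }

  # disease-linked richness gap: zero extra background species
  for (i in which(health == "diseased")) {
    nz <- which(x[i, filler] > 0)
    if (length(nz)) {
      k <- min(spec$richness_gap, length(nz))
      x[i, filler[sample(nz, k)]] <- 0
    }
  }

  # overlay per-compartment planted taxa (gradients, shared/private species)
  for (t in overlay_names) {
    mg <- spec$planted_taxa[[t]][compartment]
    mg[is.na(mg)] <- 0
    v <- numeric(n)
    pos <- mg > 0
    v[pos] <- stats::rgamma(sum(pos), shape = 9, rate = 9 / mg[pos])
    x[, t] <- v
  }
  tot <- rowSums(x)
  over <- tot > 0.995
  if (any(over)) {
    base_cols <- setdiff(taxa, overlay_names)
    ov_sum <- rowSums(x[, overlay_names, drop = FALSE])
    scale <- pmax(0.995 - ov_sum[over], 0) / rowSums(x[over, base_cols, drop = FALSE])
    x[over, base_cols] <- x[over, base_cols, drop = FALSE] * scale
  }

  table <- abundance_table(x)
  meta <- sample_metadata(data.frame(
    sample_id = ids, bioproject = bioproject,
    country = c("DE", "UK", "US", "CN", "IT", "RU", "CH", "BR")[
      (match(bioproject, bp_names) - 1L) %% 8L + 1L],
    sampling_method = c(nasal = "nasal_lavage", throat = "oropharynx_swab",
                        sputum = "sputum", lung = "lung_lavage")[compartment],
    health_status = health))

  ec <- generate_ec(spec, ids, compartment)
  pathways <- generate_pathways(spec, ids, compartment)

  truth <- structure(list(
    sample_id = ids,
    cst = stats::setNames(cst, ids),
    compartment = stats::setNames(compartment, ids),
    health_status = stats::setNames(health, ids),
    bioproject = stats::setNames(bioproject, ids),
    defining = stats::setNames(
      vapply(spec$cst_specs, `[[`, character(1), "defining_taxon"),
      vapply(spec$cst_specs, `[[`, character(1), "label")),
    compartment_cst_weights = W,
    planted_taxa = spec$planted_taxa,
    seed = spec$seed), class = "hrt_truth")

  structure(list(table = table, meta = meta, ec = ec, pathways = pathways,
                 truth = truth), class = "hrt_dataset")
}

EC_IDS <- list(
  c("1.1.1.27", "1.7.1.4", "1.14.13.39"),
  c("2.4.1.1", "2.7.1.40", "2.3.1.12"),
  c("3.2.1.1", "3.2.1.41", "3.5.1.2"),
  c("4.1.1.31", "4.2.1.2", "4.1.2.13"),
  c("5.3.1.9", "5.1.3.3", "5.4.2.11"),
  c("6.3.4.2", "6.1.1.1", "6.2.1.5"),
  c("7.2.2.21", "7.1.1.1", "7.4.2.8"))

generate_ec <- function(spec, ids, compartment) {
  n <- length(ids)
  m <- spec$ec_class_means
  s <- spec$ec_class_sd
  # log-normal perturbation sized so the renormalized class sd matches s
  cls <- matrix(0, n, 7)
  for (comp in rownames(m)) {
    idx <- which(compartment == comp)
    if (!length(idx)) next
    sig <- s[comp, ] / (m[comp, ] * (1 - m[comp, ]))
    w <- matrix(m[comp, ], length(idx), 7, byrow = TRUE) *
      exp(matrix(stats::rnorm(length(idx) * 7, 0, rep(sig, each = length(idx))),
                 length(idx), 7))
    cls[idx, ] <- w / rowSums(w)
  }
  split_w <- c(0.5, 0.3, 0.2)
  cols <- unlist(EC_IDS)
  ec <- matrix(0, n, length(cols), dimnames = list(ids, cols))
  for (k in 1:7)
    ec[, EC_IDS[[k]]] <- cls[, k] %o% split_w
  ec_table(ec)
}

generate_pathways <- function(spec, ids, compartment) {
  n <- length(ids)
  uq <- spec$pathway_plant$unique
  shared_ids <- sprintf("PWY-SHARED-%03d", seq_len(spec$pathway_plant$shared))
  uniq_ids <- unlist(lapply(names(uq), function(g)
    sprintf("PWY-%s-%03d", toupper(g), seq_len(uq[[g]]))))
  cols <- c(shared_ids, uniq_ids)
  det <- matrix(FALSE, n, length(cols), dimnames = list(ids, cols))
  det[, shared_ids] <- stats::runif(n * length(shared_ids)) < 0.9
  for (g in names(uq)) {
    idx <- which(compartment == g)
    gcols <- grep(paste0("^PWY-", toupper(g), "-"), cols, value = TRUE)
    det[idx, gcols] <- stats::runif(length(idx) * length(gcols)) < 0.8
  }
  v <- matrix(0, n, length(cols), dimnames = list(ids, cols))
  v[det] <- stats::rgamma(sum(det), shape = 2, rate = 1)
  rs <- rowSums(v)
  v[rs > 0, ] <- v[rs > 0, , drop = FALSE] / rs[rs > 0]
  pathway_table(v)
}

#' Adjusted Rand Index between two labelings
#'
#' Hubert-Arabie chance-corrected agreement; 1 for identical partitions,
#' ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(length(a), 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(if (sij == expected) 1 else 0)
  (sij - expected) / (max_index - expected)
}

#' Recovery metrics of a called catalog against the planted truth
#'
#' @param truth the `truth` element of a generated dataset.
#' @param catalog a [call_csts()] catalog on the same samples.
#' @return list: `ari` (Adjusted Rand Index; unassigned samples count as
#'   their own singleton classes), `defining_taxon_accuracy` (fraction of
#'   planted CSTs whose plurality-matched called cluster recovered the
#'   planted defining species), `prevalence_max_error` (max absolute
#'   CST-by-compartment prevalence difference, planted vs called), and
#'   `matching` (planted label -> called label).
#' @export
truth_report <- function(truth, catalog) {
  called <- catalog_labels(catalog, include_putative = TRUE)
  if (!setequal(names(called), names(truth$cst)))
    hrt_stop("hrt_alignment_error", "truth and catalog cover different samples")
  called <- called[names(truth$cst)]
  un <- called == "unassigned"
  called[un] <- paste0("unassigned_", names(called)[un])
  ari <- adjusted_rand_index(truth$cst, called)

  defs <- stats::setNames(
    vapply(catalog$csts, function(d) d$defining_taxon, character(1)),
    vapply(catalog$csts, function(d) d$label, character(1)))
  planted <- names(truth$defining)
  matching <- character(0)
  hits <- logical(length(planted))
  for (i in seq_along(planted)) {
    members <- names(truth$cst)[truth$cst == planted[i]]
    top <- names(sort(table(called[members]), decreasing = TRUE))[1]
    matching[planted[i]] <- top
    hits[i] <- !is.na(defs[top] %||% NA) && !startsWith(top, "unassigned_") &&
      identical(unname(defs[top]), unname(truth$defining[[planted[i]]]))
  }

  comps <- rownames(truth$compartment_cst_weights)
  err <- 0
  for (comp in comps) {
    in_comp <- truth$compartment == comp
    if (!any(in_comp)) next
    for (l in planted) {
      p_true <- mean(truth$cst[in_comp] == l)
      p_called <- mean(called[in_comp] == matching[[l]])
      err <- max(err, abs(p_true - p_called))
    }
  }
  list(ari = ari, defining_taxon_accuracy = mean(hits),
       prevalence_max_error = err, matching = matching)
}

#' Write a generated dataset as the pipeline's standard TSV/JSON files
#'
#' @param dataset an `hrt_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             ec = file.path(dir, "ec.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             truth = file.path(dir, "truth.json"))
  write_abundance_table(dataset$table, paths[["abundance"]])
  write_metadata(dataset$meta, paths[["metadata"]])
  write_feature_table(dataset$ec, paths[["ec"]])
  write_feature_table(dataset$pathways, paths[["pathways"]])
  tr <- dataset$truth
  jsonlite::write_json(
    list(cst = as.list(tr$cst), compartment = as.list(tr$compartment),
         health_status = as.list(tr$health_status),
         defining = as.list(tr$defining), seed = tr$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
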