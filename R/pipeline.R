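# Pipeline driver and command-line entry point. Subcommands mirror the
# analysis stages: simulate, call-csts, gradients, functional, report.

#' Default pipeline configuration
#' @noRd
default_config <- function() {
  list(abundance = NULL, metadata = NULL, ec = NULL, pathways = NULL,
       out = "hrtcst_out", seed = 1,
       k = NULL, k_min = 2, k_max = 20,
       min_fraction = 0.01, min_datasets = 2, core_prevalence = 0.85,
       presence_threshold = 0, single_project_exclude = TRUE,
       n_permutations = 1000, highlight = 0.15,
       gradient_order = c("nasal", "throat", "lung"),
       abundance_cut = 0.01, presence_min_prevalence = 0.25,
       drop_groups = "other")
}

#' Run the full CST analysis pipeline
#'
#' Load -> align -> Pearson distance -> UPGMA -> silhouette k selection (or a
#' fixed `k`) -> CST calling -> prevalence / richness / ordination /
#' PERMANOVA reports, plus gradient and functional reports when the optional
#' inputs are present. Every run writes a resolved-config YAML copy and a log
#' of parameter values, and is deterministic given `seed`.
#'
#' @param config named list; see `yaml` config keys in the README. Unset keys
#'   take the package defaults.
#' @return invisibly, a list with the in-memory results and the output
#'   directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
                            sep = "", file = log_path, append = TRUE)
  cfg$version <- as.character(utils::packageVersion("hrtcst"))
  yaml::write_yaml(cfg, file.path(cfg$out, "config_resolved.yaml"))
  logf("hrtcst %s starting, seed %d", cfg$version, cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage %s failed: %s", name, conditionMessage(e))
      hrt_stop("hrt_pipeline_error", "stage ", name, ": ", conditionMessage(e))
    })
  }

  res <- list(out = cfg$out)
  stage("profiles_io", {
    if (is.null(cfg$abundance) || is.null(cfg$metadata))
      hrt_stop("hrt_parse_error", "abundance and metadata paths are required")
    table <- load_abundance_table(cfg$abundance)
    meta <- load_metadata(cfg$metadata)
    aligned <- align_dataset(table, meta, drop_groups = cfg$drop_groups)
    res$table <- aligned$table
    res$meta <- aligned$meta
    logf("loaded %d samples x %d taxa", nrow(aligned$table), ncol(aligned$table))
  })
  stage("cst_core", {
    d <- pearson_distance(res$table)
    tree <- upgma_linkage(d)
    write_newick(tree, file.path(cfg$out, "dendrogram.nwk"))
    if (is.null(cfg$k)) {
      sel <- select_k(d, tree, cfg$k_min, cfg$k_max)
      utils::write.table(
        data.frame(k = names(sel$scores), silhouette = sel$scores),
        file.path(cfg$out, "silhouette_by_k.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      cfg$k <- sel$k
      logf("silhouette selected k = %d", sel$k)
    }
    assignment <- cut_dendrogram(tree, cfg$k)
    res$catalog <- call_csts(res$table, res$meta, assignment,
                              min_fraction = cfg$min_fraction,
                              min_datasets = cfg$min_datasets,
                              core_prevalence = cfg$core_prevalence,
                              presence_threshold = cfg$presence_threshold,
                              single_project_exclude = cfg$single_project_exclude)
    write_catalog(res$catalog, file.path(cfg$out, "cst_catalog.json"),
                  file.path(cfg$out, "cst_assignments.tsv"))
    res$dist <- d
    logf("called %d catalog entries", length(res$catalog$csts))
  })
  stage("reports", {
    prev <- cst_prevalence_by_group(res$catalog, res$meta, "compartment",
                                    highlight = cfg$highlight)
    write_prevalence(prev, file.path(cfg$out, "cst_prevalence_by_compartment.tsv"))
    rich <- richness(res$table)
    utils::write.table(data.frame(sample_id = names(rich), richness = rich),
                       file.path(cfg$out, "richness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bc <- bray_curtis(res$table)
    ord <- pcoa(bc, n_axes = 3)
    utils::write.table(
      data.frame(sample_id = ord$ids, ord$coordinates),
      file.path(cfg$out, "pcoa_coordinates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(axis = seq_along(ord$eigenvalues),
                 eigenvalue = ord$eigenvalues,
                 proportion_explained = ord$proportion_explained),
      file.path(cfg$out, "pcoa_eigenvalues.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    pm <- permanova(bc, stats::setNames(res$meta$compartment, res$meta$sample_id),
                    n_permutations = cfg$n_permutations,
                    seed = derive_seed(cfg$seed, "permanova"))
    jsonlite::write_json(unclass(pm)[c("pseudo_F", "p_value", "n_permutations", "seed")],
                         file.path(cfg$out, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)
    res$permanova <- pm
    logf("PERMANOVA by compartment: F = %.3f, p = %.4f", pm$pseudo_F, pm$p_value)
  })
  stage("gradients", {
    order_groups <- intersect(cfg$gradient_order, unique(res$meta$compartment))
    if (length(order_groups) >= 2) {
      sh <- shared_species(res$table, res$meta, cfg$abundance_cut,
                           groups = intersect(c("nasal", "throat", "sputum", "lung"),
                                              unique(res$meta$compartment)))
      jsonlite::write_json(sh, file.path(cfg$out, "shared_species.json"),
                           auto_unbox = FALSE, digits = NA)
      logf("shared species: union %d, intersection %d",
           length(sh$union), length(sh$intersection))
    }
  })
  if (!is.null(cfg$ec)) {
    stage("functional_ec", {
      ec <- load_ec_table(cfg$ec)
      prof <- ec_class_profile(ec)
      utils::write.table(data.frame(sample_id = rownames(prof), unclass(prof),
                                    check.names = FALSE),
                         file.path(cfg$out, "ec_class_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cmp <- compare_ec_classes(prof, res$meta)
      utils::write.table(cmp$anova, file.path(cfg$out, "ec_class_anova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cmp$pairwise, file.path(cfg$out, "ec_class_tukey.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$ec_comparison <- cmp
    })
  } else logf("no EC table supplied; skipping functional_ec stage")
  if (!is.null(cfg$pathways)) {
    stage("functional_pathways", {
      pw <- load_pathway_table(cfg$pathways)
      up <- unique_pathways(pw, res$meta, cfg$presence_min_prevalence)
      jsonlite::write_json(list(counts = as.list(up$counts),
                                presence_min_prevalence = up$presence_min_prevalence),
                           file.path(cfg$out, "unique_pathways.json"),
                           auto_unbox = TRUE, digits = NA)
      res$unique_pathways <- up
      logf("unique pathways: %s",
           paste(names(up$counts), up$counts, sep = "=", collapse = ", "))
    })
  } else logf("no pathway table supplied; skipping functional_pathways stage")
  logf("done")
  invisible(res)
}

#' Command-line entry point
#'
#' `Rscript -e 'hrtcst::hrtcst_cli()' <subcommand> --flags`. Subcommands:
#' `simulate` (write a synthetic dataset), `call-csts` / `report` (full
#' pipeline), `gradients`, `functional`. Returns the exit status instead of
#' quitting when `exit = FALSE` (used by tests).
#'
#' @param args character vector, defaults to the real command line.
#' @param exit call `quit(status)` when done.
#' @return integer exit status, invisibly (when `exit = FALSE`).
#' @export
hrtcst_cli <- function(args = commandArgs(trailingOnly = TRUE), exit = TRUE) {
  status <- tryCatch({
    if (length(args) == 0)
      hrt_stop("hrt_parameter_error",
               "usage: hrtcst_cli <simulate|call-csts|gradients|functional|report> [--flags]")
    cmd <- args[[1]]
    rest <- args[-1]
    opts <- parse_cli_flags(rest)
    switch(cmd,
      "simulate" = {
        spec <- synthetic_spec(
          n_samples = as.integer(opts$`n-samples` %||% 850),
          seed = as.integer(opts$seed %||% 1))
        write_dataset(generate_dataset(spec), opts$out %||% "hrtcst_sim")
      },
      "call-csts" = , "report" = {
        cfg <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
        for (key in c("abundance", "metadata", "ec", "pathways", "out"))
          if (!is.null(opts[[key]])) cfg[[key]] <- opts[[key]]
        for (key in c("k", "k-min", "k-max", "min-datasets", "seed", "n-permutations"))
          if (!is.null(opts[[key]]))
            cfg[[gsub("-", "_", key)]] <- as.integer(opts[[key]])
        for (key in c("min-fraction", "core-prevalence", "highlight",
                      "abundance-cut", "presence-min-prevalence"))
          if (!is.null(opts[[key]]))
            cfg[[gsub("-", "_", key)]] <- as.numeric(opts[[key]])
        if (!is.null(opts$order))
          cfg$gradient_order <- strsplit(opts$order, ",")[[1]]
        run_pipeline(cfg)
      },
      "gradients" = {
        table <- load_abundance_table(opts$abundance)
        meta <- load_metadata(opts$metadata)
        al <- align_dataset(table, meta)
        ord <- strsplit(opts$order %||% "nasal,throat,lung", ",")[[1]]
        taxa <- if (!is.null(opts$taxon)) opts$taxon else colnames(al$table)
        rows <- lapply(taxa, function(t) {
          g <- detect_gradient(al$table, al$meta, t, ord,
                               seed = as.integer(opts$seed %||% 1))
          data.frame(taxon = t, direction = g$direction, monotone = g$monotone,
                     p_value = g$p_value,
                     t(stats::setNames(g$means, paste0("mean_", names(g$means)))))
        })
        out <- opts$out %||% "gradients.tsv"
        utils::write.table(do.call(rbind, rows), out, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      },
      "functional" = {
        meta <- load_metadata(opts$metadata)
        out <- opts$out %||% "hrtcst_functional"
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        if (!is.null(opts$ec)) {
          prof <- ec_class_profile(load_ec_table(opts$ec))
          utils::write.table(data.frame(sample_id = rownames(prof), unclass(prof),
                                        check.names = FALSE),
                             file.path(out, "ec_class_profile.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        if (!is.null(opts$pathways)) {
          up <- unique_pathways(load_pathway_table(opts$pathways), meta,
                                as.numeric(opts$`presence-min-prevalence` %||% 0.25))
          jsonlite::write_json(list(counts = as.list(up$counts)),
                               file.path(out, "unique_pathways.json"),
                               auto_unbox = TRUE, digits = NA)
        }
      },
      hrt_stop("hrt_parameter_error", "unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  if (exit) quit(status = status) else invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      hrt_stop("hrt_parameter_error", "expected --flag, got ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[[i + 1]]
      i <- i + 2
    }
  }
  opts
}
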