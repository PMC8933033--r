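test_that("generate_dataset is deterministic and respects table invariants", {
  spec <- synthetic_spec(n_samples = 120, seed = 7)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1, d2)

  expect_true(all(rowSums(d1$table) <= 1 + 1e-9))
  expect_true(all(unclass(d1$table) >= 0))
  expect_identical(rownames(d1$table), d1$meta$sample_id)
  expect_equal(unname(rowSums(ec_class_profile(d1$ec))),
               rep(1, nrow(d1$ec)))

  d3 <- generate_dataset(synthetic_spec(n_samples = 120, seed = 8))
  expect_false(identical(unclass(d1$table), unclass(d3$table)))
})

test_that("infeasible specs fail before sampling", {
  expect_error(
    synthetic_spec(n_samples = 10, seed = 1, cst_specs = list(
      cst_spec("X", "Staphylococcus aureus", 0.6,
               core = c("Rothia mucilaginosa" = 0.35)))),
    class = "hrt_feasibility_error")
})

test_that("planted within-CST prevalences are hit within 0.05", {
  spec <- synthetic_spec(n_samples = 850, seed = 13)
  ds <- generate_dataset(spec)
  x <- unclass(ds$table)
  for (cs in spec$cst_specs) {
    members <- names(ds$truth$cst)[ds$truth$cst == cs$label]
    if (length(members) < 50) next
    got <- colMeans(x[members, names(cs$means), drop = FALSE] > 0)
    expect_true(all(abs(got - cs$prevalence) <= 0.05),
                info = paste("prevalence off in", cs$label))
    # and the defining taxon sits near its planted dominant mean
    def <- cs$defining_taxon
    expect_equal(mean(x[members, def]), unname(cs$means[def]),
                 tolerance = 0.15)
  }
})

test_that("global CST shares follow the template marginals", {
  spec <- synthetic_spec(n_samples = 850, seed = 17)
  ds <- generate_dataset(spec)
  ref <- cst_reference_summary()
  target <- ref$prevalence_total / sum(ref$prevalence_total)
  got <- table(ds$truth$cst)[names(target)] / 850
  expect_true(all(abs(got - target) < 0.04))
  # nasal compartment is CST-Se enriched, mirroring the planted tilt
  W <- ds$truth$compartment_cst_weights
  expect_gt(W["nasal", "CST-Se"], 2 * target[["CST-Se"]])
})

test_that("the planted richness gap is recovered within 2 species", {
  spec <- synthetic_spec(n_samples = 500, seed = 41,
                         cst_disease_bias = NULL, diseased_fraction = 0.5)
  ds <- generate_dataset(spec)
  r <- richness(ds$table)
  gap <- mean(r[ds$truth$health_status == "healthy"]) -
    mean(r[ds$truth$health_status == "diseased"])
  expect_equal(gap, spec$richness_gap, tolerance = 2 / spec$richness_gap)
})

test_that("planted gradients pass detect_gradient in the planted direction", {
  spec <- synthetic_spec(n_samples = 300, seed = 43,
                         compartment_probs = c(nasal = 0.25, throat = 0.25,
                                               sputum = 0.25, lung = 0.25))
  ds <- generate_dataset(spec)
  for (taxon in names(spec$planted_taxa)) {
    means <- spec$planted_taxa[[taxon]]
    ord <- names(sort(means, decreasing = TRUE))
    g <- detect_gradient(ds$table, ds$meta, taxon, ord, seed = 3)
    expect_equal(g$direction, "decreasing")
    expect_lt(g$p_value, 0.05)
  }
})

test_that("a one-CST world is handled without structure being invented", {
  spec <- synthetic_spec(n_samples = 80, seed = 61,
                         cst_specs = list(
                           cst_spec("only", "Staphylococcus aureus", 0.4)),
                         compartment_cst_tilt = NULL, planted_taxa = NULL,
                         cst_disease_bias = NULL)
  ds <- generate_dataset(spec)
  d <- pearson_distance(ds$table)
  sel <- select_k(d, upgma_linkage(d), 2, 10)   # no crash on flat structure
  expect_length(sel$scores, 9)
  expect_true(all(is.finite(sel$scores)))
  # no cut approaches the separation of genuinely planted structure
  expect_lt(diff(range(sel$scores)), 0.35)
})

test_that("adjusted_rand_index: identity, null behavior, degenerate cases", {
  a <- rep(letters[1:13], length.out = 850)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, rep("z", 850)), 0)

  set.seed(99)
  aris <- replicate(20, adjusted_rand_index(sample(a), sample(a)))
  expect_true(all(abs(aris) < 0.05))   # chance-corrected around zero
})

test_that("truth_report scores a perfect catalog at ARI 1 and accuracy 1", {
  ds <- make_toy_dataset(n = 120, seed = 3)
  # build a catalog directly from the truth labels
  asg <- stats::setNames(as.integer(factor(ds$truth$cst)), names(ds$truth$cst))
  catalog <- call_csts(ds$table, ds$meta, asg)
  rep <- truth_report(ds$truth, catalog)
  expect_equal(rep$ari, 1)
  expect_equal(rep$defining_taxon_accuracy, 1)
  expect_equal(rep$prevalence_max_error, 0)

  bad <- ds$truth
  bad$cst <- bad$cst[-1]
  expect_error(truth_report(bad, catalog), class = "hrt_alignment_error")
})

test_that("datasets round-trip through write_dataset files", {
  ds <- make_toy_dataset(n = 60, seed = 51)
  dir <- tempfile()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- load_abundance_table(paths[["abundance"]])
  expect_equal(unclass(back), unclass(ds$table), tolerance = 1e-9)
  meta <- load_metadata(paths[["metadata"]])
  expect_equal(meta$compartment, ds$meta$compartment)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(unlist(truth$cst[ds$meta$sample_id[1]]),
               ds$truth$cst[ds$meta$sample_id[1]])
})
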