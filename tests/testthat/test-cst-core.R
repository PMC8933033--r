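test_that("pearson_distance matches hand-computed values and detects degeneracy", {
  x <- rbind(s1 = c(0.2, 0.3, 0.5), s2 = c(0.2, 0.3, 0.5) * 0.5 + 0.1,
             s3 = c(1, 0, 0), s4 = c(0, 1, 0))
  colnames(x) <- c("a", "b", "c")
  d <- pearson_distance(x)
  expect_equal(d["s1", "s2"], 0)          # affine-invariant
  expect_equal(d["s3", "s4"], 1.5)        # r = -0.5
  expect_true(all(d >= 0 & d <= 2))

  flat <- rbind(s1 = c(0.1, 0.1, 0.1), s2 = c(0.3, 0.2, 0.1))
  err <- tryCatch(pearson_distance(flat), error = identity)
  expect_s3_class(err, "hrt_degenerate_sample_error")
  expect_match(conditionMessage(err), "s1")
})

test_that("upgma_linkage reproduces the 3-point merge and ultrametric input exactly", {
  d <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- upgma_linkage(d)
  expect_equal(tr$height, c(0.1, 1))

  # ultrametric: heights reproduce the cophenetic distances exactly
  du <- matrix(0.8, 4, 4); du[1, 2] <- du[2, 1] <- 0.2
  du[3, 4] <- du[4, 3] <- 0.4; diag(du) <- 0
  dimnames(du) <- list(letters[1:4], letters[1:4])
  tru <- upgma_linkage(du)
  expect_equal(as.matrix(stats::cophenetic(tru$hclust))[letters[1:4], letters[1:4]],
               du)
})

test_that("upgma_linkage agrees with a brute-force agglomerator (100 random instances)", {
  for (seed in 1:100) {
    x <- random_profiles(sample(4:8, 1), 6, seed = seed)
    d <- pearson_distance(x)
    tr <- upgma_linkage(d)
    or <- oracle_upgma(d)
    expect_equal(tr$height, or$heights, tolerance = 1e-9)
    coph <- as.matrix(stats::cophenetic(tr$hclust))[rownames(d), rownames(d)]
    expect_equal(coph, or$cophenetic, ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("cut_dendrogram covers k = 1, k = n, and refines as k grows", {
  x <- random_profiles(9, 6, seed = 11)
  tr <- upgma_linkage(pearson_distance(x))
  expect_equal(unname(cut_dendrogram(tr, 1)), rep(1L, 9))
  expect_equal(sort(unname(cut_dendrogram(tr, 9))), 1:9)
  expect_error(cut_dendrogram(tr, 0), class = "hrt_parameter_error")
  expect_error(cut_dendrogram(tr, 10), class = "hrt_parameter_error")

  for (k in 2:8) {
    fine <- cut_dendrogram(tr, k + 1)
    coarse <- cut_dendrogram(tr, k)
    # each fine cluster sits inside exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }

  d3 <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  cl <- cut_dendrogram(upgma_linkage(d3), 2)
  expect_equal(cl[["x"]], cl[["y"]])
  expect_false(cl[["x"]] == cl[["z"]])
})

test_that("silhouette_mean handles clean, degenerate and singleton cases", {
  x <- rbind(a1 = c(1, 0, 0), a2 = c(0.9, 0.1, 0), b1 = c(0, 0, 1),
             b2 = c(0, 0.1, 0.9))
  d <- pearson_distance(x)
  cl <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  expect_gt(silhouette_mean(d, cl), 0.9)

  # all points identical: a = b = 0 convention gives s = 0
  d0 <- matrix(0, 4, 4, dimnames = list(names(cl), names(cl)))
  expect_equal(silhouette_mean(d0, cl), 0)
  expect_error(silhouette_mean(d, c(a1 = 1L, a2 = 1L, b1 = 1L, b2 = 1L)),
               class = "hrt_undefined_score_error")
})

test_that("silhouette_mean equals the double-loop oracle (100 random instances)", {
  for (seed in 1:100) {
    n <- sample(4:8, 1)
    x <- random_profiles(n, 5, seed = 1000 + seed)
    d <- pearson_distance(x)
    set.seed(seed)
    k <- sample(2:(n - 1), 1)
    cl <- sample(rep_len(seq_len(k), n))   # every label used at least once
    expect_equal(silhouette_mean(d, stats::setNames(cl, rownames(d))),
                 oracle_silhouette(d, cl), tolerance = 1e-12)
  }
})

test_that("select_k finds planted structure and breaks ties at the smallest k", {
  ds <- make_toy_dataset(n = 90, seed = 4)
  d <- pearson_distance(ds$table)
  tr <- upgma_linkage(d)
  sel <- select_k(d, tr, 2, 10)
  expect_equal(sel$k, 3)
  expect_equal(unname(sel$scores[names(sel$scores) == sel$k]), max(sel$scores))

  two <- cst_spec("X", "Staphylococcus aureus", 0.5)
  spec2 <- synthetic_spec(n_samples = 60, seed = 9,
                          cst_specs = list(two,
                            cst_spec("Y", "Neisseria subflava", 0.4)),
                          compartment_cst_tilt = NULL, planted_taxa = NULL,
                          cst_disease_bias = NULL)
  ds2 <- generate_dataset(spec2)
  d2 <- pearson_distance(ds2$table)
  expect_equal(select_k(d2, upgma_linkage(d2), 2, 10)$k, 2)
  expect_error(select_k(d2, upgma_linkage(d2), 5, 5),
               class = "hrt_parameter_error")
})

test_that("call_csts applies retention filters, putative rules and labeling", {
  ds <- make_toy_dataset(n = 150, seed = 6)
  d <- pearson_distance(ds$table)
  asg <- cut_dendrogram(upgma_linkage(d), 3)
  catalog <- call_csts(ds$table, ds$meta, asg)
  labs <- sort(vapply(catalog$csts, `[[`, character(1), "label"))
  expect_equal(labs, c("CST-Pa", "CST-Rm", "CST-Se"))
  expect_true(all(vapply(catalog$csts, `[[`, character(1), "status") == "cst"))

  # every sample is exactly once in a member set or unassigned
  members <- unlist(lapply(catalog$csts, `[[`, "member_samples"))
  expect_equal(sort(c(members, catalog$unassigned_samples)),
               sort(rownames(ds$table)))
  expect_equal(anyDuplicated(members), 0L)

  # defining taxon is a core taxon with maximal mean abundance
  for (def in catalog$csts) {
    expect_true(def$defining_taxon %in% def$core_taxa$taxon)
    expect_equal(def$core_taxa$mean_abundance[1],
                 max(def$core_taxa$mean_abundance))
  }
})

test_that("call_csts size filter matches the 1%-of-849 = 8 rule", {
  # min cluster size = max(2, round(min_fraction * n)); round(8.49) = 8
  ds <- make_toy_dataset(n = 100, seed = 12)
  asg <- cut_dendrogram(upgma_linkage(pearson_distance(ds$table)), 3)
  # shrink one cluster below threshold by raising min_fraction
  sizes <- table(asg)
  small <- names(sizes)[which.min(sizes)]
  frac <- (min(sizes) + 1) / 100
  catalog <- call_csts(ds$table, ds$meta, asg, min_fraction = frac)
  expect_equal(length(catalog$unassigned_samples), min(sizes))
  expect_equal(length(catalog$csts), 2)
  # the arithmetic of the published rule itself
  expect_equal(max(2, round(0.01 * 849)), 8)

  expect_error(call_csts(ds$table, ds$meta, asg, min_fraction = 0.99),
               class = "hrt_no_cst_error")
})

test_that("clusters from unresolved species or a single bioproject become putative", {
  spec <- synthetic_spec(n_samples = 200, seed = 3,
                         include_putative_clusters = TRUE)
  ds <- generate_dataset(spec)
  d <- pearson_distance(ds$table)
  asg <- cut_dendrogram(upgma_linkage(d), 15)
  catalog <- call_csts(ds$table, ds$meta, asg, min_datasets = 1)
  status <- stats::setNames(vapply(catalog$csts, `[[`, character(1), "status"),
                            vapply(catalog$csts, `[[`, character(1), "label"))
  expect_equal(unname(status[["Cluster-P"]]), "putative_excluded")
  expect_equal(unname(status[["Cluster-S"]]), "putative_excluded")
  # same clustering with the exclusion switched off: single-project cluster
  # whose taxon resolves is kept only when its defining taxon is resolved
  cat2 <- call_csts(ds$table, ds$meta, asg, min_datasets = 1,
                    single_project_exclude = FALSE)
  s2 <- stats::setNames(vapply(cat2$csts, `[[`, character(1), "status"),
                        vapply(cat2$csts, `[[`, character(1), "label"))
  expect_equal(unname(s2[["Cluster-P"]]), "putative_excluded")  # still unresolved
})

test_that("characterize_cst_from_summary reproduces worked examples", {
  ref <- cst_reference_summary()
  pj <- characterize_cst_from_summary(ref$avg["CST-Pj", ], ref$prev["CST-Pj", ])
  expect_equal(pj$defining_taxon, "Prevotella jejuni")
  expect_equal(pj$average_abundance, 9.11)

  ns <- characterize_cst_from_summary(ref$avg["CST-Ns", ], ref$prev["CST-Ns", ])
  expect_equal(ns$defining_taxon, "Neisseria subflava")
  expect_equal(ns$average_abundance, 9.26)

  none <- characterize_cst_from_summary(c(a = 10, b = 5), c(a = 50, b = 50))
  expect_true(is.na(none$defining_taxon))
  expect_error(characterize_cst_from_summary(c(a = 1), c(b = 1)),
               class = "hrt_validation_error")
})

test_that("assign_to_cst recovers members and centroids", {
  ds <- make_toy_dataset(n = 120, seed = 8)
  asg <- cut_dendrogram(upgma_linkage(pearson_distance(ds$table)), 3)
  catalog <- call_csts(ds$table, ds$meta, asg)

  # a member resubmitted lands in its own CST
  labels <- catalog_labels(catalog)
  hits <- vapply(sample(rownames(ds$table), 25), function(id)
    assign_to_cst(catalog, ds$table, id)$label == labels[[id]], logical(1))
  expect_true(all(hits))

  # a sample equal to a centroid matches with r = 1
  cen <- catalog$csts[[1]]$centroid
  x2 <- rbind(unclass(ds$table), centroid_sample = cen[colnames(ds$table)])
  res <- assign_to_cst(catalog, abundance_table(x2), "centroid_sample")
  expect_equal(res$label, catalog$csts[[1]]$label)
  expect_equal(res$similarity, 1)

  empty <- list(csts = list(), unassigned_samples = character(0))
  class(empty) <- "cst_catalog"
  expect_error(assign_to_cst(empty, ds$table, rownames(ds$table)[1]),
               class = "hrt_no_cst_error")
})

test_that("catalogs serialize to JSON/TSV and dendrograms to Newick", {
  ds <- make_toy_dataset(n = 90, seed = 10)
  tr <- upgma_linkage(pearson_distance(ds$table))
  catalog <- call_csts(ds$table, ds$meta, cut_dendrogram(tr, 3))
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  np <- tempfile(fileext = ".nwk")
  write_catalog(catalog, jp, tp)
  write_newick(tr, np)
  parsed <- jsonlite::read_json(jp)
  expect_equal(length(parsed$csts), 3)
  tsv <- utils::read.delim(tp)
  expect_equal(sort(tsv$sample_id), sort(rownames(ds$table)))
  tree <- ape::read.tree(np)
  expect_equal(sort(tree$tip.label), sort(rownames(ds$table)))
})
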