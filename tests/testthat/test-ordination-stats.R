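test_that("bray_curtis matches hand computations and the double-loop oracle", {
  x <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0, 0.5), s3 = c(0.5, 0.5, 0),
             s4 = c(0, 0, 0))
  d <- bray_curtis(x)
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s4", "s4"], 0)              # all-zero pair convention
  y <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(y)["a", "b"], 1)   # disjoint supports
  expect_error(bray_curtis(rbind(c(-0.1, 0.2), c(0, 0.1))),
               class = "hrt_validation_error")

  for (seed in 1:50) {
    z <- random_profiles(sample(3:8, 1), 5, seed = 300 + seed)
    expect_equal(bray_curtis(z), oracle_bray_curtis(z), tolerance = 1e-12)
  }
})

test_that("pcoa is exact on Euclidean input and reports the spectrum honestly", {
  set.seed(1)
  pts <- cbind(runif(7), runif(7))
  rownames(pts) <- paste0("s", 1:7)
  d <- as.matrix(stats::dist(pts))
  ord <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(stats::dist(ord$coordinates)), d,
               ignore_attr = TRUE, tolerance = 1e-9)

  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(o2 <- pcoa(d2, n_axes = 1), NA)
  expect_equal(sort(o2$coordinates[, 1]), c(-0.5, 0.5), ignore_attr = TRUE)

  # eigenvalue sum equals the trace of the centered Gower matrix
  x <- random_profiles(6, 5, seed = 77)
  db <- bray_curtis(x)
  ord3 <- pcoa(db, n_axes = 3)
  A <- -0.5 * db^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  expect_equal(sum(ord3$eigenvalues), sum(diag(G)), tolerance = 1e-9)
  expect_true(any(ord3$eigenvalues < 0))      # Bray-Curtis is non-Euclidean
  expect_true(all(diff(ord3$eigenvalues) <= 1e-12))
})

test_that("pcoa agrees with classical-scaling oracle on random instances", {
  for (seed in 1:30) {
    x <- random_profiles(sample(4:8, 1), 6, seed = 500 + seed)
    d <- bray_curtis(x)
    ord <- pcoa(d, n_axes = 2)
    cs <- suppressWarnings(stats::cmdscale(d, k = 2, eig = TRUE))
    expect_equal(abs(ord$coordinates), abs(cs$points),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(ord$eigenvalues[1:2], cs$eig[1:2], tolerance = 1e-8)
  }
})

test_that("permanova separates planted groups and is invariant to reordering/relabeling", {
  ds <- make_toy_dataset(n = 60, seed = 21)
  d <- bray_curtis(ds$table)
  g <- ds$truth$cst
  r1 <- permanova(d, g, n_permutations = 199, seed = 5)
  expect_equal(r1$p_value, 1 / 200)           # all permuted F below observed
  expect_gt(r1$pseudo_F, 1)

  idx <- sample(nrow(d))
  r2 <- permanova(d[idx, idx], g[idx], n_permutations = 199, seed = 5)
  expect_equal(r2$pseudo_F, r1$pseudo_F, tolerance = 1e-12)
  g2 <- stats::setNames(paste0("grp_", g), names(g))
  r3 <- permanova(d, g2, n_permutations = 199, seed = 5)
  expect_equal(r3$p_value, r1$p_value)

  expect_error(permanova(d, stats::setNames(c("a", rep("b", 59)), names(g))),
               class = "hrt_group_size_error")

  # identical coordinates: F indistinguishable from its permutation null
  d0 <- matrix(0, 12, 12, dimnames = list(paste0("s", 1:12), paste0("s", 1:12)))
  r0 <- permanova(d0, rep(c("x", "y"), 6), n_permutations = 99, seed = 1)
  expect_gt(r0$p_value, 0.05)
})

test_that("richness counts taxa above a threshold", {
  x <- rbind(s1 = c(0.2, 0, 0.8 * 0.99))       # keep row sum < 1
  expect_equal(unname(richness(x)), 2L)
  expect_equal(unname(richness(x, threshold = 0.25)), 1L)
  expect_error(richness(x, threshold = -1), class = "hrt_parameter_error")
})

test_that("two_group_test: Mann-Whitney U and degenerate cases", {
  r <- two_group_test(c(1, 2, 3), c(11, 12, 13), method = "mann_whitney")
  expect_equal(r$statistic, 0)                 # all pairs favor group b
  same <- two_group_test(c(1, 2, 3, 4), c(4, 3, 2, 1), method = "mann_whitney")
  expect_gte(same$p_value, 0.99)
  expect_error(two_group_test(c(1, 1, 1), c(1, 1, 1), method = "t_test"),
               class = "hrt_undefined_statistic_error")
  welch <- two_group_test(rnorm(10), rnorm(10) + 5, method = "t_test")
  expect_lt(welch$p_value, 1e-4)
  expect_error(two_group_test(1, c(1, 2)), class = "hrt_group_size_error")
})

test_that("anova_tukey matches the brute-force q computation and handles degeneracy", {
  for (seed in 1:40) {
    set.seed(700 + seed)
    g <- rep(c("a", "b", "c"), times = sample(3:6, 3, replace = TRUE))
    v <- rnorm(length(g)) + c(a = 0, b = 0.5, c = 2)[g]
    res <- anova_tukey(v, g)
    got <- with(res$pairwise, sort(paste(group_a, group_b)[significant]))
    expect_equal(got, sort(oracle_tukey_pairs(v, g)))
  }

  const <- anova_tukey(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(const$anova$p_value, 1)
  expect_false(any(const$pairwise$significant))
  expect_error(anova_tukey(rnorm(8), rep(c("a", "b"), 4)),
               class = "hrt_group_size_error")

  # planted one-group shift: only pairs with that group significant
  set.seed(2)
  g4 <- rep(c("a", "b", "c", "d"), each = 12)
  v4 <- rnorm(48, sd = 0.5) + ifelse(g4 == "d", 3, 0)
  pw <- anova_tukey(v4, g4)$pairwise
  expect_true(all(pw$significant == (pw$group_a == "d" | pw$group_b == "d")))
})

test_that("bh_fdr reproduces hand-derived adjustments and dominates Bonferroni", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "hrt_validation_error")

  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(25)^2
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    bonf <- pmin(p * length(p), 1)
    expect_true(all(q[bonf < 0.05] < 0.05))    # BH rejects a superset
  }
})

test_that("associate_features reduces to the pooled t-test for one 2-level covariate", {
  set.seed(31)
  x <- matrix(runif(40, 0, 0.5), 20, 2,
              dimnames = list(paste0("s", 1:20), c("f1", "f2")))
  cov <- data.frame(group = rep(c("u", "v"), each = 10),
                    row.names = rownames(x))
  res <- associate_features(x, cov)
  for (f in c("f1", "f2")) {
    y <- asin(sqrt(x[, f]))
    tt <- stats::t.test(y[1:10], y[11:20], var.equal = TRUE)
    expect_equal(res$p[res$feature == f], tt$p.value, tolerance = 1e-9)
  }

  # feature driven by one level has the smallest q in the table
  x2 <- cbind(x, driven = ifelse(cov$group == "v", 0.6, 0.1))
  res2 <- associate_features(x2, cov)
  expect_equal(res2$feature[which.min(res2$q)], "driven")

  cov_bad <- data.frame(a = rep(c("u", "v"), each = 10),
                        b = rep(c("x", "y"), each = 10),
                        row.names = rownames(x))
  err <- tryCatch(associate_features(x, cov_bad), error = identity)
  expect_s3_class(err, "hrt_rank_deficiency_error")
  expect_match(conditionMessage(err), "a, b")
})
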