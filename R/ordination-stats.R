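# Beta-diversity ordination and the statistical battery: Bray-Curtis, PCoA,
# PERMANOVA, richness, two-group tests, one-way ANOVA with Tukey HSD, BH-FDR,
# and a simple per-feature association model for proportions.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)`, in `[0, 1]`. A pair of
#' all-zero samples is at distance 0 by convention.
#'
#' @param table samples x features matrix of non-negative abundances.
#' @return symmetric distance matrix.
#' @export
bray_curtis <- function(table) {
  x <- unclass(table)
  if (any(x < 0))
    hrt_stop("hrt_validation_error", "Bray-Curtis requires non-negative abundances")
  n <- nrow(x)
  rs <- rowSums(x)
  # sum |xi - xj| = si + sj - 2 * sum pmin(xi, xj); compute pmin sums pairwise
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    rest <- (i + 1):n
    mins <- colSums(pmin(t(x[rest, , drop = FALSE]), xi))
    tot <- rs[i] + rs[rest]
    dij <- ifelse(tot == 0, 0, (tot - 2 * mins) / tot)
    d[i, rest] <- d[rest, i] <- dij
  }
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns coordinates for
#' the top `n_axes` positive-eigenvalue axes scaled by `sqrt(eigenvalue)`.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but not corrected; `correction = "cailliez"`
#' adds the constant that makes the system Euclidean.
#'
#' @param dist symmetric distance matrix.
#' @param n_axes number of axes to keep (truncated with a warning when fewer
#'   positive eigenvalues exist).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return list of class `hrt_ordination`: `ids`, `coordinates` (n x m),
#'   `eigenvalues` (all n, descending), `proportion_explained` (over the
#'   positive part of the spectrum).
#' @export
pcoa <- function(dist, n_axes = 3, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  validate_distance_matrix(dist)
  n <- nrow(dist)
  if (n_axes > n - 1)
    hrt_stop("hrt_parameter_error", "n_axes must be <= n - 1")
  if (correction == "cailliez") {
    # smallest constant c such that d + c (off-diagonal) is Euclidean
    c0 <- ape_cailliez_constant(dist)
    dist <- dist + c0
    diag(dist) <- 0
  }
  A <- -0.5 * dist^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  vals <- e$values
  pos <- which(vals > 1e-9 * max(abs(vals)))
  m <- min(n_axes, length(pos))
  if (m < n_axes)
    hrt_warn("only ", length(pos), " positive eigenvalues; returning ", m, " axes")
  coords <- e$vectors[, pos[seq_len(m)], drop = FALSE] %*%
    diag(sqrt(vals[pos[seq_len(m)]]), m)
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("axis", seq_len(m))
  structure(list(ids = rownames(dist), coordinates = coords,
                 eigenvalues = vals,
                 proportion_explained = pmax(vals, 0) / sum(pmax(vals, 0))),
            class = "hrt_ordination")
}

# Cailliez (1983) constant: largest real eigenvalue of the companion system.
ape_cailliez_constant <- function(d) {
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  F1 <- -0.5 * J %*% (d^2) %*% J
  F2 <- -0.5 * J %*% d %*% J
  B <- rbind(cbind(matrix(0, n, n), 2 * F1),
             cbind(-diag(n), -4 * F2))
  max(Re(eigen(B, only.values = TRUE)$values))
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's pseudo-F computed directly from the distances:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `F = (SS_between / (a - 1)) / (SS_within / (n - a))`.
#' The p-value is `(b + 1) / (m + 1)` where `b` counts label permutations
#' with `F >= F_observed`, so the smallest attainable p is
#' `1 / (n_permutations + 1)`.
#'
#' @param dist symmetric distance matrix.
#' @param groups factor-like vector of group labels, aligned to `dist` rows
#'   (or named by sample id).
#' @param n_permutations number of label permutations, default 1000.
#' @param seed RNG seed for the permutations (mandatory for reproducibility).
#' @return list of class `hrt_permanova`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `df`.
#' @export
permanova <- function(dist, groups, n_permutations = 1000, seed = 1) {
  validate_distance_matrix(dist)
  n <- nrow(dist)
  if (!is.null(names(groups)) && !is.null(rownames(dist)))
    groups <- groups[rownames(dist)]
  g <- as.factor(groups)
  if (nlevels(g) < 2)
    hrt_stop("hrt_group_size_error", "need at least 2 groups")
  if (any(table(g) < 2))
    hrt_stop("hrt_group_size_error", "every group needs at least 2 members")
  d2 <- dist^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  a <- nlevels(g)
  f_stat <- function(idx) {
    ss_within <- 0
    for (lev in levels(g)) {
      sel <- idx[g == lev]
      sub <- d2[sel, sel]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(sel)
    }
    if (ss_within == 0)
      return(if (ss_total == 0) 0 else Inf)   # degenerate: no within-spread
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  obs <- f_stat(seq_len(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(i) f_stat(sample.int(n)), numeric(1))
  structure(list(pseudo_F = obs,
                 p_value = (sum(perm >= obs) + 1) / (n_permutations + 1),
                 n_permutations = n_permutations, seed = seed,
                 df = c(between = a - 1, within = n - a)),
            class = "hrt_permanova")
}

#' @export
print.hrt_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_permutations))
  invisible(x)
}

#' Species richness per sample
#'
#' @param table samples x taxa abundance matrix.
#' @param threshold abundance a taxon must exceed to count, default 0.
#' @return named integer vector of per-sample counts.
#' @export
richness <- function(table, threshold = 0) {
  if (threshold < 0)
    hrt_stop("hrt_parameter_error", "threshold must be >= 0")
  counts <- rowSums(unclass(table) > threshold)
  storage.mode(counts) <- "integer"
  counts
}

#' Two-group difference test
#'
#' Welch's t-test (unequal variances) or the two-sided Mann-Whitney U test
#' (normal approximation with tie correction), both as implemented in stats.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @return list of class `hrt_test`: `statistic`, `p_value`, `method`,
#'   `estimates` (group means for t, medians for Mann-Whitney).
#' @export
two_group_test <- function(values_a, values_b,
                           method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  if (length(values_a) < 2 || length(values_b) < 2)
    hrt_stop("hrt_group_size_error", "each group needs at least 2 values")
  if (method == "t_test") {
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
        stats::sd(c(values_a, values_b)) == 0)
      hrt_stop("hrt_undefined_statistic_error",
               "t statistic undefined: both groups constant and identical")
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
    est <- c(mean_a = mean(values_a), mean_b = mean(values_b))
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE))
    est <- c(median_a = stats::median(values_a), median_b = stats::median(values_b))
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = method, estimates = est),
            class = "hrt_test")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fits a one-way ANOVA (>= 3 groups, each with >= 2 members) and runs Tukey's
#' honestly-significant-difference test on all group pairs, with the
#' Tukey-Kramer adjustment for unequal group sizes. When all observations are
#' identical the F statistic is undefined; this degenerate case is reported
#' as `p = 1` with every pairwise comparison non-significant.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param alpha significance level used for the `significant` flag.
#' @return list: `anova` (an `hrt_test` with the F statistic) and `pairwise`
#'   (data.frame: group_a, group_b, diff, p_adj, significant).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  g <- as.factor(groups)
  if (nlevels(g) < 3)
    hrt_stop("hrt_group_size_error",
             "need >= 3 groups; use two_group_test() for two groups")
  if (any(table(g) < 2))
    hrt_stop("hrt_group_size_error", "every group needs at least 2 members")
  pairs <- t(utils::combn(levels(g), 2))
  if (stats::sd(values) == 0) {
    pw <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                     diff = 0, p_adj = 1, significant = FALSE)
    return(list(anova = structure(list(statistic = 0, p_value = 1,
                                       method = "anova_F",
                                       estimates = tapply(values, g, mean)),
                                  class = "hrt_test"),
                pairwise = pw))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  key <- paste(pairs[, 2], pairs[, 1], sep = "-")  # TukeyHSD orders b-a
  pw <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                   diff = -tk[key, "diff"],
                   p_adj = tk[key, "p adj"],
                   significant = tk[key, "p adj"] < alpha,
                   row.names = NULL)
  list(anova = structure(list(statistic = an$`F value`[1],
                              p_value = an$`Pr(>F)`[1], method = "anova_F",
                              estimates = tapply(values, g, mean)),
                         class = "hrt_test"),
       pairwise = pw)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, order-preserving.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    hrt_stop("hrt_validation_error", "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-feature association with categorical covariates
#'
#' For each feature, fits a least-squares linear model of the
#' arcsin-sqrt-transformed abundance on dummy-coded covariates and reports the
#' Wald p-value of every non-intercept coefficient, with BH-FDR across the
#' whole result table. This is deliberately simple plumbing for screening
#' associations (one fixed-effects model per feature), not a reimplementation
#' of any published multivariate framework.
#'
#' @param table samples x features matrix of proportions in `[0, 1]`.
#' @param covariates data.frame of categorical covariates (rownames or a
#'   `sample_id` column aligned to the table).
#' @return data.frame: feature, covariate, level, coef, p, q.
#' @export
associate_features <- function(table, covariates) {
  x <- unclass(table)
  if (!is.null(covariates$sample_id)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  covariates <- covariates[rownames(x), , drop = FALSE]
  covariates[] <- lapply(covariates, as.factor)
  if (any(vapply(covariates, nlevels, integer(1)) < 2))
    hrt_stop("hrt_validation_error", "every covariate needs >= 2 levels")
  mm <- stats::model.matrix(~ ., data = covariates)
  if (qr(mm)$rank < ncol(mm)) {
    # name the covariate pairs that alias each other
    hrt_stop("hrt_rank_deficiency_error",
             "collinear covariates (design matrix is rank-deficient): ",
             paste(names(covariates), collapse = ", "))
  }
  y_all <- asin(sqrt(pmin(pmax(x, 0), 1)))
  rows <- vector("list", ncol(x))
  # decode "covNAMElevel" coefficient names into (covariate, level)
  coef_names <- colnames(mm)[-1]
  cov_of <- level_of <- character(length(coef_names))
  for (v in names(covariates)) {
    hit <- startsWith(coef_names, v)
    cov_of[hit] <- v
    level_of[hit] <- substring(coef_names[hit], nchar(v) + 1)
  }
  for (j in seq_len(ncol(x))) {
    fit <- stats::lm.fit(mm, y_all[, j])
    rss <- sum(fit$residuals^2)
    df <- nrow(mm) - fit$rank
    sigma2 <- rss / df
    xtx_inv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    se <- sqrt(diag(xtx_inv) * sigma2)
    tval <- fit$coefficients / se
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    rows[[j]] <- data.frame(feature = colnames(x)[j], covariate = cov_of,
                            level = level_of,
                            coef = unname(fit$coefficients[-1]),
                            p = unname(p[-1]))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}
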