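# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. Deliberately naive: different
# algorithms, plain double loops, no shared code with R/.

oracle_bray_curtis <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- sum(x[i, ] + x[j, ])
    d[i, j] <- if (tot == 0) 0 else sum(abs(x[i, ] - x[j, ])) / tot
  }
  d
}

oracle_silhouette <- function(d, cl) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(cl == cl[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- Inf
    for (g in setdiff(unique(cl), cl[i]))
      b <- min(b, mean(d[i, cl == g]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# naive UPGMA agglomerator that recomputes every inter-cluster mean from the
# original leaf distances at each step; returns merge heights and the
# cophenetic matrix (height at which each pair first co-clusters)
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# Tukey-Kramer significant pairs from first principles: q statistic against
# the studentized-range distribution
oracle_tukey_pairs <- function(values, groups, alpha = 0.05) {
  g <- as.factor(groups)
  k <- nlevels(g)
  ns <- tabulate(g)
  means <- tapply(values, g, mean)
  df <- length(values) - k
  mse <- sum((values - means[g])^2) / df
  sig <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    p <- stats::ptukey(q, k, df, lower.tail = FALSE)
    if (p < alpha) sig <- c(sig, paste(levels(g)[i], levels(g)[j]))
  }
  sig
}

# random abundance-like matrix for property tests
random_profiles <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(stats::rexp(n * p), n, p)
  x <- x / rowSums(x) * stats::runif(n, 0.5, 0.95)
  dimnames(x) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(p)))
  x
}

# small ready-made dataset for calling tests: 3 planted clusters
make_toy_dataset <- function(n = 120, seed = 42) {
  spec <- synthetic_spec(
    n_samples = n, seed = seed,
    cst_specs = list(
      cst_spec("A", "Staphylococcus epidermidis", 0.45, weight = 1),
      cst_spec("B", "Rothia mucilaginosa", 0.35,
               core = c("Streptococcus mitis" = 0.08), weight = 1),
      cst_spec("C", "Pseudomonas aeruginosa", 0.5, weight = 1)),
    compartment_cst_tilt = NULL, planted_taxa = NULL,
    cst_disease_bias = NULL)
  generate_dataset(spec)
}
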