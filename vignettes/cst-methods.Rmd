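---
title: "Community state typing of respiratory-tract microbiome profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community state typing of respiratory-tract microbiome profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrtcst)
```

## The problem

Shotgun-metagenomic surveys of the human respiratory tract (HRT) produce
species-level relative-abundance profiles for samples collected by very
different methods — nasal lavage, nasopharynx/oropharynx/cough swabs,
sputum, lung lavage, biopsies. Large meta-analyses of such profiles
recur to *community state types* (CSTs): recurrent community configurations,
each named after the high-prevalence species that dominates it. `hrtcst`
implements that analysis as a reusable, tested pipeline: CST calling from an
abundance table, compartment-level prevalence and gradient reports,
beta-diversity and richness statistics, and Enzyme Commission (EC) class
functional comparisons, together with a synthetic-data generator that makes
every stage testable offline.

## The CST-calling model

The procedure operates on a samples × species matrix $X$ of relative
abundances (fractions of classified reads; row sums may be below 1, the
residual being reads unclassified at species level).

1. **Distance.** $d(i,j) = 1 - r(i,j)$, with $r$ the Pearson correlation of
   the two samples' abundance vectors, so $d \in [0, 2]$. Correlation is
   computed on raw abundances; per-taxon standardization is a documented
   open alternative, but raw abundances preserve the field's convention that
   a CST is defined by its dominant species.
2. **Clustering.** Agglomerative hierarchical clustering with average
   linkage (UPGMA). The upstream method description names only the software
   and the metric; UPGMA is the common default for abundance-profile
   clustering, is monotone (no height inversions), and is exact on
   ultrametric inputs. Complete linkage and Ward-on-distances are exposed
   as options.
3. **Choice of k.** The dendrogram is cut at every $k$ in a search range
   (default 2–20) and scored by the mean silhouette width on the same
   Pearson distance; the argmax wins, ties going to the smallest $k$.
   Samples in singleton clusters score 0, as does the fully degenerate
   $a=b=0$ case.
4. **Retention filters.** Clusters smaller than
   $\max(2, \mathrm{round}(f \cdot n))$ samples (default $f = 1\%$; with
   $n = 849$ this reproduces the published cut-off of eight samples via R's
   round-half-to-even) or drawn from fewer than two bioprojects are
   dissolved; their samples are reported as unassigned.
5. **Characterization.** Within a retained cluster, a taxon's prevalence is
   the fraction of member samples where it exceeds a presence threshold
   (default: any non-zero abundance). Taxa with prevalence $> 85\%$ form
   the core; the core taxon with the highest mean abundance is the
   *defining taxon* and names the CST ("CST-" plus genus/species initials).
   Ties break alphabetically, for determinism.
6. **Putative exclusion.** Clusters whose defining taxon is not resolved at
   species level (names containing " sp." or "unclassified") are flagged
   `putative_excluded` and labeled `Cluster-<genus initial>`; optionally
   the same happens to clusters drawn from a single bioproject. Putative
   clusters stay in the catalog with their members — they are excluded from
   CST status, not from bookkeeping. Note that with the default
   `min_datasets = 2` a strictly single-project cluster is already
   dissolved by the retention filter; the `single_project_exclude` flag
   matters when that filter is relaxed.

`characterize_cst_from_summary()` applies step 5 directly to printed
summary rows (percent averages and prevalences), which lets published
tables serve as machine-checked worked examples.

## Statistics

* **Bray–Curtis** $d(i,j) = \sum_t |x_{it} - x_{jt}| / \sum_t (x_{it} + x_{jt})$,
  with $d = 0$ for a pair of all-zero samples.
* **PCoA** is classical scaling: double-center $-\tfrac12 D^2$,
  eigendecompose, scale eigenvectors by $\sqrt{\lambda}$. Negative
  eigenvalues (Bray–Curtis is non-Euclidean) are reported, not silently
  corrected; a Cailliez correction is available as an option.
* **PERMANOVA** uses Anderson's pseudo-F computed directly from the
  distance matrix, with label permutations and the
  $(b + 1)/(m + 1)$ p-value convention, so $p = 0$ is unattainable and the
  smallest achievable p is $1/(m+1)$. A fully degenerate all-zero distance
  matrix is reported as $F = 0$, $p = 1$.
* **Two-group tests** default to the Mann–Whitney U test (normal
  approximation with tie correction); the t-test variant is Welch's, since
  equal variances are not assumable across sampling methods.
* **ANOVA + Tukey HSD** uses the studentized-range distribution with the
  Tukey–Kramer unequal-n adjustment. All-constant input is reported as
  $p = 1$ with no significant pairs rather than an error.
* **FDR** is Benjamini–Hochberg step-up.
* **`associate_features()`** fits, per feature, a least-squares linear model
  of the arcsin-square-root-transformed abundance on dummy-coded
  categorical covariates, with Wald p-values and BH-FDR across the whole
  table. This is a deliberately simple screening model — a stand-in for
  published multivariate frameworks (fixed effects only, no
  normalization/prevalence filters), not a reimplementation of any of them.
  With one two-level covariate its p-value is algebraically the pooled
  two-sample t-test on transformed values.
* **Gradients.** Published compartment gradients are descriptive; to make
  "gradient" falsifiable, `detect_gradient()` adds a Jonckheere–Terpstra
  trend statistic evaluated by seeded permutation (two-sided), and reports
  strict monotonicity of the group means separately. With two groups the
  statistic reduces to the Mann–Whitney U count.

## The synthetic world

`synthetic_spec()` states one fixed world patterned on the published
meta-analysis; its defaults are the package's test bed.

* **CST templates.** The packaged reference summary (13 CSTs × 13 species,
  percent means and prevalences, global shares 11%…1%) drives the plants:
  each member sample draws abundances from a Dirichlet whose mean vector
  holds the template means, a uniform background over 40 accessory species
  (total mass 0.20 — the largest value for which the heaviest template row,
  70% planted mass, stays feasible), and an unclassified residual.
* **Concentration.** The Dirichlet total concentration is anchored so each
  background species has concentration 0.8; values below 1 give the sparse,
  dropout-rich accessory profiles of real data, and the implied total
  ($0.8 \times 40 / 0.20 = 160$) gives the defining species a realistic
  ~25% coefficient of variation. (A looser reading — total concentration
  proportional to the taxon count — yields profiles so noisy that planted
  13-CST structure is unrecoverable by any clustering of Pearson profiles;
  the anchoring above is the reading consistent with the generator's stated
  recovery property.)
* **Prevalence plants are exact.** For each planted taxon a fixed number of
  members, $\mathrm{round}((1-p) \cdot n_c)$, is zeroed at random, so
  within-CST prevalences land within $1/(2 n_c)$ of target; background
  species drop out i.i.d. with probability 0.5 (accessory prevalences in
  the realistic 30–70% band).
* **Compartments.** Four compartments (nasal 10%, throat 42%, sputum 26%,
  lung 22% — the approximate mix of the published sample inventory).
  Compartment–CST association is specified as enrichment multipliers on the
  joint distribution (nasal×CST-Se 8, throat×Pj/Rm/Sm 3/2/2,
  lung×Sa/Pa/Tj 3/3/3) followed by iterative proportional fitting, so the
  published global CST shares and the compartment mix are both preserved
  exactly in expectation. Bioprojects come from disjoint per-compartment
  pools with skewed weights, giving the mild compartment–study confounding
  the retention filter needs to be exercised.
* **Disease.** Five CSTs are diseased-biased (95%) and one healthy-biased
  (7% diseased), mirroring the published associations; diseased samples
  additionally lose `richness_gap = 14` background species. The published
  account is internally inconsistent about the *direction* of the richness
  difference (the text says diseased communities are simpler while the
  printed numbers read the other way); the generator follows the text, and
  no test asserts the direction.
* **Gradients, EC classes, pathways.** Two gradient species are overlaid
  with per-compartment means (decreasing from nasal; sputum-peaked).
  EC class profiles are drawn log-normally around per-compartment 7-class
  means with oxidoreductases at 19.60% ± 1.62% (nasal) and 17.43% ± 3.65%
  (lung); remaining class spreads default to 8% relative. Pathway tables
  plant 150 shared pathways (90% per-sample detection everywhere) and
  86/101/237/95 compartment-private pathways (80% detection in the home
  compartment, absent elsewhere), so the 25%-prevalence presence rule
  recovers the counts exactly.

**What a green test does and does not establish.** The generator produces
i.i.d. samples from clean parametric families: no sequencing error, no host
contamination, no compositional read-depth artifacts, no batch effects
beyond the planted bioproject pools, and cluster shapes that are
Dirichlet-round rather than real-data ragged. Recovery results (ARI ≥ 0.9
etc.) therefore validate the pipeline's logic, not its behavior on
arbitrary public data.

## Numerical choices and edge cases

* Percent-vs-fraction autodetection triggers when any abundance exceeds
  1.5, with an explicit `percent` override.
* Missing cells are rejected, not imputed — relative-abundance tables are
  complete by construction.
* Distance matrices must be symmetric to 1e-12; Pearson distances are
  clamped at 0 against floating-point `r > 1`.
* `cut_dendrogram` ties at the cut height break by merge order (later
  merges removed first).
* The defining-taxon argmax breaks ties alphabetically. One template row
  (CST-Pj) has a near-tie — 9.11% vs 8.95% for its top two core taxa — so
  on synthetic replicates the called defining taxon of that CST can flip;
  the end-to-end tests budget one miss out of 13 for exactly this reason.
* `truth_report()` counts unassigned samples as their own singleton
  classes in the ARI, penalizing over-aggressive filtering.
* All permutation procedures take explicit seeds; the pipeline derives
  per-stage seeds from the user seed (kept below $2^{31}$).

## Known limitations

* The catalog reflects one clustering; no consensus/bootstrap stability
  assessment is provided.
* `associate_features()` is a screening tool, not a replacement for a full
  multivariate association framework.
* The CLI targets TSV/JSON/Newick; BIOM and read-level formats are out of
  scope.
* Re-deriving the published catalog from the original public accessions is
  explicitly out of scope; the package mirrors the procedure, with the
  printed summary table serving as the worked-example anchor.
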