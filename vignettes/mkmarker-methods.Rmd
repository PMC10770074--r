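---
title: "Methods: multi-cohort multi-kingdom microbiome biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort multi-kingdom microbiome biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mkmarker implements a stratified, multi-cohort workflow for discovering and
validating gut-microbiome biomarkers of colorectal cancer (CRC) from
multi-kingdom shotgun-metagenomic relative-abundance profiles. The intended
setting is a body-weight-stratified case/control design: subjects with
excess body weight (EBW, BMI ≥ 25 kg/m²) and lean subjects (BMI < 25) are
analyzed as separate arms, each with its own discovery cohorts, marker
panel, and validation cohorts. This vignette describes the statistical
procedures, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Input model

The central container, `abundance_profile`, holds a feature-by-sample
matrix of relative abundances (fractions; every sample sums to at most 1),
per-feature kingdom labels (bacteria, fungi, archaea, viruses; absent for
functional tables), and per-sample metadata (cohort, CRC/CTR status,
body-weight stratum, age, BMI, gender). The stratum is defined by BMI:
EBW if and only if BMI ≥ 25 kg/m², and the constructor enforces this
consistency. Compositionality is a modelling fact, not an inconvenience:
several stages below (the arcsine-square-root transform, SparCC) exist
precisely because the data are closed.

## Feature filtering

`filter_features()` applies three rules sequentially, each to the
survivors of the previous one:

1. keep features whose *per-cohort mean* relative abundance reaches
   `max_cohort_mean_min` (default 1e-5, i.e. 0.001%) in at least
   `min_cohorts_passing` (default 2) cohorts;
2. keep features with *overall mean* abundance of at least
   `overall_mean_min` (default 1e-4, i.e. 0.01%);
3. keep features with *prevalence* (fraction of samples with non-zero
   abundance) of at least `prevalence_min` (default 20%).

Thresholds are stored as fractions, never percentages, to keep the
arithmetic unambiguous. Rule 1 is read as "pass in at least two cohorts":
the exclusion of features that do not exceed the floor in at least two
studies is the complement of that condition. Prevalence is computed over
the pooled analysis set of the stratum being analyzed, because one filter
is applied per arm before cross-cohort analysis; applying the filter per
cohort instead is possible by subsetting first. Filtering never
renormalizes the retained abundances — downstream modelling must see the
original fractions.

## Covariate screening and batch designation

`select_covariates()` runs a marginal (one-variable-at-a-time) PERMANOVA
of each demographic variable on Bray–Curtis distances (999 permutations by
default). The cohort is always designated the batch variable — in
multi-study data it is reliably the dominant source of variation — and any
other candidate (gender, age, BMI) with permutation p < 0.05 becomes a
model covariate. Marginal rather than sequential tests are used because
the question is each variable's individual impact, not a joint model.
PERMANOVA p-values carry the +1 correction, so the smallest attainable p
is 1/(permutations+1).

## Batch-aware differential abundance

`differential_features()` fits, within each cohort separately, a linear
model of the arcsine-square-root-transformed relative abundance on the
CRC indicator plus the selected covariates. The arcsine-square-root
transform is the standard variance-stabilizer for proportions in
microbiome meta-analysis. Fitting per cohort and never pooling samples
across cohorts is the batch handling: cohort-specific intercepts (and
noise levels) can differ freely. Per-cohort estimates are combined by
fixed-effect inverse-variance pooling — weights 1/se², pooled standard
error (Σw)^(-1/2), two-sided normal p — which is deterministic and closed
form. A DerSimonian–Laird random-effects alternative (with I² reported) is
available via `method = "random"` for settings with visible heterogeneity;
fixed effects remain the default because no heterogeneity model is assumed
by the rest of the workflow. No ComBat-style location/scale correction is
applied before fitting: the per-cohort stratification already absorbs
location shifts, and rescaling fractions would break compositional
interpretation.

Features constant within every cohort are reported *untestable* (NA
p-value) rather than given p = 1; a feature constant in only some cohorts
simply loses those cohorts. Significance uses the dual threshold
p < 0.05 **and** BH-adjusted q < 0.1. Benjamini–Hochberg adjustment is the
step-up procedure (`stats::p.adjust`), and the test-suite checks it
against a brute-force implementation of the definition.

`overlap_summary()` expresses the agreement of the two arms' differential
sets as percentages of the union, the convention used in Venn-style
reporting of shared and stratum-specific species.

## Three-step marker selection

`select_markers()` chains:

1. **Effective-feature screening.** Each differential feature is scored by
   the orientation-free (max(a, 1−a)) stratified 5-fold cross-validated
   AUROC of the feature used as its own classifier score. The retention
   threshold defaults to 0.55; the value is exposed because published
   pipelines that bundle this step do not print their default, and 0.55
   ("slightly better than chance, in either orientation") is the natural
   reading. With ~60 samples the single-feature AUROC has a standard error
   near 0.075, so this step is a coarse sieve, not a test.
2. **Collinear exclusion.** Pairwise Spearman correlations (robust to the
   heavy-tailed abundances; the choice of coefficient is not dictated by
   the upstream literature) among the survivors; pairs with |r| > 0.8 are
   resolved greedily in descending |r| order, dropping the member with the
   lower univariate AUROC (ties drop the lexicographically later id).
   Pairs touching an already-dropped feature are skipped.
3. **Recursive feature elimination.** A random forest is fitted, the mean
   stratified 5-fold CV AUROC of the current panel recorded, and the
   feature with the lowest impurity importance removed — one feature per
   iteration, since realistic panels are small (10–20 features) and the
   cost is negligible. The returned panel is the size that maximized mean
   CV AUROC, ties resolved toward the smaller panel.

`tune_and_fit()` then searches the random-forest hyperparameter space
(tree count, maximum depth, features per split, per-tree sample fraction)
by seeded random search under a configurable budget; the contract is only
"maximize mean stratified 5-fold CV AUROC under the budget", so a grid or
Bayesian optimizer can be substituted. The reported model performance is
the mean over folds, with a percentile bootstrap 95% CI (≥1000 resamples
of the pooled out-of-fold score/label pairs). All fits run on one thread
with derived seeds, so the whole discovery path is bit-reproducible.

## Cross-cohort validation and disease specificity

`cohort_to_cohort()` trains on each cohort and scores every other; the
diagonal, which the matrix layout needs but no transfer defines, is filled
with the within-cohort 5-fold CV AUROC and labelled as such. `loco()`
holds out each cohort in turn. `external_validate()` offers both readings
of external validation: `refit_cv` (refit on the external cohort
restricted to the panel, 5-fold CV — the default) and `frozen` (transfer
the fitted model unchanged); both exist because the two conventions are
common and answer different questions (panel transferability vs model
transferability).

`disease_specificity()` implements the spike-in assessment: `n_spike`
(default 15) subjects of a chosen class from a donor dataset are added to
the control arm of an external validation cohort, the *unchanged* model is
re-scored, and the percent change 100·(AUROC_spiked − AUROC_plain)/AUROC_plain
is averaged over `n_repeats` (default 10) draws. When the donor class has
fewer than `n_spike` subjects a 5-case + 5-control fallback draw is used
and logged. Spiking exchangeable controls should leave the AUROC
essentially unchanged; spiking the model's own target cases into the
control arm is the baseline that should depress it materially. The
function never mutates its inputs.

## SparCC co-abundance networks

`sparcc_correlations()` is a full implementation of the SparCC estimator
for correlations among basis (unobserved absolute) abundances from
compositional data: per iteration, per-sample fractions are drawn from a
Dirichlet posterior (pseudocount 1 on count-like input), the log-ratio
variance matrix t_ij = var(log x_i/x_j) is formed, basis variances are
solved from its row sums under the sparse-correlation approximation, and
pairwise correlations follow as (ω_i² + ω_j² − t_ij)/(2 ω_i ω_j), clipped
to [−1, 1]. The most strongly correlated pair above the exclusion
threshold is iteratively removed from the basis system (up to
`n_exclusion_rounds` times), and the element-wise median over
`n_iterations` Dirichlet draws is returned. Defaults follow the common
command-line implementation of the algorithm: 50 iterations, 10 exclusion
rounds, exclusion threshold 0.1, 1000 permutations. Because the estimator
needs count-like input, `to_counts()` scales relative abundances by a
nominal depth (1e5) and rounds — a documented conversion, not an attempt
to reconstruct sequencing depth.

Two numerical guards matter in practice. Non-positive solved basis
variances (the linear approximation can undershoot for small feature sets)
are replaced by the smallest positive solved variance rather than by an
arbitrary epsilon — an epsilon floor explodes the correlation ratio and
produces spurious ±1 estimates. And a feature cannot leave its own basis
equation entirely: exclusion stops for a component whose equation would
drop below two terms.

`sparcc_pvalues()` permutes each feature's samples independently,
recomputes the full estimate, and reports the two-sided permutation
p-value with the +1 floor, BH-adjusted across pairs. Note the arithmetic
consequence: with m feature pairs and P permutations the smallest
attainable q is m/(P+1), so claiming q < 0.05 for a single planted pair
requires roughly P ≥ 20·m permutations. `build_network()` keeps pairs with
q < 0.05 (`significant` mode) or additionally |r| strictly above 0.3
(`strong` mode), and drops isolated nodes, matching the convention of
reporting per-network species counts as connected species.
`summarize_network()` counts positive/negative and interkingdom edges and
reports "key species" as the top-degree nodes (ties broken by summed |r|,
then lexicographically) — degree centrality is one reasonable reading of
an otherwise undefined term, and is labelled as an interpretation.
`compare_edge_proportions()` contrasts two networks' sign composition with
a 2×2 chi-square without continuity correction.

## Species–pathway association

`associate()` computes Spearman correlations between every differential
species and every differential pathway over a chosen condition's samples,
with two-sided t-approximation p-values, BH adjustment over all pairs, and
significance tiers at q ≤ 0.05/0.01/0.001. This is deliberately the plain
pairwise layer of hierarchical all-against-all testing: the hierarchical
blocking step only affects power and requires clustering parameters that
have no principled default here, while the reportable quantities
(coefficients and FDR-adjusted p per pair) live entirely in the pairwise
layer. Which samples define a condition (cases only, or cases plus
controls, per stratum) is a parameter, since either convention is
defensible; the orchestrated pipeline uses all samples of the stratum.

## The synthetic generator

`generate_cohorts()` produces the study conditions every downstream stage
is tested on. Latent log-abundances are per-feature log-normal baselines
(sd 2 around kingdom intercepts of 0 / −2.5 / −3.5 / −3.5 for bacteria /
fungi / archaea / viruses, so bacteria dominate totals and abundances are
heavy-tailed), plus a per-cohort batch offset N(0, `batch_sd`), plus the
planted CRC shift, plus optional per-feature covariate loadings, plus
residual noise. Zeros are imposed per sample by removing the smallest
latent values until the `sparsity` target is met — a detection limit, the
mechanism that actually generates most zeros in taxonomic profilers — and
the sample is then closed to proportions.

Defaults are the conditions exercised throughout the tests: 5 cohorts of
30 CRC + 30 CTR, 200 features (140/30/15/15 across kingdoms), 20 planted
features at log-effect 2.0 (half up, half down), batch sd 0.5, 30% zeros,
unit residual noise. Planted features are drawn from the 30th–75th
percentile of baseline abundance: discoverable biomarkers must clear the
detection-limit filters, and planting a shift on a dominant species would
leak into every other feature through closure, making "null" features
genuinely differential in relative-abundance space. Even with this
restriction a small closure spillover remains — it is a property of
compositions, not an artefact — and the tests therefore treat the
false-positive rate among unplanted features as bounded by, not equal to,
the nominal FDR.

What the generator does **not** emulate: read-count noise and
depth-dependent zeros, taxonomic misassignment, strain-level structure,
within-condition co-abundance (features are conditionally independent
given batch and covariates, so realistic network density must come from
the dedicated forward model used in the SparCC tests), and real
demographic confounding beyond the optional age/BMI/gender couplings.
Passing tests on these conditions show the machinery is correct and
calibrated, not that real CRC cohorts will yield the same AUROCs.

`generate_pathway_profile()` adds a functional table over the same
samples; coupled pathways are monotone power transforms of their partner
species times log-normal noise, and the table is scaled by one global
constant (per-sample closure would destroy the planted monotone
couplings, which the association tests rely on).

## Problem sizes and runtime choices

The shipped test-suite runs the full study conditions (300 samples, 200
features) for signal-recovery and null-calibration properties (20 seeds
each), 200-replicate type-I-error checks for PERMANOVA, Wilcoxon and
SparCC significance at reduced sizes (16–30 samples, 8 features, 99
permutations), and SparCC forward-model checks at 12–20 features and
60–100 samples with 10–20 Dirichlet iterations. These sizes were chosen so
that each property is measured with enough replication to be stable while
the whole suite stays in the minutes range on a laptop; all of them are
ordinary function arguments, so larger studies simply pass larger values.
The orchestrated pipeline defaults (`sparcc_iterations = 20`,
`sparcc_permutations = 199`) are likewise desk-scale defaults; for
publication-grade networks raise them to the algorithm's conventional
50 / 1000.

## Known limitations

- Fixed-effect pooling assumes a common effect across cohorts; strong
  cohort-by-effect interaction calls for `method = "random"`.
- The arcsine-square-root linear model is a variance-stabilized
  approximation, not a count model; extremely sparse features lean on the
  untestable/degenerate handling.
- SparCC's sparse-correlation assumption degrades below ~10 features and
  under strong single-feature dominance; the permutation null widens
  accordingly, and the implementation warns below 10 samples and refuses
  below 4 features.
- AUROCs on small cohorts (tens of samples) carry sampling noise of
  several points; the bootstrap CIs, not the point estimates, are the
  reportable quantity there.
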