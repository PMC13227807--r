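---
title: "Building serum miRNA diagnostic panels: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building serum miRNA diagnostic panels: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seromiR)
```

## The problem

Circulating microRNAs are candidate blood biomarkers for Alzheimer's
disease (AD), but observational serum cohorts are heavily confounded: AD
cases are older, more often female, and enriched for the APOE &epsilon;4
risk allele, and serum miRNAs form strongly correlated co-expression
clusters. A credible diagnostic panel must therefore (i) adjust
differential expression for clinical covariates, (ii) respect the
correlation structure when picking panel members, (iii) estimate
performance without information leakage, and (iv) report clinically
interpretable operating characteristics. seromiR implements this whole
chain as reusable, seeded, testable components, together with a synthetic
cohort generator that reproduces the confounding structure so that every
stage can be validated without access to individual-level patient data.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate a large serum miRNA
microarray case-control cohort. The defaults are fixed once to the
structure the workflow targets:

* **Group sizes** 1021 AD vs 288 controls.
* **Age** drawn per group from a normal truncated to 55–95 years,
  location 80 (AD) vs 71 (control), scale 6. Only a median and IQR are
  typically reported for such cohorts, so location/scale are free
  configuration with these defaults; truncation keeps ages clinically
  plausible.
* **Sex** Bernoulli per group (female probability 714/1021 vs 137/288)
  and **APOE &epsilon;4 count** categorical per group
  ((577, 376, 68)/1021 vs (238, 46, 4)/288). Confounding with diagnosis
  is induced *only* through these per-group sampling parameters — there
  is no structural model linking covariates to expression — which mirrors
  the purely observational imbalance of a case-control series.
* **Expression** is log2-scale: per-feature baseline ~ N(7, 1.5), plus a
  configured group effect (log2FC, AD minus control — the injected effect
  *is* the true mean difference before noise), plus noise with SD 0.5
  log2 units.
* **Clusters**: members of a configured cluster share a Gaussian latent
  factor with loading `sqrt(rho)`, so the expected within-cluster
  correlation equals `rho` analytically; the default plants one
  18-member candidate cluster at rho = 0.85, matching the single large
  module such cohorts show at |&rho;| &ge; 0.8.
* **Candidates**: a 32-miRNA literature-derived set split into a
  positively correlated subset (correlated with cognitive scores, hence
  expected *down* in AD, default effect −0.5) and a negatively correlated
  subset (expected *up*, default +0.5), including arm-expanded forms.
* **Missingness** is off by default and injected completely at random on
  request (`missing_rate`), to exercise the pairwise-complete and
  imputation code paths.

What the generator does **not** emulate: platform probe effects, batch
structure, heteroscedastic intensity-dependent noise beyond the variance
trend, and realistic missing-not-at-random patterns. Passing tests on
these cohorts therefore demonstrate the *statistical machinery* —
calibration, leakage-freedom, effect recovery — not performance on any
real cohort.

## Normalization, filtering and moderated differential expression

Raw intensities are log2-transformed and quantile-normalized across
samples (ties share the mean of their tied target positions). Features
are then filtered by row standard deviation: the default keeps features
with row SD at or above the 25th percentile (Q25) of all row SDs, using
the linear-interpolation quantile definition. The filter runs on the
normalized matrix before model fitting.

`fit_moderated_de()` fits, per feature, ordinary least squares on the
design `[intercept, diagnosis, covariates]`, with the diagnosis
coefficient reported as log2FC, positive = higher in AD — every
downstream direction rule uses this convention. Residual variances are
shrunk toward an empirical-Bayes prior,

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

with $(d_0, s_0^2)$ estimated by the method of moments on log residual
variances; the moderated t uses $\tilde{s}_g$ with $d_0 + d_g$ degrees of
freedom. With `trend = TRUE` (the default) the prior variance is a smooth
function of average log2 expression, fitted by lowess with a fixed span
of 0.5. The implementation agrees with the reference empirical-Bayes
implementation to 1e-6 on complete data without a trend; with a trend the
smoother spans differ between implementations, so agreement is close but
not exact (the test suite checks both statements). Robust hyperparameter
estimation is deliberately **not** implemented — the `robust` flag is
reserved and warns — and per-array quality weights are replaced by an
optional user-supplied sample-weight vector with a uniform default.
Missing expression values are handled per feature (complete cases within
feature); features with fewer than 10 complete samples per group are
dropped with a warning. Benjamini–Hochberg adjustment controls the FDR,
and `compare_covariate_models()` quantifies sensitivity to covariate
coding (APOE as categorical 0/1/2 dummies, as a continuous count, or
excluded) by the Jaccard overlap of significant sets and the Spearman
correlation of shared log2FCs; an empty union of significant sets yields
a missing Jaccard rather than 0.

## Directionality and the signature score

Literature-derived candidates carry an expected direction: miRNAs
positively correlated with cognitive performance should be
*down*-regulated in AD, negatively correlated ones *up*-regulated. A
member is directionally consistent iff it is significant (q < 0.05) and
its log2FC has the expected sign. At set level, `mean_rank_set_test()`
compares the set members' moderated t statistics (log2FC when t is
unavailable) against all remaining post-filter features with a one-sided
Wilcoxon rank-sum normal approximation using tie and continuity
corrections; the continuity correction keeps the approximation within
0.02 of exhaustive enumeration down to universes of 7 features. The test
ranks the post-filter universe, since that is the population the fitted
statistics describe. Individual-level robustness uses one-tailed exact
binomial sign tests (zeros dropped, the standard convention) and
one-sided Wilcoxon signed-rank tests (exact for n &le; 25, normal
approximation with continuity correction otherwise).

The signature score z-scores each candidate feature across **all**
samples — not within diagnosis groups, so the score is computable per
sample without label knowledge — and averages with weight +1 for the
negatively correlated set and −1 for the positively correlated set. The
score is invariant to per-feature affine transforms. Its group effect is
estimated by OLS on diagnosis + age + sex + APOE &epsilon;4.

## Covariate diagnostics

Univariate diagnostic value of age, sex (coded female = 1, matching the
convention that a threshold of 1 classifies females positive) and APOE
count is summarized by rank-based AUC (midrank formula, exactly the
pairwise-concordance probability), average precision (step sum over
distinct descending thresholds, no interpolation), and Youden-optimal
operating points with the rule score &ge; threshold &rArr; positive.
Threshold candidates are midpoints between adjacent distinct scores plus
&plusmn;&infin;, ties in J break toward the lowest threshold, and the
smallest attained score in the positive region is reported alongside —
for integer-valued covariates this reproduces printed integer cutoffs.
`crossval_univariate()` estimates small-sample transfer: per stratified
fold, a univariate logistic model and its Youden threshold are derived on
the training split and applied unchanged to the validation split.
Association between features and covariates uses partial Spearman
correlation: rank-transform everything, residualize feature and target on
the remaining covariates, correlate the residuals, with t-distribution
p-values (df = n − 2 − #adjusters) and BH correction across features;
with no adjusters this reduces exactly to Spearman's &rho;. Cramér's V
(chi-square without continuity correction) summarizes contingency-table
imbalance.

## Correlation network and clusters

Pairwise Spearman correlations use pairwise-complete observations;
entries supported by fewer than `min_pairs = 10` pairs are missing, and
missing entries are treated as below threshold when building the network
(conservative connectivity). Clusters are connected components of the
|&rho;| &ge; threshold graph (primary threshold 0.80, scan over
0.90–0.70); singletons are counted separately from clusters of size
&ge; 2. Cluster IDs are deterministic (lexicographically smallest
member). The module eigengene is the first principal component of the
median-imputed, z-scored member matrix, scaled to unit variance, sign
oriented so the mean loading is positive.

## Panel selection

`forward_select_fold()` runs greedy forward selection over candidate
miRNAs on a training fold: each step scores every remaining candidate by
the gain in inner-CV AUC (pooled out-of-fold, fixed elastic-net penalty)
over the current model (baseline covariates + selected features).
A candidate is admitted iff its gain reaches &Delta;AUC &ge; 0.005, or
the stricter &Delta;AUC &ge; 0.010 when its cluster already holds a
selected member — the one-representative-per-cluster rule, relaxed only
through the stricter gate. We read the within-cluster rule as admitting a
second member *in addition to* the first; a `cluster_mode = "replace"`
flag implements the alternative reading in which a same-cluster candidate
may only swap with the resident. The greedy loop uses a fixed default
penalty (strength 0.01, l1 ratio 0.5) rather than per-step tuning to keep
it tractable; full hyperparameter tuning happens in the final evaluation.
Ties break by higher gain, then higher univariate CV-AUC, then
lexicographic ID, guaranteeing run-to-run determinism at a fixed seed.

Across outer folds &times; repeats (default 5 &times; 4 = 20 run units,
both configurable), selections are deduplicated within each run unit,
counted, and cluster-deduplicated keeping the highest-frequency member.
The K-AUC path evaluates baseline + top-K frequency-panel prefixes by
cross-validation (K = 0 is the baseline-only model), and the 1-SE rule
picks the smallest K whose AUC reaches

$$\text{threshold} = \max_K \text{AUC} - \frac{\text{SD}_{\text{folds}}(\text{best } K)}{\sqrt{n_{\text{folds}}}}.$$

This max-minus-one-SE construction is inferred from the published
threshold pairs (0.823 &rarr; 0.810 and 0.836 &rarr; 0.823, both
consistent with SE &asymp; 0.013) and is fixed as stated.

## Classifier evaluation

The primary classifier is elastic-net logistic regression; median
imputation and standardization are fitted inside the training pipeline
only, and class imbalance is handled by class-weight balancing.
Performance estimation uses 5 &times; 5 nested cross-validation: inner
folds tune the penalty grid (strength {0.001, 0.01, 0.1, 1, 10} &times;
l1 ratio {0.1, 0.5, 0.9} by default) by pooled inner-CV AUC; each
sample's out-of-fold probability comes from a model never trained on it.
With repeats, OOF probabilities are averaged across repeats before pooled
metrics (per-repeat metric averaging is the noted alternative). Reported:
AUC with a 95% stratified-bootstrap percentile CI (2000 draws), average
precision, Brier score, expected calibration error over 10 equal-width
bins (ECE is bin-sensitive; the bin count is fixed and documented),
decision curves (net benefit $TP/N - (FP/N)\,p_t/(1-p_t)$ against
treat-all and treat-none over $p_t$ = 0.01–0.50), and three operating
points: Youden-optimal, highest sensitivity at specificity &ge; 0.90, and
highest specificity at sensitivity &ge; 0.90. Linear/RBF SVM and random
forest comparators plug into the same interface when their packages are
available; all headline analyses use the elastic net.

## Numerical choices and degenerate inputs

* Quantile normalization: ties share the mean of tied target positions;
  a single-sample matrix is returned unchanged (identity quantile step).
* Row-SD quantile: linear-interpolation order-statistic definition.
* Zero-SD features are excluded from signature scores (warning); an
  all-missing row is excluded from filtering (warning).
* A rank-deficient design matrix fails fast, naming the collinear
  columns.
* Empty candidate sets select nothing (not an error); an empty union of
  significant sets gives a missing Jaccard.
* Unattainable operating-point constraints yield rows of missing metrics
  with a warning.
* Per-stage pipeline seeds are derived by hashing (top seed, stage name),
  so stages draw from decoupled streams and skipping one stage does not
  shift another's randomness.

## Problem sizes used in validation

The test suite validates statistical behavior at deliberately modest
sizes: effect recovery at n = 300/300 with 400 background features over
20 seeds (recovered mean log2FC within &plusmn;0.1 of 1.0); type-I error
of the moderated t on 200 null cohorts of 50 features &times; 200
samples (within [0.03, 0.07]); permutation-null nested CV on 50
relabelings of a 120-sample, 10-feature matrix (mean OOF AUC within
0.5 &plusmn; 0.05); planted-signal selection over 20 seeded cohorts of
240 samples (true representative top-ranked in &ge; 90%). These sizes
give the Monte-Carlo bands quoted; larger cohorts only tighten them.

## Known limitations

* Robust empirical-Bayes estimation and array-quality weighting are out
  of scope; heavy-tailed variance outliers will pull the plain moment
  estimates.
* The trend fit uses a fixed lowess span; very small feature sets make
  the trend unstable (use `trend = FALSE` below ~50 features).
* Connected components are a deliberately simple clustering; no
  soft-thresholding or community detection.
* Published absolute panel performance (AUC &asymp; 0.82–0.84 on the real
  cohort) is not reproducible without individual-level data; the package
  validates the machinery, not those numbers.
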