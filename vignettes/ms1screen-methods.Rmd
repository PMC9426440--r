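---
title: "Methods: module-based screening of MS1-only feature intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module-based screening of MS1-only feature intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms1screen)
```

## The problem

Data-dependent MS/MS metaproteomics identifies peptides by fragmenting the
most intense MS1 precursors and searching the fragments against a database.
For complex microbiome samples this is slow, biased toward abundant
peptides, and hostage to database completeness. When the question is a
*screen* — "which drugs, doses, or diagnoses shift the community, and which
look alike?" — identification is not actually needed. `ms1screen`
clusters experimental conditions directly from the aligned MS1
feature-intensity matrix `X` (features x samples), skipping MS/MS entirely.

The pipeline is: preprocess `X`; decompose it into robust independent
components; group features into modules by k-medoids on the component
loadings; summarize each module as an eigenfeature; correlate eigenfeatures
with condition indicators; and cluster conditions hierarchically from those
correlations, with multiscale-bootstrap support. A lasso step can then pull
candidate marker features out of the most outcome-correlated module.

## Preprocessing

The stages run in a fixed order: quartile-based missingness definition,
per-group prevalence filter, kNN imputation, median-of-ratios
normalization, log2.

* **Missingness by intensity quartile.** Raw intensities are pooled over
  all observed cells and split into quartiles (linear-interpolation
  quantiles; the convention is stated because quantile definitions differ).
  Observed values below the first quartile are treated as *missing for
  filtering only*: low-intensity MS1 features behave like dropouts, but
  once a feature passes the filter its low values are kept as data, so
  nothing is censored twice. Passing `censor = "high"` or `"high+medium"`
  moves the threshold to the third or second quartile, reproducing the
  harsher censoring comparison in which only abundant features count as
  observed.
* **Prevalence filter.** A feature is kept only if it is non-missing in at
  least `min_frac` (default 0.5) of the samples of *every* condition,
  controls included. This is deliberately conservative: a feature absent
  from one whole condition cannot be attributed to biology versus
  acquisition.
* **kNN imputation.** Only truly absent entries are imputed (`k = 10`
  neighbor features, feature-mean fallback above 50% missingness, hard
  error if a sample exceeds `colmax = 0.95`). Neighbor distance is the mean
  squared difference over mutually observed samples; the mean (rather than
  the sum) keeps pairs with different overlap comparable.
* **Median-of-ratios normalization.** Per-feature geometric-mean reference,
  per-sample size factor = median ratio to the reference. No pseudo-count
  is needed because imputation guarantees positivity.

## Robust consensus ICA

ICA models the centered matrix as `X = S A` with statistically independent,
non-Gaussian feature loadings (columns of `S`) mixed into samples by
activities `A`. A single FastICA run (logcosh contrast, symmetric
decorrelation, tolerance `1e-6`, at most 1000 iterations) depends on its
random initialization, so the pipeline runs it 100 times with seeds derived
from the master seed, pools all resulting components, clusters them by
single linkage on `1 - |r|` at threshold 0.1, keeps clusters drawing on at
least half the runs, and returns sign-aligned cluster centroids as the
robust components. The component count is the smallest number of principal
components explaining 99% of the variance of the feature-centered matrix.

Two numerical points deserve honesty:

* **Whitening.** The fixed-point updates are empirical expectations over
  features, so the whitened signals are centered along the feature index
  (as well as per feature) before decomposition.
* **Convergence in the near-Gaussian regime.** With ~50 components
  requested from ~50 samples, most directions beyond the true sources are
  close to Gaussian. For a standard normal `u`, `E[u tanh u] - E[1 -
  tanh^2 u]` is about 0.011, while its estimation error at `N` features is
  about `N^{-1/2}` — at a few thousand features the noise exceeds the
  signal and those directions rotate chaotically, so the `1e-6` tolerance
  is unreachable no matter how many iterations are spent. Runs therefore
  stop early once their best rotation stops improving by 5% within 100
  iterations and are flagged unconverged. If fewer than two runs converge,
  all completed runs are pooled: the strongly non-Gaussian source
  directions lock in within tens of iterations regardless, and the
  consensus clustering is exactly the filter that separates those
  reproducible directions from the chaotic remainder. On data with a clear
  low-dimensional source structure (for example the source-recovery
  benchmarks) runs converge normally and unconverged runs are excluded as
  usual.

## Feature modules and eigenfeatures

Rows of `S` are clustered with k-medoids under correlation distance
`1 - r`. Seeding is k-medoids++ (first medoid uniform, later ones with
probability proportional to squared distance); iteration alternates
nearest-medoid assignment with per-module medoid minimization until the
cost stops improving. `k` is scanned (default 10-50) and chosen by maximum
mean silhouette on the same distance; singleton clusters contribute
silhouette 0; ties go to the smallest `k`. One seeded start per `k` is the
default (`restarts` raises it; best cost wins).

Each module's standardized (centered, unit-variance) log2 sub-matrix is
decomposed by SVD and the first right singular vector over samples is the
module **eigenfeature** — the eigengene construction applied to MS1
features. Standardization makes the summary invariant to per-feature
intensity scale; the sign is anchored to correlate non-negatively with the
module's mean standardized profile, which makes the output deterministic.
Explained variance is the first squared singular value over the total.

## Condition clustering and support

Eigenfeatures are correlated (Pearson) against one-hot condition
indicators; encoding conditions as indicators rather than ordered doses is
the central reconstruction choice, recorded here because dose ordering is
deliberately not assumed. Condition distance is `1 - r` between profile
columns; the tree is average linkage (UPGMA), so each merge height is the
mean inter-group correlation distance; the flat cut is again chosen by
maximum silhouette.

Node support uses the multiscale bootstrap: module rows of the correlation
profile are resampled with replacement at relative sizes 0.5-1.4 (step
0.1), 1000 resamples each, and each observed node's bootstrap proportion
`BP(r)` is the fraction of resampled trees containing the same leaf set.
`z(r) = qnorm(1 - BP(r))` is regressed on `{sqrt(r), 1/sqrt(r)}` by
weighted least squares (binomial-variance weights), giving signed distance
`v` and curvature `c`, and `AU = 1 - pnorm(v - c)`; `BP` is reported at
scale 1. Nodes whose proportions are degenerate or nearly so (0 or 1 at
all, or all but one, scale) cannot support the extrapolation and are
clamped to AU 0 or 1 according to which side their proportions sit on; a
genuinely mixed node with fewer than two informative scales yields `NA`
with a message. Resampling the *module rows* (not raw features) is a
design choice: the modules are the objects being correlated, and it keeps
support independent of module size. Constant condition columns arising in
a resample are given correlation 0 so agglomeration can proceed.

## Tree comparison and markers

Two condition trees over the same leaves are compared by the Pearson
correlation of their cophenetic distances. Significance comes from
shuffling the leaf labels of the second tree (10,000 permutations by
default) and counting `|r_perm| >= |r_obs|`; the add-one correction
`p = (count + 1) / (n_perm + 1)` keeps p away from exactly zero. Shuffling
one tree rather than both gives the same null distribution.

Marker selection takes the module with the maximum `|r|` for the outcome
condition, then fits an L1-penalized logistic model (`alpha = 1`) on that
module's log2 features: 100 log-spaced penalties spanning two decades below
the smallest all-zero penalty, leave-one-out cross-validated binomial
deviance, `lambda.1se` (the largest penalty within one standard error of
the minimum) for the final fit. Features are standardized internally and
coefficients reported on the log2 scale. A model is kept only if more than
one coefficient is nonzero — a single-feature "signature" is not a module
finding. Discrimination is leave-one-out AUC over held-out probabilities
(mid-rank ties); in-fold predictions are never used. One artifact needs
explicit handling: when a fold's refit selects no features, its held-out
probability varies only with the training prevalence — leaving out a case
lowers the fold's intercept — which anti-ranks the predictions perfectly
even though the model knows nothing. Folds are therefore tracked, and an
all-intercept leave-one-out model is reported as AUC 0.5 (no
discrimination) with a warning, as is any constant prediction vector.

## The synthetic screen generator

`simulate_screen()` emulates the data model the pipeline assumes, with
known truth: per-feature log-normal baselines (log2 mean 24, sd 2 — about
the intensity scale of Orbitrap MS1 features); 12 signal modules of 100
features among 2000; 16 conditions x 3 replicates in three planted groups
(7 control-like with zero effect, 4 strong at 2 log2 units, 5 intermediate
at 1); module-level per-sample activity noise (sd 0.25) shared within a
module; per-entry residual noise (sd 0.5); per-sample scaling factors
(log2 sd 0.3) that median-of-ratios should remove; and intensity-dependent
(MNAR) dropout — entries in the lowest quartile are absent with
probability 0.6. These defaults were chosen once as a realistic drug-screen
layout and are the conditions under which the end-to-end tests run.

What the generator does **not** emulate: retention-time structure, charge
states and isotope envelopes, correlated batch drift beyond an optional
two-level shift, heavy-tailed single-feature outliers, and any taxonomic
composition. Passing tests therefore show that the statistical machinery
recovers planted structure under the assumed noise model — not that a real
microbiome screen will behave as cleanly.

## Problem sizes, determinism, degenerate inputs

The shipped tests run the full pipeline at the generator defaults (2000
features, 48 samples, 100 ICA runs, k scanned 10-50, 1000 bootstrap
resamples) for the condition-recovery and support checks, and smaller
configurations (a few hundred features, 10-20 runs) where only the
mechanics are under test; the sizes are stated in the test files. All
randomness flows from one master seed through fixed per-stage offsets, so
a rerun with the same configuration and seed is byte-identical, which the
manifest hashes verify. Per-stage wall-clock timings are recorded in the
(unhashed) manifest rather than the hashed run report, keeping reruns
comparable.

Degenerate inputs have defined behavior rather than surprises: constant
matrices, single conditions, all-missing features, `k >= n`, single-class
outcomes and label mismatches raise errors naming the offender; two-leaf
trees skip the silhouette cut; degenerate (constant-height) trees compare
with correlation 0 and p = 1; fewer than 4 modules skip bootstrap support
with a message.

## Known limitations

* The one-hot condition encoding ignores dose ordering; a monotone dose
  response spread over three dose levels is three separate indicator
  correlations.
* Module count selection by silhouette inherits silhouette's bias toward
  compact, balanced clusters; planted elongated modules may be split.
* AU values from the weighted least-squares extrapolation are unstable for
  nodes observed at proportions very close to 0 or 1 at only a few scales;
  such nodes are clamped or reported `NA` rather than extrapolated.
* With ~replicate-free designs (one sample per condition) the eigenfeature
  correlations are exact fits and the bootstrap is the only guard against
  overinterpretation.
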