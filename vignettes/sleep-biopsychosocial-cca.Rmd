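---
title: "Linking multidimensional sleep to biopsychosocial and connectome measures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking multidimensional sleep to biopsychosocial and connectome measures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcca)
```

## The problem

Sleep health is multidimensional: satisfaction, latency, duration,
efficiency, disturbances, medication use and daytime dysfunction can vary
partly independently, and each can relate to a different slice of a
person's mental health, cognition, personality, substance use and physical
health. `sleepcca` implements the multivariate machinery for studying those
joint patterns in cohorts that contain many related individuals (twins and
siblings), where naive resampling-based inference is invalid.

The pipeline has three layers:

1. **Two-block CCA** between a small sleep block (the seven sleep-quality
   sub-scores, ordinal 0–3 in real questionnaires but treated numerically)
   and a wide behavioral block, yielding latent components (LCs): per-block
   weight vectors, a canonical correlation, per-subject canonical scores,
   and structure coefficients (loadings) for interpretation.
2. **Inference that respects family structure**: restricted permutations
   over exchangeability blocks for component significance, bootstrap
   resampling for loading stability, and family-aware k-fold
   cross-validation for generalizability.
3. **Connectome characterization**: per-subject functional-connectivity
   matrices regressed edge-wise and network-wise on LC composite scores,
   and graph metrics (module-degree z, participation coefficient, an
   integration/segregation ratio) of the resulting coefficient network.

## The CCA model and its numerical route

Given standardized blocks $X \in \mathbb{R}^{n\times p}$ and
$Y \in \mathbb{R}^{n\times q}$, CCA finds weight pairs $(a_k, b_k)$
maximizing $\mathrm{corr}(Xa_k, Yb_k)$ subject to score orthogonality.
`fit_cca()` whitens each block by a thin SVD (singular values below
`rank_tol` $\times$ the largest are dropped, reducing the component count
under rank deficiency) and takes the SVD of the cross-product of the two
whitened bases; the singular values are the canonical correlations, and the
back-transformed weights are scaled so canonical scores have unit sample
variance. This route is numerically stable and rank-aware, and it matches
the generalized-eigenproblem closed form to $10^{-8}$ in the test suite.

Three conventions the literature leaves open are fixed deterministically:

* **Sign**: each component is flipped so the sleep variable with the
  largest absolute loading loads positively ("higher = worse" on the sleep
  side). Any deterministic rule would do; this one makes repeated fits on
  permuted row orders bit-identical.
* **Standardization** uses the sample standard deviation ($n-1$), and the
  training means/sds are stored in the model so held-out data are always
  standardized with training parameters before projection.
* **Missing values are rejected**, not imputed: the target study design
  excludes subjects with incomplete data, and silent imputation would
  change every downstream statistic.

**Covariance explained** is defined as
$\sigma_k^2 / \sum_j \sigma_j^2$ with $\sigma_k$ the sample covariance
between the paired canonical scores of component $k$; the fractions sum to
one over the fitted components and are reported as percentages. An
alternative convention uses the singular values of the cross-correlation
matrix directly; the two differ only by normalization, and the package
deliberately commits to the score-covariance form rather than guessing
which one any particular publication used.

**Quantile normalization** (a robustness variant of the main analysis) is
the rank-based inverse-normal transform with the Blom offset,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, average ranks for ties. The
exact recipe behind published "quantile normalization" phrases varies;
Blom is the common biostatistics default and is documented here rather than
asserted as anyone's original.

## Restricted permutations

In a cohort of twins and siblings the rows are exchangeable only in a
restricted sense. `build_blocks()` encodes the two admissible move types
used by the PALM family of methods: within a family, members sharing a
zygosity role (MZ–MZ, DZ–DZ, sibling–sibling) may swap; and whole families
with identical role multisets may be exchanged as units. The sampler
composes independent uniform draws of both move types, which makes every
admissible permutation equally likely (the two factors decompose the
restricted permutation group uniquely); on a tiny design the test suite
enumerates all eight admissible permutations and checks the sampler's
support and uniformity exactly. A `scheme = "role_stratified"` switch
offers the looser literal reading — free permutation within role strata
across the whole sample — for sensitivity analyses.

The null statistic for component $k$ is the $k$-th canonical correlation of
the refit after permuting the behavior block's rows (so the null is not
centered at zero — overfitting inflates all sample canonical correlations);
p-values use the add-one convention $(1+b)/(1+B)$, which can never be zero,
and q-values are Benjamini–Hochberg across components. FDR is applied
within this family of component tests only; pooling with post-hoc tests is
left to the caller.

## Bootstrap stability of loadings

Bootstrap replicates resample subjects with replacement (family-level
resampling is available by flag; subject-level is the default to mirror the
stated procedure of the motivating design), refit the CCA, and must then be
**aligned** to the original fit: components can reorder and flip sign under
resampling. Alignment matches replicate components to original ones by
maximal absolute correlation of stacked weight vectors (greedily), then
flips signs so the match is positive; the diagnostics report how often
either happened. Per loading we report the bootstrap mean and standard
deviation, a normal-theory confidence interval, $z = \text{mean}/\text{sd}$
with a two-sided normal p, and BH q-values within each component-by-block
family. The z-based test is one reasonable formalization of marking
"significant after FDR" loadings; the original test statistic behind such
labels is typically unstated, so the package documents its choice instead
of claiming equivalence. Replicates that produce a constant column (or lose
rank) are redrawn with a bounded retry budget and counted.

## Family-aware cross-validation

`make_folds()` shuffles families with a seeded generator and deals them
round-robin, so no family spans folds and fold sizes differ by at most one
family. Per fold, the CCA is trained on the remaining data, the held-out
blocks are standardized with training parameters, projected through
training weights, and the per-component correlation between projected sleep
and behavior scores is the generalization measure; the fold mean is
reported. Its significance uses admissible restricted permutations of each
fold's held-out pairings — one defensible construction of a
cross-validation p-value, documented as the package's choice.

## Connectome stages

* **Censoring** (`build_censor_mask`): frames with framewise displacement
  \> 0.2 mm or DVARS \> 75 are outliers; one frame before and two after are
  censored too; kept segments shorter than five frames are dropped; runs
  with more than half their frames censored are excluded. The two
  hand-simulated 12-frame cases in the tests pin the exact boundary
  behavior.
* **RSFC assembly** (`compute_rsfc`): Pearson correlation over kept frames
  per run, clipped to $\pm(1-10^{-7})$ before the Fisher z-transform
  (atanh diverges at $\pm 1$), averaged across non-excluded runs.
* **Confounds** (`residualize_confounds`): per-edge OLS on intercept +
  covariates (age, sex, education in the motivating design), residuals
  forward; collinearity falls back to a pseudo-inverse with a warning.
* **GLMs**: per edge or per network pair, `value ~ intercept + composite`;
  the slope's T, the model F (= T² with one predictor) and its p-value are
  reported; edge-wise betas stay unthresholded, network-wise tests get
  BH-FDR across the $M(M+1)/2$ unique network pairs (171 for 18 networks).
  Exact fits (zero residual variance) are flagged rather than dividing by
  zero. Network averaging uses all cross-block parcel pairs off-diagonal
  and unique unordered pairs within blocks; single-parcel networks are NA
  within.
* **Graph metrics** (`module_degree_z`, `participation_coefficient`,
  `integration_segregation_ratio`): computed on the edge-wise beta matrix
  of a component (or any symmetric matrix, e.g. the sample-average RSFC).
  The beta matrix is signed while the classical formulas presuppose
  nonnegative strengths; the default policy zeroes negative entries after
  max-|w| normalization, with an absolute-value policy selectable — the
  package implements both because the convention is genuinely ambiguous in
  the literature. "Normalized" in the within:between ratio is interpreted
  as per-metric min–max scaling across nodes with an $\epsilon = 10^{-6}$
  guard; the raw z/PC ratio is scale-inconsistent and can divide by zero.

## The synthetic cohort generator

The generator exists so that every stage is testable without
restricted-access data, and its defaults define the study conditions the
tests run under.

Rows of the joint (sleep, behavior) vector are drawn from a Gaussian with
$\Sigma_{xx} = I_p$, $\Sigma_{yy} = I_q$ and
$\Sigma_{xy} = A\,\mathrm{diag}(\rho)\,B^\top$, where $A$ and $B$ are
orthonormalized sparse sign patterns (disjoint contiguous supports by
default). Under this law the population canonical correlations equal the
planted $\rho$ *exactly* and the population structure coefficients equal
the pattern columns — which is what the recovery tests assert, with
tolerances calibrated by pilot simulation at the stated sizes. An
alternative sketch — latent scores times loadings plus additive noise,
then standardization — was rejected because observation noise attenuates
the canonical correlations below the planted targets by a noise- and
pattern-dependent factor, making "planted" values only approximate.

Family dependence is induced by icc-weighted mixing: each subject's latent
vector is $\sqrt{c_r}\,g_f + \sqrt{1-c_r}\,e_i$ with a family-level draw
$g_f$ and an individual draw $e_i$ of the same law, $c_r$ the role's
intra-class correlation (defaults MZ 0.5, DZ 0.3, siblings 0.2, singletons
0). Marginals are exact and same-family members correlate at
$\sqrt{c_r c_s}$ in **both** blocks. Crucially the family effect is *not*
a single realized value added to both blocks: that would constitute a
genuine shared cross-block signal, inflating population canonical
correlations above the planted values and making a true null
(`planted_rho = 0`) impossible — the permutation-calibration property the
package tests would then be unattainable by construction. With the mixing
construction, a null cohort has genuinely independent blocks while rows
remain family-dependent, which is exactly the situation restricted
permutation inference is built for.

The connectome generator plants block effects — every edge between two
chosen networks moves as `slope × composite score` — plus symmetric
Gaussian edge noise. Published work in this design space rarely reports
RSFC effect sizes, so the default planted slope (0.3 at noise sd 1,
n = 400) is chosen for comfortable recovery rather than realism, and the
tests treat it as a recovery benchmark, not an empirical claim.

What the generator does **not** emulate: within-block correlation among
phenotype variables (real sleep sub-scores are collinear; the generator's
identity within-block covariance makes planted values exact at the cost of
that realism), ordinal measurement (a quartile-thresholding option exists
but is off by default), temporal autocorrelation of fMRI noise, and any
item-level questionnaire structure. Passing tests therefore demonstrate
correctness of the machinery under a clean latent-variable law, not
robustness to those real-data features.

## Problem sizes, seeds and determinism

The test suite and the acceptance script run the pipeline at sizes chosen
to make Monte-Carlo properties measurable while keeping a full run
comfortably interactive: recovery at $n = 2000$ over 20 seeds, permutation
calibration over 500 null cohorts of $n = 200$ with 199 permutations,
bootstrap coverage over 200 cohorts of $n = 400$ with 200 replicates, and
connectome recovery at $n = 400$ with 50 parcels. Defaults inside
`pipeline_config()` are the method's reference settings (10,000
permutations, 1,000 bootstrap replicates, 5 folds, q = 0.05).

Every stochastic stage consumes an independent named seed stream derived
from one master seed (`stage_seed()`), so adding a stage never perturbs
earlier stages' draws; running the full pipeline twice with one
configuration produces bitwise-identical tables and manifests, and the run
manifest records the seeds and per-file digests needed to verify that.

## Known limitations

* The permutation scheme covers within-family role swaps and whole-family
  exchanges; it does not implement residual-based schemes (e.g.
  Freedman–Lane) or tail approximations for very small p-values.
* The intended regime is $n \gg p$; a ridge (covariance-shrinkage) hook is
  exposed on `fit_cca()` but off by default, and no sparse or kernel CCA
  is provided.
* Bootstrap CIs are normal-theory (mean ± z·sd); percentile intervals
  would need the full replicate matrix, which is not retained.
* Graph metrics treat modules as given (a parcel→network map); no
  community detection.
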