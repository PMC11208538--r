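---
title: "Methods: complexity and connectivity features of rsfMRI and their use in phenotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity and connectivity features of rsfMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexconn)
```

## What the package computes

`complexconn` implements a complete, testable pipeline for comparing
resting-state fMRI (rsfMRI) derived features against basic individual
characteristics (age, gender, total intracranial volume) as predictors of
behavioral phenotypes. It covers four stages:

1. **Feature extraction.** Nine per-ROI features: four temporal-complexity
   measures — Hurst exponent (`HE`), weighted permutation entropy (`wPE`),
   the tolerance-domain AUC of range entropy B (`RangeEnB_AUC`), the
   scale-domain AUC of multiscale entropy (`MSE_AUC`) — and five
   functional-connectivity measures — eigenvector centrality (`EC`) and
   weighted clustering coefficient (`wCC`) on the Pearson connectome, and
   fALFF, local correlation (`LCOR`) and global correlation (`GCOR`)
   computed voxel-wise and averaged within ROIs.
2. **tSNR-based ROI selection.** Per-ROI temporal signal-to-noise ratio,
   normalized per subject, averaged over the cohort, and thresholded at a
   percentage of the group maximum.
3. **Prediction.** Four confound-handling scenarios under five repeats of
   5-fold nested cross-validation with ridge models (39-value
   regularization grid) or a heuristic-cost linear SVM, with balanced
   male/female subsampling over a grid of sample sizes.
4. **Identification.** Connectome-fingerprinting-style matching of one
   feature map to another across the population, scored as the proportion
   of self-matches.

Because population imaging data are access-controlled, the package ships a
first-class synthetic-cohort generator that reproduces the statistical
structure these stages assume, with full ground truth.

## Temporal-complexity measures

All four complexity measures operate on a single ROI-mean time series,
nominally 490 samples at a repetition time of 0.735 s (the defaults of the
synthetic generator).

**Hurst exponent** (`hurst_rs`). Rescaled-range analysis: window sizes are
log-spaced from 16 to $n/2$ (at least 8 sizes); each window is demeaned,
the range of its cumulative deviations divided by its SD, averaged over
windows of a size, and the slope of $\log(R/S)$ against $\log$ window size
is the estimate. $H > 0.5$ indicates long-range dependence, $H < 0.5$
anti-persistence, $H \approx 0.5$ a memoryless series. The estimator is
validated against an *exact* fractional-Gaussian-noise generator
(`generate_fgn`, circulant embedding of the true autocovariance
$\gamma(k) = \tfrac12(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$); plain R/S
has a small upward bias on white noise at these lengths, which the tests
quantify rather than correct, matching common practice.

**Weighted permutation entropy** (`weighted_permutation_entropy`). Ordinal
patterns with $m = 4$, $\tau = 1$; each pattern occurrence is weighted by
the variance of its embedded vector; the Shannon entropy of the
weight-normalized distribution is divided by $\log_2(m!)$ so values lie in
$[0, 1]$. Ordinal ties are broken by order of occurrence (a stable
ranking), and zero-variance vectors carry zero weight.

**Range entropy B** (`range_entropy_B`). The sample-entropy counting
scheme with the Chebyshev distance replaced by the normalized range
distance $d = (\max_k - \min_k)/(\max_k + \min_k)$ over coordinate-wise
absolute differences, which is bounded in $[0,1]$; identical templates
(a $0/0$ case) are assigned distance 0. At tolerance $r = 1$ every pair
matches, so the value is *exactly* 0 for any finite non-constant series —
this makes the whole $r$-trajectory a bounded signature of the dynamics.
The feature used for prediction is the trapezoidal area under the
trajectory with $m = 2$ over a default grid of 20 equally spaced
tolerances on $(0, 1]$; the grid is a configuration knob and the AUC is
stable under refinement (a tested property: 51- and 501-point grids agree
within 2% on white noise).

**Multiscale entropy** (`multiscale_entropy_auc`). Sample entropy
($-\ln(A/B)$ over template pairs, self-matches excluded) of
coarse-grained series at scales $1..\tau_{max}$ with $m = 2$, $r = 0.5$,
$\tau_{max} = 10$. The tolerance is $0.5 \times$ SD *of the original
scale-1 series*, held fixed across scales — the standard multiscale
convention; the source description states $r = 0.5$ without units and we
adopt the SD-relative reading, which also makes every entropy measure
invariant to positive affine transforms of the input. The feature is the
trapezoidal AUC of the scale trajectory divided by $\tau_{max}$.

**Undefined entropy points.** Zero match counts make sample entropy
undefined; such points are returned as `NA` (never an exception), and the
AUC reducers drop them with abscissa renormalization and a warning. This
preserves comparability across ROIs of different noisiness rather than
poisoning a whole feature map with one degenerate scale.

The pair-counting kernels are implemented in C++ (`Rcpp`), and every one
of them is checked against brute-force R enumeration oracles in the test
suite.

## Connectivity measures

`fc_matrix` computes the Pearson connectome of ROI-mean series. For the
graph measures, negative correlations and the diagonal are set to zero
first: Perron–Frobenius theory needs a nonnegative matrix for a
well-defined, nonnegative leading eigenvector, and the source description
is silent on negative weights — this was a genuinely open design choice,
resolved in favor of the most common convention in the connectomics
literature. `eigenvector_centrality` is the unit-norm leading eigenvector;
`weighted_clustering_coefficient` is the Onnela form (geometric-mean
triangle intensity on weights rescaled by the global maximum, divided by
$k_i(k_i-1)$), with coefficient 0 at degree $< 2$.

`falff` is the ratio of amplitude-spectrum mass (square root of the
single-taper periodogram, DC excluded) in 0.008–0.09 Hz to the mass over
$(0, \text{Nyquist}]$; amplitude rather than power is the conventional
fALFF definition. `gcor` is each voxel's mean correlation with all other
in-mask voxels (self excluded; an `include_self` flag documents the
$\sim 1/N$ shift). `lcor` is the Gaussian-kernel-weighted mean correlation
with neighbors (FWHM 25 mm, $\sigma = \text{FWHM}/2\sqrt{2\ln 2}$,
truncated at $3\sigma$, self excluded, weights renormalized at mask
edges). Voxel maps are averaged within ROIs by `parcellate`, ignoring
undefined voxels and erroring on fully undefined ROIs.

Feature maps are kept on their physical scale at extraction; any z-scoring
across subjects happens inside the prediction engine only, fold-wise.

## tSNR thresholding

Per-ROI tSNR is mean/SD over time. "Normalized over ROIs" is implemented
as divide-by-max: each subject's profile is divided by its own maximum,
the profiles are averaged, and the group mean re-normalized to maximum 1.
Min–max scaling was rejected because the 0%-threshold endpoint (keep
every ROI) would then fail for the minimum ROI. Thresholding keeps ROIs
*strictly above* `level/100`, which makes both published endpoints exact:
0% keeps all ROIs and 100% keeps none. The group map is computed once on
the full cohort and reused at all sample sizes (the stated practice of the
study design; the mild data-leakage caveat of doing so is acknowledged
here). Note one internal tension in the published description: a map
normalized to maximum 1 always has at least one ROI above any threshold
below 100%, so the claim that levels just above 60% leave no
suprathreshold ROIs cannot hold simultaneously — the package follows the
exact endpoint contract and does not assert that claim.

The package ships synthetic stand-in profiles
(`inst/extdata/tsnr_schaefer400_synthetic.tsv`,
`tsnr_glasser360_synthetic.tsv`) whose suprathreshold count sequences at
0–60% in 5% steps equal the published group-map counts for the two
atlases; the per-ROI values are otherwise arbitrary placements inside the
5% bins those counts imply. They exercise the thresholding contract
end-to-end; they are not the real group maps.

## Prediction engine

Four scenarios define the role of age, gender and TIV: S1 features only;
S2 features with the characteristics treated as confounds; S3 features
concatenated with the characteristics ($n_{roi} + 3$ columns); S4 the
three characteristics alone. Confound removal in S2 follows the study
design exactly: at the *target* level for regression and at the *feature*
level for classification, both fit on outer-train rows only and applied
to the held-out fold.

The cross-validation is five repeats of 5-fold nested CV (the inner loop
is also 5-fold — the source states "nested" without an inner count, so the
inner count is a configuration knob). Ridge regression/classification
searches the fixed 39-value grid from 0 to $10^6$ by inner-fold mean
score; $\lambda = 0$ is solved as minimum-norm least squares via the SVD
pseudo-inverse. The linear SVM uses the heuristic cost
$C = 1 / \frac{1}{N}\sum_n \|x_n\|$ on the z-scored training design, with
no search. Scores are the Spearman correlation (regression) or balanced
accuracy (classification) per outer fold, averaged over the 25
(repeat, fold) pairs. Constant predictions are recorded as score 0 with a
flag; note that because Spearman correlation is rank-based, extreme
regularization shrinks coefficients without driving the score to zero
until predictions become exactly constant.

Sample-size sweeps draw gender-balanced subsamples (`balanced_subsample`)
with per-cell seeds derived deterministically from the master seed and the
cell labels, so any cell can be reproduced in isolation and failures are
isolated per cell. The published sweep grid (100 to 2000 by 50, 2000 to
20,000 by 500) yields 75 unique sizes, while the published bookkeeping
quotes 78 population sizes and model counts $9 \times 4 \times 78 \times
13 = 36{,}504$ and $9 \times 78 \times 13 = 9{,}126$; `ukb_size_grid()`
returns the 75 stated sizes, `count_models()` takes the cardinalities
explicitly, and the discrepancy is documented rather than resolved.

## Identification analysis

`identify_subjects` matches each subject's map of feature X to the most
Pearson-correlated map of feature Y across the population; accuracy is the
fraction of self-matches. Both directions are computed and the headline
value is their mean (one direction is what the source describes; the
fingerprinting literature it adapts averages both, and both are stored).
Confound removal here is whole-sample OLS per ROI — this analysis is
descriptive, not predictive, so no cross-validation is involved. Exact
correlation ties count as misses (conservative, measure-zero under
continuous noise); constant maps exclude the subject with a warning.

## The synthetic-cohort generator

`generate_cohort` draws, per subject, ROI series as a loading-weighted
mixture of shared white-noise latent factors plus per-ROI exact fGn plus
optional white noise, standardized and placed on a constant offset so that
mean/SD equals the requested tSNR exactly. Defaults: 490 time points at
TR 0.735 s; per-subject-per-ROI Hurst exponents uniform on (0.55, 0.85),
the range typical of BOLD; 3 latent factors with loading SD 0.7 (moderate
inter-ROI correlation); tSNR target 50, a typical ROI-level value; age
uniform on 47–79 years and TIV Gaussian with gender-dependent means
(1250/1400 ml, SD 110) emulating a population-imaging age range; gender
balanced by construction because the prediction engine subsamples to
equal counts. Targets are standardized linear combinations of the
z-scored per-ROI Hurst ground truth (weighted by `beta_feat`, scaled by
$1/\sqrt{n_{roi}}$ so the coefficient is comparable to the covariate
betas) and z-scored covariates, plus Gaussian noise; the binary target
thresholds an independent noisy draw of the latent score at its median;
null targets are independent of everything. The default effect sizes make
the continuous target depend on both the feature and the covariates, the
regime in which the scenario ordering S3 ≥ max(S1, S4) is expected.

No generative model of brain–behavior coupling is established for these
data; the linear effect structure is a transparent stand-in that makes
ground truth known, not a claim about biology. Likewise the generator does
not emulate scanner or physiological artifacts (motion, respiration,
ICA-cleaned residual structure), so passing pipeline tests demonstrates
correctness of the statistical machinery on data with known structure —
not performance on real rsfMRI.

## Problem sizes used in the shipped tests

The test suite exercises the estimator-recovery properties at the sizes at
which their tolerances are meaningful (fGn length 8192, 20–50 seeds;
sample-entropy analytic recovery at length 30,000, where the estimator's
standard error is far below the 0.05 tolerance) and the pipeline
properties on cohorts of up to 1000 subjects with 48-sample series and
6–8 ROIs, where nested CV is exact but cheap. The acceptance quantities
(suprathreshold count sequences, factorial model counts, the zero of
range entropy at $r = 1$) are scale-free and computed exactly.

## Known limitations

- GCOR/LCOR pairwise-correlation computation materializes the voxel
  correlation structure and targets the small synthetic volumes used here,
  not whole-brain voxel grids.
- The R/S Hurst estimator carries its usual small-sample bias; the
  package reports it uncorrected.
- `extract_feature_maps` computes fALFF on ROI-mean series when only ROI
  series exist; the voxel-level route (`voxel_feature_roi` +
  `parcellate`) is the faithful construction when 4D data are available.
- Identification on raw synthetic maps with few ROIs saturates quickly;
  interior accuracies require noise, as in the tests.
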