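# complexconn

Temporal-complexity and functional-connectivity features of resting-state
fMRI, and a confound-aware framework for asking a blunt question: **do
rsfMRI-derived features predict behavioral phenotypes any better than age,
gender and total intracranial volume (TIV) do?**

The package is aimed at neuroimaging methodologists who want the full
comparison machinery — feature extraction, ROI selection by temporal SNR,
nested cross-validated prediction under four confound scenarios, and
feature-pair fingerprinting — as tested, reusable code that runs
end-to-end on synthetic cohorts with known ground truth (population
imaging datasets being access-controlled).

## What it implements

**Nine per-ROI rsfMRI features.** Four temporal-complexity measures of
the ROI-mean BOLD series x(t):

- `HE` — Hurst exponent by rescaled-range analysis: the slope of
  log(R/S) vs log window length; H > 0.5 marks long-range dependence;
- `wPE` — weighted permutation entropy (m = 4, τ = 1), ordinal-pattern
  entropy with embedded-vector-variance weights, normalized by log₂(m!);
- `RangeEnB_AUC` — range entropy B (m = 2), a sample-entropy variant on
  the normalized range distance d ∈ [0, 1] (so it is exactly 0 at
  tolerance r = 1), reduced to the area under its r-trajectory;
- `MSE_AUC` — multiscale entropy (m = 2, r = 0.5·SD, scales 1..10), the
  area under the scale trajectory divided by τ_max;

and five connectivity measures: eigenvector centrality `EC` and Onnela
weighted clustering `wCC` on the Pearson connectome; `fALFF`
(amplitude-spectrum fraction in 0.008–0.09 Hz), local correlation `LCOR`
(Gaussian kernel, FWHM 25 mm) and global correlation `GCOR` at voxel
level, averaged within ROIs.

**tSNR thresholding.** Per-ROI mean/SD, per-subject max-normalization,
group averaging, and strict percent-of-maximum ROI selection (0% keeps
all ROIs, 100% keeps none).

**Prediction.** Four scenarios for the role of age/gender/TIV (features
raw; features deconfounded — target-level for regression, feature-level
for classification; features + covariates; covariates only), five repeats
of 5-fold nested CV, ridge models over a fixed 39-value λ grid and linear
SVM with the heuristic cost C = 1 / mean‖xₙ‖, Spearman ρ / balanced
accuracy scoring, balanced male/female subsampling, and factorial
sample-size × tSNR-level sweeps.

**Identification.** Fingerprinting across feature pairs: accuracy = the
proportion of subjects whose map of feature X correlates best with their
own map of feature Y across the population.

**Synthetic cohorts.** Exact fractional-Gaussian-noise simulation
(circulant embedding), latent-factor inter-ROI correlation, exact per-ROI
tSNR control, covariates, and targets that are noisy linear functions of
the per-ROI Hurst ground truth and/or covariates, plus null targets.

## Worked example

```r
library(complexconn)

spec <- cohort_spec(n_subjects = 200, n_rois = 10, n_timepoints = 490,
                    tsnr_target = seq(20, 60, length.out = 10),
                    beta_feat = 3, target_noise_sd = 0.5, seed = 42)
cohort <- generate_cohort(spec)

maps <- extract_feature_maps(cohort$series, cohort$tr_seconds,
                             features = c("HE", "wPE", "fALFF"))
round(maps$HE[1:3, 1:5], 3)
#>       [,1]  [,2]  [,3]  [,4]  [,5]
#> [1,] 0.688 0.683 0.675 0.620 0.789
#> [2,] 0.763 0.637 0.575 0.895 0.729
#> [3,] 0.683 0.492 0.698 0.554 0.574

profile <- normalize_and_group_mean(lapply(cohort$series, roi_tsnr))
suprathreshold_counts(profile, c(0, 40, 60, 80))
#>  0 40 60 80
#> 10  9  6  3

design <- assemble_design(maps$HE, cohort$covariates,
                          "S3_features_plus_covariates")
res <- nested_cv_predict(design, cohort$targets$target_cont,
                         model_spec("ridge", "regression"),
                         cv_config(seed = 1))
res
#> nested-CV regression (ridge), n = 200, scenario S3_features_plus_covariates
#>   mean Spearman rho over 25 folds: 0.5253 (SD 0.0820)

identify_subjects(maps$HE, maps$wPE)
#> identification over 200 subjects: accuracy 0.013 (x->y 0.010, y->x 0.015)
```

Reading the output: the extracted `HE` map recovers each subject's per-ROI
Hurst exponents (generated in (0.55, 0.85)); the graded tSNR targets
translate into a normalized group profile whose suprathreshold counts
shrink as the threshold rises; combining the HE feature with
age/gender/TIV (scenario S3) predicts the synthetic target — built from
the Hurst ground truth plus covariates — at mean Spearman ρ ≈ 0.53 across
the 25 outer folds; and two features that share no individual-specific
structure at 10 ROIs identify subjects at roughly the 1/n chance rate.

`run_experiment()` (or the thin wrapper
`inst/scripts/run_experiment.R --config cfg.yaml --out DIR`) chains the
whole pipeline from a YAML configuration and writes tidy CSV/TSV result
tables.

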