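Package: complexconn
Title: Temporal Complexity and Connectivity Features of rsfMRI for
    Behavioral Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts four temporal-complexity measures (Hurst exponent via
    rescaled-range analysis, weighted permutation entropy, range entropy and
    its tolerance-domain AUC, multiscale entropy and its scale-domain AUC)
    and five functional-connectivity measures (eigenvector centrality and
    weighted clustering coefficient on the Pearson connectome; fALFF, local
    correlation and global correlation at voxel level with ROI averaging)
    from parcellated resting-state fMRI time series.  Provides ROI-wise
    temporal signal-to-noise thresholding, a confound-aware nested
    cross-validation engine with four scenarios for handling age, gender and
    total intracranial volume (ridge models and heuristic-C linear SVM),
    sample-size sweeps with balanced male/female subsampling, and a
    feature-pair identification (fingerprinting) analysis.  Includes a
    synthetic-cohort generator with exact fractional-Gaussian-noise
    simulation, controllable inter-ROI correlation structure, tSNR and
    linear brain-behavior effects, so that the complete pipeline can be
    exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
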