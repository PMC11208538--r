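# Experiment orchestration: a validated configuration drives synthetic
# cohort generation (or file input), feature extraction, tSNR-based ROI
# selection, the prediction sweep and the identification analysis, with
# tidy result tables written to an output directory.

#' Build and validate an experiment configuration
#'
#' @param cohort A [cohort_spec()] (synthetic input mode) or `NULL` when
#'   `series_paths` are given (file mode).
#' @param series_paths,covariates_path,targets_path File-mode inputs: one
#'   ROI-series TSV per subject plus subject-keyed covariate/target tables.
#' @param features Feature names to extract (see [extract_feature_maps()]).
#' @param targets Target column names to predict.
#' @param scenarios Scenario subset (default all four).
#' @param models List of [model_spec()]s.
#' @param cv A [cv_config()].
#' @param sizes Sample-size grid.
#' @param tsnr_levels tSNR threshold levels in percent.
#' @param master_seed Master seed for all per-cell streams.
#' @param run_identification Whether to run the pairwise identification
#'   analysis on the extracted maps.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = NULL, series_paths = NULL,
                              covariates_path = NULL, targets_path = NULL,
                              features = c("HE", "wPE", "fALFF"),
                              targets = c("target_cont", "null_cont"),
                              scenarios = SCENARIOS,
                              models = list(model_spec("ridge",
                                                       "regression")),
                              cv = cv_config(),
                              sizes = c(100L, 150L),
                              tsnr_levels = 0,
                              master_seed = 1L,
                              run_identification = TRUE) {
  if (is.null(cohort) && is.null(series_paths))
    stop("either a cohort spec (synthetic mode) or series_paths ",
         "(file mode) is required", call. = FALSE)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  if (!is.null(series_paths)) {
    missing <- series_paths[!file.exists(series_paths)]
    if (length(missing) > 0L)
      stop("missing input file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    for (p in c(covariates_path, targets_path))
      if (is.null(p) || !file.exists(p))
        stop("file mode requires existing covariates_path and ",
             "targets_path", call. = FALSE)
  }
  features <- match.arg(features, ROI_FEATURES, several.ok = TRUE)
  scenarios <- match.arg(scenarios, SCENARIOS, several.ok = TRUE)
  stopifnot(inherits(cv, "cv_config"), length(sizes) >= 1L,
            all(tsnr_levels >= 0), all(tsnr_levels <= 100))
  for (m in models) stopifnot(inherits(m, "model_spec"))
  structure(list(cohort = cohort, series_paths = series_paths,
                 covariates_path = covariates_path,
                 targets_path = targets_path, features = features,
                 targets = targets, scenarios = scenarios, models = models,
                 cv = cv, sizes = as.integer(sizes),
                 tsnr_levels = tsnr_levels,
                 master_seed = as.integer(master_seed),
                 run_identification = isTRUE(run_identification)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Understands the synthetic input mode: a `cohort:` block with
#' [cohort_spec()] fields plus top-level `features`, `targets`,
#' `scenarios`, `models` (list of `{model, task}`), `sizes`,
#' `tsnr_levels`, `cv: {n_repeats, n_outer_folds, n_inner_folds}` and
#' `master_seed`.
#'
#' @param path Path to the YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) do.call(cohort_spec, y$cohort)
  models <- lapply(y$models %||% list(list(model = "ridge",
                                           task = "regression")),
                   function(m) model_spec(m$model, m$task))
  cv <- if (!is.null(y$cv)) do.call(cv_config, y$cv) else cv_config()
  experiment_config(cohort = cohort,
                    features = y$features %||% c("HE", "wPE", "fALFF"),
                    targets = y$targets %||% c("target_cont", "null_cont"),
                    scenarios = y$scenarios %||% SCENARIOS,
                    models = models, cv = cv,
                    sizes = y$sizes %||% c(100L, 150L),
                    tsnr_levels = y$tsnr_levels %||% 0,
                    master_seed = y$master_seed %||% 1L,
                    run_identification = y$run_identification %||% TRUE)
}

#' Run a full experiment
#'
#' Synthetic mode: generates the cohort, extracts the requested feature
#' maps, computes the normalized group tSNR profile, runs the prediction
#' sweep for every model spec and (optionally) the pairwise identification
#' analysis. Deterministic given the configuration's master seed. When
#' `out_dir` is given, the resolved configuration, feature maps, tSNR
#' profile and result tables are written there.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `predictions` (data frame), `identification`
#'   (accuracy matrix or `NULL`), `tsnr_profile`, `feature_maps`,
#'   `cohort`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(config$cohort)) {
    series <- lapply(config$series_paths, read_roi_series_tsv)
    covariates <- read_subject_table_tsv(config$covariates_path)
    targets_tab <- read_subject_table_tsv(config$targets_path)
    tr <- 0.735
    cohort <- list(series = series, covariates = covariates,
                   targets = targets_tab, tr_seconds = tr)
  } else {
    cohort <- generate_cohort(config$cohort)
    tr <- cohort$tr_seconds
  }
  missing_targets <- setdiff(config$targets, names(cohort$targets))
  if (length(missing_targets) > 0L)
    stop("unknown target(s): ", paste(missing_targets, collapse = ", "),
         call. = FALSE)
  maps <- extract_feature_maps(cohort$series, tr, config$features)
  tsnr_profile <- normalize_and_group_mean(lapply(cohort$series, roi_tsnr))
  targets <- lapply(config$targets, function(t) cohort$targets[[t]])
  names(targets) <- config$targets
  preds <- lapply(config$models, function(ms) {
    binary <- vapply(targets, function(t) length(unique(t)) == 2L,
                     logical(1))
    use <- if (ms$task == "classification") targets[binary]
           else targets[!binary]
    if (length(use) == 0L) return(NULL)
    sample_size_sweep(maps, use, cohort$covariates,
                      scenarios = config$scenarios, spec = ms,
                      sizes = config$sizes,
                      tsnr_profile = tsnr_profile,
                      tsnr_levels = config$tsnr_levels, cv = config$cv,
                      master_seed = config$master_seed)
  })
  predictions <- do.call(rbind, preds[!vapply(preds, is.null, logical(1))])
  ident <- if (config$run_identification && length(maps) >= 2L)
    identification_matrix(maps, cohort$covariates[, c("age", "gender",
                                                      "tiv")])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(predictions, file.path(out_dir, "predictions.csv"))
    utils::write.table(
      data.frame(roi_id = seq_along(tsnr_profile), tsnr = tsnr_profile),
      file.path(out_dir, "tsnr_profile.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    for (f in names(maps))
      write_feature_map_tsv(maps[[f]],
                            file.path(out_dir, paste0("map_", f, ".tsv")))
    if (!is.null(ident))
      write_results_csv(data.frame(feature = rownames(ident), ident,
                                   check.names = FALSE),
                        file.path(out_dir, "identification.csv"))
    resolved <- unclass(config)
    resolved$cohort <- unclass(config$cohort)
    resolved$models <- lapply(config$models, unclass)
    resolved$cv <- unclass(config$cv)
    yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  }
  list(predictions = predictions, identification = ident,
       tsnr_profile = tsnr_profile, feature_maps = maps, cohort = cohort)
}
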