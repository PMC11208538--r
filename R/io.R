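# Readers and writers for the pipeline's on-disk formats: TSV for ROI
# series, feature maps, covariates and targets; CSV for result tables;
# NIfTI-1 (via RNifti) for 4D volumes and integer label volumes.

#' Read and write per-subject ROI time series as TSV
#'
#' The file is `n_roi x n_timepoints` with a header row of ROI ids; one
#' file per subject.
#'
#' @param series `n_roi x n_timepoints` numeric matrix.
#' @param path Output/input file path.
#' @return `read_roi_series_tsv()` returns the matrix with ROI ids as row
#'   names.
#' @export
write_roi_series_tsv <- function(series, path) {
  stopifnot(is.matrix(series))
  tab <- data.frame(roi_id = rownames(series) %||% seq_len(nrow(series)),
                    series, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_series_tsv
#' @export
read_roi_series_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  colnames(m) <- NULL
  m
}

#' Read and write subject-keyed tables (covariates, targets) as TSV
#'
#' Tables carry a header and a `subject_id` key column.
#'
#' @param tab Data frame with a `subject_id` column.
#' @param path File path.
#' @return `read_subject_table_tsv()` returns the data frame.
#' @export
write_subject_table_tsv <- function(tab, path) {
  stopifnot("subject_id" %in% names(tab))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_table_tsv
#' @export
read_subject_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Read and write feature maps as TSV
#'
#' A feature map table is `n_subjects x (1 + n_roi)`: a `subject_id` column
#' followed by one column per ROI.
#'
#' @param map `n_subjects x n_roi` numeric matrix.
#' @param path File path.
#' @return `read_feature_map_tsv()` returns the matrix.
#' @export
write_feature_map_tsv <- function(map, path) {
  stopifnot(is.matrix(map))
  tab <- data.frame(subject_id = rownames(map) %||% seq_len(nrow(map)),
                    map, check.names = FALSE)
  names(tab)[-1L] <- colnames(map) %||% paste0("roi_", seq_len(ncol(map)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_map_tsv
#' @export
read_feature_map_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}

#' Read a 4D NIfTI volume and its ROI label volume
#'
#' Label volumes with non-contiguous positive ids are remapped to
#' contiguous `1..K` with a message reporting the mapping.
#'
#' @param data_path Path to the 4D NIfTI image.
#' @param label_path Path to the 3D integer label NIfTI image.
#' @param tr_seconds Repetition time (read from the file header if `NULL`).
#' @return A [voxel_image()]; the label remap table (if any) is attached as
#'   attribute `label_map`.
#' @export
read_voxel_image_nifti <- function(data_path, label_path,
                                   tr_seconds = NULL) {
  img <- RNifti::readNifti(data_path)
  dat <- as.array(img)
  dat <- array(as.double(dat), dim(dat)) # strip NIfTI attributes
  if (length(dim(dat)) != 4L) stop("expected a 4D NIfTI image",
                                   call. = FALSE)
  lab <- array(as.integer(round(as.array(RNifti::readNifti(label_path)))),
               dim = dim(dat)[1:3])
  if (is.null(tr_seconds)) tr_seconds <- RNifti::pixdim(img)[4L]
  ids <- sort(unique(lab[lab > 0]))
  map_tab <- NULL
  if (length(ids) > 0L && !identical(ids, seq_along(ids))) {
    map_tab <- data.frame(original = ids, remapped = seq_along(ids))
    lab2 <- lab
    for (k in seq_along(ids)) lab2[lab == ids[k]] <- k
    lab <- lab2
    message("non-contiguous ROI labels remapped: ",
            paste(ids, "->", seq_along(ids), collapse = ", "))
  }
  vi <- voxel_image(dat, RNifti::pixdim(img)[1:3], lab, tr_seconds)
  attr(vi, "label_map") <- map_tab
  vi
}

#' Write a voxel image (and its labels) as NIfTI-1
#'
#' @param img A [voxel_image()].
#' @param data_path,label_path Output paths.
#' @return Invisibly, the data path.
#' @export
write_voxel_image_nifti <- function(img, data_path, label_path) {
  ni <- RNifti::asNifti(img$data)
  RNifti::pixdim(ni) <- c(img$voxel_size_mm, img$tr_seconds)
  RNifti::writeNifti(ni, data_path)
  nl <- RNifti::asNifti(img$labels)
  RNifti::pixdim(nl) <- img$voxel_size_mm
  RNifti::writeNifti(nl, label_path)
  invisible(data_path)
}

#' Read and write prediction-result tables as CSV
#'
#' @param results Data frame as returned by [sample_size_sweep()].
#' @param path File path.
#' @return `read_results_csv()` returns the data frame.
#' @export
write_results_csv <- function(results, path) {
  utils::write.table(results, path, sep = ",", row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
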