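#' Dense intensity volume for one patient
#'
#' Fills the grid with background noise and overwrites lesion voxels with
#' their stored intensities (later lesions win where lesions overlap).
#'
#' @param x a `lesion_set`.
#' @param background_mean,background_sd background tissue distribution
#'   (HU-like).
#' @return 3D numeric array.
#' @export
intensity_volume <- function(x, background_mean = 30, background_sd = 5) {
  stopifnot(inherits(x, "lesion_set"))
  v <- array(stats::rnorm(prod(x$dim), background_mean, background_sd), x$dim)
  for (les in x$lesions) v[les$voxels] <- les$intensity
  v
}

#' Write a synthetic cohort to disk
#'
#' Exports the atlas and per-patient volumes as NIfTI-1 (identity
#' orientation, shared grid), the clinical table as CSV, the region table
#' as CSV, and the generating parameters as JSON.
#'
#' @param cohort an `ich_cohort`.
#' @param dir output directory (created if needed).
#' @param images if TRUE also write dense intensity volumes (slow for
#'   large cohorts).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, images = FALSE) {
  stopifnot(inherits(cohort, "ich_cohort"))
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (images)
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
  RNifti::writeNifti(cohort$atlas$volume, file.path(dir, "atlas.nii.gz"))
  utils::write.csv(cohort$atlas$region_table,
                   file.path(dir, "region_table.csv"), row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  for (ls in cohort$lesions) {
    RNifti::writeNifti(as_mask(ls),
                       file.path(dir, "masks",
                                 paste0(ls$patient_id, "_mask.nii.gz")))
    if (images) {
      bg <- cohort$truth$placement[[1]]$intensity
      RNifti::writeNifti(intensity_volume(ls, bg$background_mean,
                                          bg$background_sd),
                         file.path(dir, "images",
                                   paste0(ls$patient_id, "_ct.nii.gz")))
    }
  }
  truth <- cohort$truth
  truth$placement <- lapply(truth$placement, unclass)
  truth$outcome <- unclass(truth$outcome)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a labeled atlas from NIfTI + CSV
#'
#' @param volume_file NIfTI file of integer region labels.
#' @param region_file CSV with columns `label`, `name`, `structure`.
#' @return `labeled_atlas`.
#' @export
read_atlas <- function(volume_file, region_file) {
  vol <- as.array(RNifti::readNifti(volume_file))
  tab <- utils::read.csv(region_file, stringsAsFactors = FALSE)
  labeled_atlas(vol, tab)
}

#' Read a binary lesion mask on the atlas grid
#'
#' The mask must share the atlas grid exactly; a shape mismatch is an
#' error (no resampling is attempted).
#'
#' @param file NIfTI mask file.
#' @param atlas `labeled_atlas` defining the expected grid.
#' @return 3D integer array of 0/1.
#' @export
read_mask <- function(file, atlas) {
  m <- as.array(RNifti::readNifti(file))
  if (!identical(dim(m), dim(atlas$volume)))
    stop(sprintf("mask %s has grid %s but the atlas grid is %s",
                 basename(file), paste(dim(m), collapse = "x"),
                 paste(dim(atlas$volume), collapse = "x")))
  storage.mode(m) <- "integer"
  (m != 0L) + 0L
}
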