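#' Write a CT volume as NIfTI with a metadata sidecar
#'
#' The voxel grid is written as NIfTI (reordered to the conventional
#' x, y, z axis order). NIfTI headers assume uniform slice spacing, so the
#' per-slice thickness vector and the HU calibration are written to a JSON
#' sidecar named `<volume>.meta.json`; the sidecar is authoritative for
#' slice geometry.
#'
#' @param volume A [ct_volume()].
#' @param path Output path; `.nii.gz` is appended if no NIfTI extension is
#'   present.
#' @return Invisibly, a list with the NIfTI `path` and the sidecar
#'   `meta_path`.
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  # [slice,row,col] -> [x,y,z]
  arr <- aperm(volume$values, c(3, 2, 1))
  th <- volume$slice_thicknesses_mm
  img <- RNifti::asNifti(arr, pixdim = c(volume$in_plane_spacing_mm,
                                         volume$in_plane_spacing_mm,
                                         mean(th)))
  RNifti::writeNifti(img, path)
  meta_path <- sub("\\.nii(\\.gz)?$", ".meta.json", path)
  jsonlite::write_json(
    list(
      in_plane_spacing_mm = volume$in_plane_spacing_mm,
      slice_thicknesses_mm = th,
      hu_calibration = list(slope = 1, intercept = 0,
                            note = "voxel values are Hounsfield units")
    ),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(path = path, meta_path = meta_path))
}

#' Read a CT volume from NIfTI plus its sidecar
#'
#' @param path Path to the NIfTI file; the sidecar `<volume>.meta.json` is
#'   looked up next to it (or pass `meta_path`).
#' @param meta_path Optional explicit sidecar path.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.nii(\\.gz)?$", ".meta.json", path)
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  arr <- aperm(as.array(img), c(3, 2, 1))  # [x,y,z] -> [slice,row,col]
  cal <- meta$hu_calibration
  if (!is.null(cal)) arr <- arr * cal$slope + cal$intercept
  ct_volume(arr, meta$in_plane_spacing_mm, meta$slice_thicknesses_mm)
}

#' Write a cohort to disk
#'
#' Writes each phantom volume as NIfTI + sidecar and the cohort manifest
#' (per-phantom spec fields and ground truth) as CSV.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$phantoms)) {
    write_ct_volume(cohort$phantoms[[i]]$volume,
                    file.path(dir, sprintf("phantom_%03d.nii.gz", i)))
  }
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(cohort$manifest, manifest_path)
  invisible(manifest_path)
}
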