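#' CT-like volume with per-slice thickness
#'
#' Container for a 3D grid of Hounsfield-unit (HU) values. The array is
#' ordered `[slice, row, column]`, slice index increasing inferior to
#' superior. In-plane spacing is isotropic; slice thickness may vary
#' through the scan, so it is carried as a vector with one entry per slice
#' rather than a scalar.
#'
#' @param values 3D numeric array of HU, dimension `[n_slices, n_rows, n_cols]`.
#' @param in_plane_spacing_mm Isotropic in-plane voxel spacing in mm.
#' @param slice_thicknesses_mm Numeric vector of per-slice thickness in mm,
#'   length equal to `dim(values)[1]`.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, in_plane_spacing_mm, slice_thicknesses_mm) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array ordered [slice, row, column]", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  if (!is.numeric(in_plane_spacing_mm) || length(in_plane_spacing_mm) != 1L ||
      in_plane_spacing_mm <= 0) {
    stop("`in_plane_spacing_mm` must be a single positive number", call. = FALSE)
  }
  if (length(slice_thicknesses_mm) != dim(values)[1]) {
    stop("`slice_thicknesses_mm` must have one entry per slice", call. = FALSE)
  }
  if (any(slice_thicknesses_mm <= 0)) {
    stop("slice thicknesses must all be positive", call. = FALSE)
  }
  structure(
    list(
      values = values,
      in_plane_spacing_mm = as.numeric(in_plane_spacing_mm),
      slice_thicknesses_mm = as.numeric(slice_thicknesses_mm)
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  th <- x$slice_thicknesses_mm
  cat(sprintf(
    "<ct_volume> %d slices x %d rows x %d cols, %.2f mm in-plane, slice thickness %s mm\n",
    d[1], d[2], d[3], x$in_plane_spacing_mm,
    if (length(unique(th)) == 1L) format(th[1]) else
      paste0("variable (", format(min(th)), "-", format(max(th)), ")")
  ))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

n_slices <- function(volume) dim(volume$values)[1]

#' Binary lesion mask congruent with a CT volume
#'
#' @param voxels Logical 3D array with the same dimensions as the parent
#'   volume's values.
#' @param provenance A list recording how the mask was obtained (threshold
#'   window, connectivity, seed point, edits applied).
#'
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, provenance = list()) {
  if (!is.logical(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a logical 3D array", call. = FALSE)
  }
  structure(list(voxels = voxels, provenance = provenance), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d voxels on a %s grid\n",
              sum(x$voxels), paste(dim(x$voxels), collapse = " x ")))
  invisible(x)
}

check_congruent <- function(mask, volume) {
  if (!identical(dim(mask$voxels), dim(volume$values))) {
    stop("mask and volume grids are not congruent", call. = FALSE)
  }
}

check_mask_nonempty <- function(mask) {
  if (!any(mask$voxels)) stop("mask is empty", call. = FALSE)
}

# Lower z face of each slice plus the top face, in mm (length n_slices + 1).
slice_z_breaks <- function(volume) {
  c(0, cumsum(volume$slice_thicknesses_mm))
}
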