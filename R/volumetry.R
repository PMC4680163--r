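#' Per-slice haemorrhage areas
#'
#' Area of the masked region on each axial slice, in cm^2: voxel count
#' times the squared in-plane spacing. Lesion-free slices report 0.
#'
#' @param mask A [lesion_mask()].
#' @param volume The parent [ct_volume()].
#' @return A tibble with columns `slice`, `area_cm2`, `thickness_mm`.
#' @export
slice_areas <- function(mask, volume) {
  check_congruent(mask, volume)
  counts <- apply(mask$voxels, 1, sum)
  tibble::tibble(
    slice = seq_along(counts),
    area_cm2 = counts * volume$in_plane_spacing_mm^2 / 100,
    thickness_mm = volume$slice_thicknesses_mm
  )
}

# Boundary voxels of a logical slice (4-neighbour erosion complement).
slice_boundary <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  er <- m
  er[-1, ] <- er[-1, ] & m[-ny, ]
  er[-ny, ] <- er[-ny, ] & m[-1, ]
  er[, -1] <- er[, -1] & m[, -nx]
  er[, -nx] <- er[, -nx] & m[, -1]
  # voxels on the array edge are boundary whenever present
  edge <- row(m) %in% c(1L, ny) | col(m) %in% c(1L, nx)
  m & (!er | edge)
}

#' Measure the A and B diameters
#'
#' A is the longest lesion diameter in the axial plane: per slice, the
#' maximum pairwise distance between points of the sub-voxel boundary
#' contour (marching squares at the 0.5 level, reduced to its convex
#' hull), maximised over slices, ties broken toward the lower slice index.
#' B is the maximal extent of the same slice's contour measured
#' perpendicular to the A direction. The contour is taken on the
#' antialiased slice, which places the boundary on the underlying smooth
#' shape: a single voxel has extent one spacing, and an axis-aligned
#' rendered ellipse measures its true axes without the half-voxel
#' truncation or the staircase-corner inflation that voxel-centre
#' distances suffer.
#'
#' @param mask A non-empty [lesion_mask()].
#' @param volume The parent [ct_volume()].
#' @return A one-row tibble: `A_cm`, `B_cm`, `a_slice_index`.
#' @export
measure_A_B <- function(mask, volume) {
  check_congruent(mask, volume)
  check_mask_nonempty(mask)
  sp <- volume$in_plane_spacing_mm
  best <- list(A = -Inf, slice = NA_integer_, dir = c(1, 0), pts = NULL)
  for (k in seq_len(dim(mask$voxels)[1])) {
    m <- mask$voxels[k, , ]
    if (!any(m)) next
    pts <- slice_contour_points(m, sp)
    h <- grDevices::chull(pts)
    hx <- pts[h, 1]; hy <- pts[h, 2]
    dx <- outer(hx, hx, "-"); dy <- outer(hy, hy, "-")
    d2 <- dx^2 + dy^2
    i <- which.max(d2)
    a_k <- sqrt(d2[i])
    dir_k <- if (a_k > 0) c(dx[i], dy[i]) / a_k else c(1, 0)
    if (a_k > best$A + 1e-9) {
      best <- list(A = a_k, slice = k, dir = dir_k, pts = pts)
    }
  }
  perp <- c(-best$dir[2], best$dir[1])
  proj <- best$pts[, 1] * perp[1] + best$pts[, 2] * perp[2]
  tibble::tibble(
    A_cm = best$A / 10,
    B_cm = (max(proj) - min(proj)) / 10,
    a_slice_index = best$slice
  )
}

# Vertices (x, y in mm) of the marching-squares 0.5-level contour of a
# binary slice, on a zero-padded grid so contours always close. The slice
# is antialiased with a 3x3 box filter first, which places the contour on
# the underlying smooth boundary instead of on staircase corners (whose
# oblique chords overestimate diameters); regions too thin to survive
# smoothing fall back to the raw binary contour (a single voxel then
# yields a diamond of extent one spacing).
slice_contour_points <- function(m, spacing_mm) {
  ny <- nrow(m); nx <- ncol(m)
  padded <- matrix(0, ny + 4L, nx + 4L)
  padded[3:(ny + 2L), 3:(nx + 2L)] <- as.numeric(m)
  ycoord <- (seq_len(ny + 4L) - 2.5) * spacing_mm
  xcoord <- (seq_len(nx + 4L) - 2.5) * spacing_mm
  pts_at <- function(z) {
    cl <- grDevices::contourLines(x = ycoord, y = xcoord, z = z, levels = 0.5)
    do.call(rbind, lapply(cl, function(cc) cbind(x = cc$y, y = cc$x)))
  }
  pts <- pts_at(box3_smooth(padded))
  if (is.null(pts) || nrow(pts) < 2L) pts <- pts_at(padded)
  pts
}

# 3x3 box filter with replicated edges.
box3_smooth <- function(z) {
  n1 <- nrow(z); n2 <- ncol(z)
  sh <- function(d1, d2) z[pmin(pmax(seq_len(n1) + d1, 1L), n1),
                           pmin(pmax(seq_len(n2) + d2, 1L), n2)]
  acc <- z * 0
  for (d1 in -1:1) for (d2 in -1:1) acc <- acc + sh(d1, d2)
  acc / 9
}

#' Craniocaudal extent C (standard rule)
#'
#' Sum of slice thicknesses over slices showing any haemorrhage. With
#' uniform slices this is the classic "slice thickness times number of
#' slices"; summation is the faithful generalisation when thickness varies
#' through the scan.
#'
#' @inheritParams measure_A_B
#' @return C in cm.
#' @export
c_standard <- function(mask, volume) {
  check_congruent(mask, volume)
  check_mask_nonempty(mask)
  has <- apply(mask$voxels, 1, any)
  sum(volume$slice_thicknesses_mm[has]) / 10
}

#' Craniocaudal extent C (modified rule)
#'
#' Weights each slice by its haemorrhage area relative to the largest
#' slice: weight 0 below 25% of the maximum area, 0.5 from 25% to 75%
#' (boundary values inclusive), 1 above 75%. C is the weighted sum of
#' slice thicknesses.
#'
#' @param areas_cm2 Per-slice areas (cm^2), e.g. from [slice_areas()].
#' @param thicknesses_mm Per-slice thicknesses (mm).
#' @return C in cm.
#' @export
c_modified <- function(areas_cm2, thicknesses_mm) {
  if (length(areas_cm2) != length(thicknesses_mm)) {
    stop("areas and thicknesses must align per slice", call. = FALSE)
  }
  amax <- max(areas_cm2)
  if (!is.finite(amax) || amax <= 0) {
    stop("at least one slice must have positive area", call. = FALSE)
  }
  rel <- areas_cm2 / amax
  eps <- 1e-9
  w <- ifelse(rel > 0.75 + eps, 1, ifelse(rel >= 0.25 - eps, 0.5, 0))
  sum(w * thicknesses_mm) / 10
}

#' ABC/2 volume from a diameter triple
#'
#' The bedside ellipsoid approximation: volume = A x B x C / 2, all
#' lengths in cm, volume in cm^3. For a true ellipsoid this returns 3/pi
#' (about 0.955) of the exact volume pi/6 x A x B x C.
#'
#' @param A_cm,B_cm,C_cm Diameters in cm; `A_cm >= B_cm > 0`, `C_cm > 0`.
#' @return Volume in cm^3.
#' @export
abc2 <- function(A_cm, B_cm, C_cm) {
  if (any(c(A_cm, B_cm, C_cm) <= 0)) {
    stop("all of A, B, C must be positive", call. = FALSE)
  }
  if (B_cm > A_cm + 1e-9) stop("A must be the longest axial diameter (A >= B)",
                               call. = FALSE)
  A_cm * B_cm * C_cm / 2
}

#' Semiautomated segmentation (SAS) volume
#'
#' Planimetric volume: per-slice haemorrhage areas summed after weighting
#' by slice thickness. Equal to voxel count times voxel volume when
#' thickness is uniform.
#'
#' @inheritParams measure_A_B
#' @return A one-row tibble: `method`, `volume_cm3`.
#' @export
sas_volume <- function(mask, volume) {
  sa <- slice_areas(mask, volume)
  check_mask_nonempty(mask)
  tibble::tibble(
    method = "sas",
    volume_cm3 = sum(sa$area_cm2 * sa$thickness_mm / 10)
  )
}

#' Automatic volume calculation (AVC) by 3D region growing
#'
#' Grows a 26-connected region from a seed point within the HU window
#' (threshold-constrained 3D region growing over the entire series) and
#' reports voxel count times voxel volume. Mirroring the behaviour of the
#' clinical tooling it models, it refuses scans with varying slice
#' thickness unless explicitly overridden.
#'
#' @param volume A [ct_volume()].
#' @param params A [seg_params()] with `seed_point` set.
#' @param allow_variable_thickness Set `TRUE` to process variable-thickness
#'   scans anyway (volume is then summed per-slice).
#' @return A one-row tibble: `method`, `volume_cm3`.
#' @export
avc_volume <- function(volume, params, allow_variable_thickness = FALSE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(params, "seg_params"))
  if (is.null(params$seed_point)) {
    stop("AVC requires a seed point near the haemorrhage centre", call. = FALSE)
  }
  th <- volume$slice_thicknesses_mm
  if (max(th) - min(th) > 1e-9 && !allow_variable_thickness) {
    stop("variable slice thickness unsupported", call. = FALSE)
  }
  grow_params <- seg_params(params$hu_low, params$hu_high, connectivity = 26L,
                            seed_point = params$seed_point)
  mask <- segment_threshold(volume, grow_params)
  counts <- apply(mask$voxels, 1, sum)
  tibble::tibble(
    method = "avc",
    volume_cm3 = sum(counts * volume$in_plane_spacing_mm^2 * th) / 1000
  )
}

#' Visual size category from the longest diameter
#'
#' Ordered categories used for visual size adjudication, based on the
#' longest diameter in any plane: `<3`, `3-4.9`, `5-8`, `>8` cm. The bins
#' are `[0,3)`, `[3,5)`, `[5,8]`, `(8,Inf)`; 5.0 cm falls in `5-8` because
#' the printed categories are adjacent and exhaustive.
#'
#' @param longest_diameter_cm Positive diameter(s) in cm.
#' @return An ordered factor with levels `<3`, `3-4.9`, `5-8`, `>8`.
#' @export
size_category <- function(longest_diameter_cm) {
  if (any(longest_diameter_cm <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  lv <- c("<3", "3-4.9", "5-8", ">8")
  idx <- findInterval(longest_diameter_cm, c(3, 5, 8 + 1e-9)) + 1L
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Measure a volume with every method
#'
#' Runs threshold segmentation, then the four volume-measurement methods:
#' standard ABC/2, modified ABC/2 (both from the measured diameter triple),
#' SAS planimetry and, on uniform-thickness scans, AVC region growing
#' seeded at the mask centroid.
#'
#' @param volume A [ct_volume()] (or a `ct_phantom`, whose volume is used).
#' @param params A [seg_params()]; for phantoms [midpoint_window()] is a
#'   sensible default.
#' @param include_avc Include the AVC method where the scan permits it.
#' @return A tibble with one row per method: `method`, `A_cm`, `B_cm`,
#'   `C_cm`, `volume_cm3` (diameters are `NA` for the planimetric methods).
#' @export
measure_all <- function(volume, params = seg_params(), include_avc = TRUE) {
  if (inherits(volume, "ct_phantom")) volume <- volume$volume
  mask <- segment_threshold(volume, params)
  measure_all_from_mask(mask, volume, params, include_avc = include_avc)
}

# Measurement core shared by direct measurement and the observer model.
# `ab_scale` multiplies the measured A and B diameters (observer error);
# with the defaults the output is the unperturbed measurement.
measure_all_from_mask <- function(mask, volume, params, include_avc = TRUE,
                                  ab_scale = c(1, 1)) {
  sa <- slice_areas(mask, volume)
  ab <- measure_A_B(mask, volume)
  A <- ab$A_cm * ab_scale[1]
  B <- ab$B_cm * ab_scale[2]
  if (B > A) { tmp <- A; A <- B; B <- tmp }  # keep A the longer axis
  C_std <- c_standard(mask, volume)
  C_mod <- c_modified(sa$area_cm2, sa$thickness_mm)
  out <- tibble::tibble(
    method = c("abc2", "modified_abc2", "sas"),
    A_cm = c(A, A, NA),
    B_cm = c(B, B, NA),
    C_cm = c(C_std, C_mod, NA),
    volume_cm3 = c(abc2(A, B, C_std), abc2(A, B, C_mod),
                   sas_volume(mask, volume)$volume_cm3)
  )
  th <- volume$slice_thicknesses_mm
  if (include_avc && max(th) - min(th) <= 1e-9) {
    seedv <- mask_centroid_voxel(mask, volume, params)
    avc <- avc_volume(volume, seg_params(params$hu_low, params$hu_high,
                                         seed_point = seedv))
    out <- dplyr::bind_rows(out, tibble::tibble(
      method = "avc", A_cm = NA, B_cm = NA, C_cm = NA,
      volume_cm3 = avc$volume_cm3
    ))
  }
  out
}

# An in-mask voxel close to the mask centroid. When a volume and window
# are supplied, only voxels whose HU lies in the window are candidates
# (hole filling can admit mask voxels outside it, which could not seed
# region growing).
mask_centroid_voxel <- function(mask, volume = NULL, params = NULL) {
  keep <- mask$voxels
  if (!is.null(volume) && !is.null(params)) {
    inwin <- volume$values >= params$hu_low & volume$values <= params$hu_high
    if (any(keep & inwin)) keep <- keep & inwin
  }
  vx <- which(keep, arr.ind = TRUE)
  cen <- colMeans(vx)
  i <- which.min(rowSums(sweep(vx, 2, cen)^2))
  as.integer(vx[i, ])
}
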