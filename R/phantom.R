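#' Specify a synthetic haematoma phantom
#'
#' Defines a CT-like digital phantom containing a single haematoma built
#' from a core ellipsoid, optionally fused with satellite "lobe" ellipsoids
#' centred on the core surface to produce irregular shapes. The rendered
#' grid uses partial-volume mixing: each voxel's HU is the occupancy-weighted
#' mixture of lesion and background attenuation, with occupancy computed at
#' 4x supersampling, so lesion boundaries are realistically blurred.
#'
#' @param diameters_mm Length-3 positive numeric: the core ellipsoid
#'   diameters in mm, ordered (axial x, axial y, through-plane z).
#' @param rotation_deg In-plane rotation of the core (and lobes) about the
#'   z axis, degrees.
#' @param centre_mm Lesion centre in mm, or `NULL` to centre the lesion on
#'   an automatically sized grid (the centre is snapped to a voxel corner,
#'   which makes rendered extents of axis-aligned shapes land on whole
#'   voxel counts).
#' @param n_lobes Number of satellite sub-ellipsoids fused to the core
#'   (0 = regular shape; 2 or more gives ground-truth class "irregular").
#' @param lobe_scale Lobe diameters as a fraction of the core diameters.
#' @param lobe_depth Radial position of lobe centres as a fraction of the
#'   distance from the core centre to its surface: 1 puts lobe centres on
#'   the surface (strongly protruding satellites), smaller values embed
#'   them so the lobes read as marginal undulations rather than separate
#'   balls - the appearance of most irregular haematomas.
#' @param mean_hu Mean lesion attenuation (HU). Acute haematoma is
#'   hyperattenuating, typically 40-80 HU.
#' @param hetero_sd_hu Standard deviation (HU) of the spatially smoothed
#'   intra-lesion heterogeneity field.
#' @param background_hu Brain background attenuation (HU).
#' @param noise_sd_hu Global acquisition noise SD (HU), added everywhere.
#' @param in_plane_spacing_mm Isotropic in-plane spacing, mm.
#' @param slice_thicknesses_mm Per-slice thickness vector in mm, or `NULL`
#'   to cover the lesion with uniform slices of `slice_thickness_mm`.
#' @param slice_thickness_mm Uniform thickness used when
#'   `slice_thicknesses_mm` is `NULL`.
#' @param grid_mm Optional length-2 numeric, in-plane grid extent (x, y) in
#'   mm; `NULL` sizes the grid to the lesion plus a margin.
#' @param centre_offset_mm Length-3 offset (mm) added to the automatic
#'   centre, used to emulate the arbitrary alignment of a lesion with the
#'   slice grid of a real acquisition (an auto-centred lesion otherwise
#'   sits exactly on a slice boundary and a voxel corner).
#' @param seed Integer seed; identical specs with identical seeds render
#'   bit-identical phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(diameters_mm,
                         rotation_deg = 0,
                         centre_mm = NULL,
                         n_lobes = 0L,
                         lobe_scale = 0.35,
                         lobe_depth = 0.75,
                         mean_hu = 65,
                         hetero_sd_hu = 0,
                         background_hu = 30,
                         noise_sd_hu = 4,
                         in_plane_spacing_mm = 1,
                         slice_thicknesses_mm = NULL,
                         slice_thickness_mm = 4,
                         grid_mm = NULL,
                         centre_offset_mm = c(0, 0, 0),
                         seed = 1L) {
  if (length(diameters_mm) != 3L || any(!is.finite(diameters_mm)) ||
      any(diameters_mm <= 0)) {
    stop("`diameters_mm` must be 3 positive lengths", call. = FALSE)
  }
  if (mean_hu <= background_hu) {
    stop("`mean_hu` must exceed `background_hu` (hyperattenuating lesion)",
         call. = FALSE)
  }
  if (!is.null(slice_thicknesses_mm) && any(slice_thicknesses_mm <= 0)) {
    stop("slice thicknesses must all be positive", call. = FALSE)
  }
  if (is.null(slice_thicknesses_mm) && slice_thickness_mm <= 0) {
    stop("`slice_thickness_mm` must be positive", call. = FALSE)
  }
  if (!is.null(grid_mm) && (length(grid_mm) != 2L || any(grid_mm <= 0))) {
    stop("`grid_mm` must be two positive extents (x, y) in mm", call. = FALSE)
  }
  if (in_plane_spacing_mm <= 0) stop("`in_plane_spacing_mm` must be positive",
                                     call. = FALSE)
  if (n_lobes < 0) stop("`n_lobes` must be >= 0", call. = FALSE)
  if (lobe_depth <= 0 || lobe_depth > 1) {
    stop("`lobe_depth` must lie in (0, 1]", call. = FALSE)
  }
  if (hetero_sd_hu < 0 || noise_sd_hu < 0) {
    stop("noise and heterogeneity SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(
      diameters_mm = as.numeric(diameters_mm),
      rotation_deg = as.numeric(rotation_deg),
      centre_mm = if (is.null(centre_mm)) NULL else as.numeric(centre_mm),
      n_lobes = as.integer(n_lobes),
      lobe_scale = as.numeric(lobe_scale),
      lobe_depth = as.numeric(lobe_depth),
      mean_hu = as.numeric(mean_hu),
      hetero_sd_hu = as.numeric(hetero_sd_hu),
      background_hu = as.numeric(background_hu),
      noise_sd_hu = as.numeric(noise_sd_hu),
      in_plane_spacing_mm = as.numeric(in_plane_spacing_mm),
      slice_thicknesses_mm = if (is.null(slice_thicknesses_mm)) NULL else
        as.numeric(slice_thicknesses_mm),
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      grid_mm = if (is.null(grid_mm)) NULL else as.numeric(grid_mm),
      centre_offset_mm = as.numeric(centre_offset_mm),
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# An ellipsoid: centre (x,y,z) mm, semi-axes (a,b,c) mm, in-plane rotation.
new_ellipsoid <- function(centre, semi, rot_deg = 0) {
  list(centre = centre, semi = semi, rot = rot_deg * pi / 180)
}

# Axis-aligned bounding box of a z-rotated ellipsoid.
ellipsoid_bbox <- function(e) {
  hx <- sqrt((e$semi[1] * cos(e$rot))^2 + (e$semi[2] * sin(e$rot))^2)
  hy <- sqrt((e$semi[1] * sin(e$rot))^2 + (e$semi[2] * cos(e$rot))^2)
  rbind(lo = e$centre - c(hx, hy, e$semi[3]),
        hi = e$centre + c(hx, hy, e$semi[3]))
}

union_bbox <- function(ellipsoids) {
  boxes <- lapply(ellipsoids, ellipsoid_bbox)
  rbind(lo = apply(vapply(boxes, function(b) b["lo", ], numeric(3)), 1, min),
        hi = apply(vapply(boxes, function(b) b["hi", ], numeric(3)), 1, max))
}

# Draw lobe ellipsoids along random directions, centred at `depth` times
# the core-surface distance.
draw_lobes <- function(core, n_lobes, lobe_scale, depth = 1) {
  if (n_lobes == 0L) return(list())
  dirs <- matrix(stats::rnorm(3L * n_lobes), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  lapply(seq_len(n_lobes), function(i) {
    u <- dirs[i, ]
    t_surf <- 1 / sqrt(sum((u / core$semi)^2))
    p_local <- depth * t_surf * u
    cr <- cos(core$rot); sr <- sin(core$rot)
    p_world <- core$centre + c(
      cr * p_local[1] - sr * p_local[2],
      sr * p_local[1] + cr * p_local[2],
      p_local[3]
    )
    new_ellipsoid(p_world, core$semi * lobe_scale, core$rot * 180 / pi)
  })
}

# Indicator of the ellipsoid union on an xy point grid at height z.
# X, Y are matrices of point coordinates (mm); returns a logical matrix.
union_indicator_plane <- function(ellipsoids, X, Y, z) {
  ind <- NULL
  for (e in ellipsoids) {
    dz <- z - e$centre[3]
    if (abs(dz) >= e$semi[3]) next
    rad2 <- 1 - (dz / e$semi[3])^2
    cr <- cos(e$rot); sr <- sin(e$rot)
    dx <- X - e$centre[1]; dy <- Y - e$centre[2]
    u <- cr * dx + sr * dy
    v <- -sr * dx + cr * dy
    hit <- (u / e$semi[1])^2 + (v / e$semi[2])^2 <= rad2
    ind <- if (is.null(ind)) hit else (ind | hit)
  }
  if (is.null(ind)) ind <- matrix(FALSE, nrow(X), ncol(X))
  ind
}

# Fold a (4*ny) x (4*nx) logical matrix into an ny x nx count matrix.
fold4 <- function(ind, ny, nx) {
  a <- array(ind, dim = c(4L, ny, 4L, nx))
  r1 <- colSums(a, dims = 1L)              # ny x 4 x nx
  colSums(aperm(r1, c(2L, 1L, 3L)), dims = 1L)  # ny x nx
}

# Separable Gaussian smoothing that keeps the array orientation.
smooth3d <- function(f, sigma_vox = 1.2) {
  half <- 3L
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k <- k / sum(k)
  dims <- dim(f)
  pad_filter <- function(m) {
    # filter each column of matrix m with kernel k, replicate-padded
    n <- nrow(m)
    mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
                m[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * half + 1L)) {
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  # dim 1
  f <- array(pad_filter(matrix(f, dims[1])), dims)
  # dim 2
  f <- aperm(f, c(2, 1, 3))
  f <- array(pad_filter(matrix(f, dims[2])), dims[c(2, 1, 3)])
  f <- aperm(f, c(2, 1, 3))
  # dim 3
  f <- aperm(f, c(3, 2, 1))
  f <- array(pad_filter(matrix(f, dims[3])), dims[c(3, 2, 1)])
  aperm(f, c(3, 2, 1))
}

#' Render a phantom and its ground truth
#'
#' Renders the phantom described by a [phantom_spec()] onto a voxel grid and
#' returns the CT-like volume together with oracle ground truth. The oracle
#' lesion volume is computed from the analytic shape by 4x supersampled
#' voxelisation (not from the rendered grid), so it is independent of the
#' partial-volume rendering and of any later segmentation.
#'
#' @param spec A [phantom_spec()].
#'
#' @return An object of class `ct_phantom`: a list with elements
#'   * `volume`: the rendered [ct_volume()];
#'   * `truth`: a one-row tibble with `true_volume_cm3`, `shape_class`
#'     (`"regular"` for fewer than 2 lobes, `"irregular"` otherwise),
#'     `density_class` (ordinal 1-5 surrogate from the heterogeneity
#'     coefficient of variation), `longest_diameter_cm` (maximal 3D extent
#'     of the analytic shape) and `n_lobes`;
#'   * `truth_mask`: a [lesion_mask()] of voxels with analytic occupancy
#'     >= 0.5 (the surface-unbiased ground-truth mask);
#'   * `spec`: the input spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  s <- spec$in_plane_spacing_mm
  core0 <- new_ellipsoid(c(0, 0, 0), spec$diameters_mm / 2, spec$rotation_deg)
  lobes0 <- draw_lobes(core0, spec$n_lobes, spec$lobe_scale, spec$lobe_depth)
  bbox0 <- union_bbox(c(list(core0), lobes0))
  half_lo <- -bbox0["lo", ]
  half_hi <- bbox0["hi", ]
  margin <- 4

  if (is.null(spec$slice_thicknesses_mm)) {
    t0 <- spec$slice_thickness_mm
    n_below <- ceiling((half_lo[3] + margin) / t0)
    n_above <- ceiling((half_hi[3] + margin) / t0)
    thick <- rep(t0, n_below + n_above)
    centre_z <- n_below * t0
  } else {
    thick <- spec$slice_thicknesses_mm
    centre_z <- if (is.null(spec$centre_mm)) sum(thick) / 2 else spec$centre_mm[3]
  }
  zb <- c(0, cumsum(thick))

  size_xy <- function(axis) {
    if (is.null(spec$grid_mm)) {
      n_lo <- ceiling((half_lo[axis] + margin) / s)
      n_hi <- ceiling((half_hi[axis] + margin) / s)
      list(n = n_lo + n_hi, centre = n_lo * s)
    } else {
      list(n = ceiling(spec$grid_mm[axis] / s),
           centre = if (is.null(spec$centre_mm)) {
             # snap the grid midpoint to the nearest voxel corner
             round(ceiling(spec$grid_mm[axis] / s) / 2) * s
           } else spec$centre_mm[axis])
    }
  }
  gx <- size_xy(1); gy <- size_xy(2)
  nx <- gx$n; ny <- gy$n; nz <- length(thick)
  centre <- c(gx$centre, gy$centre, centre_z) + spec$centre_offset_mm

  # world-frame ellipsoids
  shift <- function(e) { e$centre <- e$centre + centre; e }
  ells <- lapply(c(list(core0), lobes0), shift)
  bbox <- union_bbox(ells)
  ax_names <- c("x", "y", "z")
  lims <- rbind(hi = c(nx * s, ny * s, zb[nz + 1L]))
  for (axis in 1:3) {
    if (bbox["lo", axis] < 0 || bbox["hi", axis] > lims[1, axis]) {
      stop(sprintf("lesion extends outside the grid along the %s axis",
                   ax_names[axis]), call. = FALSE)
    }
  }

  # voxel index ranges covering the lesion bounding box
  ix <- max(1L, floor(bbox["lo", 1] / s)):min(nx, ceiling(bbox["hi", 1] / s))
  iy <- max(1L, floor(bbox["lo", 2] / s)):min(ny, ceiling(bbox["hi", 2] / s))
  iz <- which(zb[-1L] > bbox["lo", 3] & zb[-(nz + 1L)] < bbox["hi", 3])
  nxb <- length(ix); nyb <- length(iy)

  fine <- function(idx) ((min(idx) - 1L) * 4L + seq_len(4L * length(idx)) - 0.5) * (s / 4)
  Xf <- matrix(fine(ix), nrow = 4L * nyb, ncol = 4L * nxb, byrow = TRUE)
  Yf <- matrix(fine(iy), nrow = 4L * nyb, ncol = 4L * nxb)

  occ <- array(0, dim = c(nz, nyb, nxb))
  oracle_mm3 <- 0
  for (k in iz) {
    t_k <- thick[k]
    counts <- matrix(0, nyb, nxb)
    for (q in 1:4) {
      zq <- zb[k] + (q - 0.5) * t_k / 4
      ind <- union_indicator_plane(ells, Xf, Yf, zq)
      counts <- counts + fold4(ind, nyb, nxb)
    }
    occ[k, , ] <- counts / 64
    oracle_mm3 <- oracle_mm3 + sum(counts) * (s / 4)^2 * (t_k / 4)
  }

  # lesion HU field: mean + smoothed heterogeneity, partial-volume mixed
  values <- array(spec$background_hu, dim = c(nz, ny, nx))
  lesion_vox <- occ >= 0.5
  h <- 0
  if (spec$hetero_sd_hu > 0) {
    h <- smooth3d(array(stats::rnorm(nz * nyb * nxb), dim = c(nz, nyb, nxb)))
    sd_ref <- if (sum(lesion_vox) >= 2L) stats::sd(h[lesion_vox]) else stats::sd(h)
    if (sd_ref > 0) h <- h / sd_ref * spec$hetero_sd_hu
  }
  block <- spec$background_hu + occ * (spec$mean_hu - spec$background_hu + h)
  values[, iy, ix] <- block
  if (spec$noise_sd_hu > 0) {
    values <- values + stats::rnorm(length(values), sd = spec$noise_sd_hu)
  }

  truth_vox <- array(FALSE, dim = c(nz, ny, nx))
  truth_vox[, iy, ix] <- lesion_vox

  cv <- spec$hetero_sd_hu / spec$mean_hu
  density_class <- findInterval(cv, c(0.04, 0.08, 0.14, 0.22)) + 1L

  truth <- tibble::tibble(
    true_volume_cm3 = oracle_mm3 / 1000,
    shape_class = if (spec$n_lobes >= 2L) "irregular" else "regular",
    density_class = density_class,
    longest_diameter_cm = longest_extent_mm(ells) / 10,
    n_lobes = spec$n_lobes
  )

  structure(
    list(
      volume = ct_volume(values, s, thick),
      truth = truth,
      truth_mask = lesion_mask(truth_vox, provenance = list(source = "oracle occupancy >= 0.5")),
      spec = spec
    ),
    class = "ct_phantom"
  )
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> true volume %.2f cm^3, %s shape, longest diameter %.1f cm\n",
              x$truth$true_volume_cm3, x$truth$shape_class,
              x$truth$longest_diameter_cm))
  print(x$volume)
  invisible(x)
}

# Maximal pairwise extent of the ellipsoid union, from surface point clouds.
longest_extent_mm <- function(ellipsoids, n_pts = 400L) {
  pts <- do.call(rbind, lapply(ellipsoids, function(e) {
    i <- seq_len(n_pts)
    phi <- acos(1 - 2 * (i - 0.5) / n_pts)
    theta <- pi * (1 + sqrt(5)) * i
    p <- cbind(e$semi[1] * sin(phi) * cos(theta),
               e$semi[2] * sin(phi) * sin(theta),
               e$semi[3] * cos(phi))
    # add the exact axis endpoints: quasi-uniform surface sampling misses
    # the poles, which are the extreme points of axis-aligned shapes
    ends <- rbind(c(e$semi[1], 0, 0), c(-e$semi[1], 0, 0),
                  c(0, e$semi[2], 0), c(0, -e$semi[2], 0),
                  c(0, 0, e$semi[3]), c(0, 0, -e$semi[3]))
    p <- rbind(p, ends)
    cr <- cos(e$rot); sr <- sin(e$rot)
    cbind(cr * p[, 1] - sr * p[, 2] + e$centre[1],
          sr * p[, 1] + cr * p[, 2] + e$centre[2],
          p[, 3] + e$centre[3])
  }))
  max(stats::dist(pts))
}
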