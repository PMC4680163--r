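#' Segmentation parameters
#'
#' Threshold window and connectivity used by semiautomated segmentation
#' ([segment_threshold()]) and automatic region growing ([avc_volume()]).
#' Acute haemorrhage is typically windowed at 40-80 HU on clinical scans;
#' for phantoms whose background and lesion attenuations are known,
#' [midpoint_window()] emulates the manual practice of sampling both
#' tissues and placing the lower bound midway, which makes the thresholded
#' surface unbiased under partial-volume blur.
#'
#' @param hu_low,hu_high Lower and upper HU bounds; `hu_low < hu_high`.
#' @param connectivity Voxel connectivity for connected components: 6, 18
#'   or 26 (26 = most inclusive, the default).
#' @param seed_point Optional integer voxel coordinate `c(slice, row, col)`
#'   selecting the connected component to keep; without it the largest
#'   component is kept.
#' @param edit_mask Optional "manual edit" layer: a logical 3D array of
#'   voxels to force-include, or a list with elements `include` and/or
#'   `exclude` (logical arrays). Include overrides exclude overrides the
#'   threshold.
#' @param fill_holes If `TRUE`, interior holes of the selected component
#'   are filled slice-wise, emulating the manual boundary editing used when
#'   thresholds drop interior voxels.
#'
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(hu_low = 40, hu_high = 80, connectivity = 26L,
                       seed_point = NULL, edit_mask = NULL,
                       fill_holes = FALSE) {
  if (!is.numeric(hu_low) || !is.numeric(hu_high) || hu_low >= hu_high) {
    stop("`hu_low` must be strictly less than `hu_high`", call. = FALSE)
  }
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  structure(
    list(hu_low = hu_low, hu_high = hu_high,
         connectivity = as.integer(connectivity),
         seed_point = seed_point, edit_mask = edit_mask,
         fill_holes = isTRUE(fill_holes)),
    class = "seg_params"
  )
}

#' Surface-unbiased threshold window for a phantom
#'
#' Places the lower HU bound midway between background and lesion mean
#' attenuation, the window a practitioner obtains by sampling haemorrhage
#' and normal brain. At this level the partial-volume occupancy ramp is cut
#' at 0.5, so the thresholded mask neither dilates nor erodes the true
#' surface. The upper bound defaults high because phantoms render no bright
#' confounds (bone, calcification) that a clinical 80 HU cap exists to
#' exclude.
#'
#' @param spec A [phantom_spec()] (or a `ct_phantom`).
#' @param hu_high Upper bound, HU.
#' @param ... Passed to [seg_params()].
#' @return A [seg_params()].
#' @export
midpoint_window <- function(spec, hu_high = 200, ...) {
  if (inherits(spec, "ct_phantom")) spec <- spec$spec
  stopifnot(inherits(spec, "phantom_spec"))
  seg_params(hu_low = (spec$background_hu + spec$mean_hu) / 2,
             hu_high = hu_high, ...)
}

# Neighbour offsets (half-set) for 6/18/26 connectivity in [slice,row,col].
conn_offsets <- function(connectivity) {
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  manh <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- switch(as.character(connectivity),
                 "6" = offs[manh == 1, ],
                 "18" = offs[manh <= 2, ],
                 "26" = offs)
  # keep one representative of each (o, -o) pair
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  offs[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array. Returns an integer
# array (0 = background) plus component sizes. Adjacency edges are built
# by array shifting; component labelling is delegated to igraph.
label_components <- function(vox, connectivity = 26L) {
  dims <- dim(vox)
  idx <- array(0L, dims)
  ids <- which(vox)
  if (length(ids) == 0L) {
    return(list(labels = idx, sizes = integer(0)))
  }
  idx[ids] <- seq_along(ids)
  offs <- conn_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    dz <- offs$dz[r]; dy <- offs$dy[r]; dx <- offs$dx[r]
    z1 <- max(1, 1 + dz):min(dims[1], dims[1] + dz)
    y1 <- max(1, 1 + dy):min(dims[2], dims[2] + dy)
    x1 <- max(1, 1 + dx):min(dims[3], dims[3] + dx)
    a <- idx[z1, y1, x1, drop = FALSE]
    b <- idx[z1 - dz, y1 - dy, x1 - dx, drop = FALSE]
    hit <- a > 0L & b > 0L
    if (any(hit)) {
      from <- c(from, a[hit]); to <- c(to, b[hit])
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)
  lab <- array(0L, dims)
  lab[ids] <- comp$membership
  list(labels = lab, sizes = as.integer(comp$csize))
}

# Fill holes of a logical slice: background not connected (4-conn) to the
# slice border becomes foreground.
fill_holes_slice <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  outside <- matrix(FALSE, ny, nx)
  # flood fill from the border over !m using simple queue-free sweeps
  frontier <- !m & (row(m) %in% c(1L, ny) | col(m) %in% c(1L, nx))
  outside <- frontier
  repeat {
    grown <- outside
    grown[-1, ] <- grown[-1, ] | outside[-ny, ]
    grown[-ny, ] <- grown[-ny, ] | outside[-1, ]
    grown[, -1] <- grown[, -1] | outside[, -nx]
    grown[, -nx] <- grown[, -nx] | outside[, -1]
    grown <- grown & !m
    if (identical(grown, outside)) break
    outside <- grown
  }
  m | (!m & !outside)
}

#' Threshold-based lesion segmentation
#'
#' Selects voxels whose HU lies within the window, keeps the connected
#' component containing the seed point (or the largest component when no
#' seed is given), then applies manual edits: include overrides exclude
#' overrides the threshold. This is the semiautomated segmentation (SAS)
#' region-of-interest step.
#'
#' @param volume A [ct_volume()].
#' @param params A [seg_params()].
#' @return A [lesion_mask()] carrying its provenance.
#' @export
segment_threshold <- function(volume, params = seg_params()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(params, "seg_params"))
  vox <- volume$values >= params$hu_low & volume$values <= params$hu_high
  if (!any(vox)) {
    stop(sprintf("no lesion in window [%g, %g] HU",
                 params$hu_low, params$hu_high), call. = FALSE)
  }
  lc <- label_components(vox, params$connectivity)
  if (!is.null(params$seed_point)) {
    sp <- as.integer(params$seed_point)
    lab_seed <- lc$labels[sp[1], sp[2], sp[3]]
    if (lab_seed == 0L) {
      stop("seed not in window", call. = FALSE)
    }
    keep <- lc$labels == lab_seed
  } else {
    keep <- lc$labels == which.max(lc$sizes)
  }
  edits_applied <- character(0)
  if (isTRUE(params$fill_holes)) {
    for (k in seq_len(dim(keep)[1])) {
      sl <- keep[k, , ]
      if (any(sl)) keep[k, , ] <- fill_holes_slice(sl)
    }
    edits_applied <- c(edits_applied, "fill_holes")
  }
  em <- params$edit_mask
  if (!is.null(em)) {
    if (is.array(em)) em <- list(include = em)
    if (!is.null(em$exclude)) {
      keep <- keep & !em$exclude
      edits_applied <- c(edits_applied, "exclude")
    }
    if (!is.null(em$include)) {
      keep <- keep | em$include
      edits_applied <- c(edits_applied, "include")
    }
  }
  if (!any(keep)) {
    stop(sprintf("no lesion in window [%g, %g] HU after edits",
                 params$hu_low, params$hu_high), call. = FALSE)
  }
  lesion_mask(keep, provenance = list(
    hu_low = params$hu_low, hu_high = params$hu_high,
    connectivity = params$connectivity,
    seed_point = params$seed_point,
    edits = edits_applied
  ))
}
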