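#' Configure a phantom cohort
#'
#' Describes the statistical mixture a generated cohort emulates: the
#' visual size-category proportions of a large acute-ICH imaging series,
#' the probability of an irregular shape within each size category (larger
#' haemorrhages are more often irregular; the defaults give roughly 64%
#' irregular overall), axis-ratio and density-heterogeneity ranges, and
#' the acquisition geometry.
#'
#' @param n Number of phantoms.
#' @param size_proportions Proportions for the longest-diameter categories
#'   `<3`, `3-4.9`, `5-8`, `>8` cm; must sum to 1.
#' @param diameter_ranges_cm 4x2 matrix of (min, max) core long diameters
#'   per category, cm.
#' @param irregular_prob Probability of an irregular (lobulated) shape per
#'   size category.
#' @param n_lobes_range Lobe counts (sampled uniformly) for irregular
#'   shapes; at least 2 so the ground-truth class is irregular.
#' @param lobe_scale_range Range of lobe diameter fractions.
#' @param lobe_depth Radial lobe-centre position (fraction of the core
#'   surface distance); see [phantom_spec()].
#' @param axis_ratio_range Range of the B/A and C/A core axis ratios.
#' @param hetero_sd_range_hu Range of intra-lesion heterogeneity SD, HU.
#' @param mean_hu,background_hu,noise_sd_hu Tissue attenuation defaults.
#' @param in_plane_spacing_mm,slice_thickness_mm Acquisition geometry.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 100L,
                          size_proportions = c(0.41, 0.41, 0.16, 0.02),
                          diameter_ranges_cm = rbind(c(1.5, 3), c(3, 5),
                                                     c(5, 8), c(8, 9.5)),
                          irregular_prob = c(0.50, 0.70, 0.85, 0.95),
                          n_lobes_range = c(2L, 4L),
                          lobe_scale_range = c(0.30, 0.45),
                          lobe_depth = 0.75,
                          axis_ratio_range = c(0.60, 0.90),
                          hetero_sd_range_hu = c(2, 12),
                          mean_hu = 65, background_hu = 30, noise_sd_hu = 4,
                          in_plane_spacing_mm = 1, slice_thickness_mm = 4) {
  if (abs(sum(size_proportions) - 1) > 1e-8) {
    stop("size-category proportions must sum to 1", call. = FALSE)
  }
  if (length(size_proportions) != 4L || length(irregular_prob) != 4L) {
    stop("four size categories are expected", call. = FALSE)
  }
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a phantom cohort
#'
#' Draws `n` phantoms from the mixture described by a [cohort_config()]:
#' size category (multinomial), core diameters, in-plane rotation, shape
#' class and lobe geometry, heterogeneity, and a random sub-voxel
#' alignment of the lesion with the slice grid. A cohort is a pure
#' function of `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return An object of class `phantom_cohort`: a list with `phantoms`
#'   (list of `ct_phantom`) and `manifest` (one tibble row per phantom:
#'   spec fields plus ground truth).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- withr::with_seed(seed, draw_cohort_specs(config))
  phantoms <- lapply(specs, generate_phantom)
  manifest <- if (length(phantoms) == 0L) empty_manifest() else
    dplyr::bind_rows(lapply(seq_along(phantoms), function(i) {
      sp <- specs[[i]]
      tr <- phantoms[[i]]$truth
      tibble::tibble(
        scan_id = sprintf("phantom_%03d", i),
        seed = sp$seed,
        target_category = attr(sp, "target_category"),
        d1_mm = sp$diameters_mm[1], d2_mm = sp$diameters_mm[2],
        d3_mm = sp$diameters_mm[3],
        rotation_deg = sp$rotation_deg,
        n_lobes = sp$n_lobes, lobe_scale = sp$lobe_scale,
        mean_hu = sp$mean_hu, background_hu = sp$background_hu,
        hetero_sd_hu = sp$hetero_sd_hu, noise_sd_hu = sp$noise_sd_hu,
        in_plane_spacing_mm = sp$in_plane_spacing_mm,
        slice_thickness_mm = sp$slice_thickness_mm,
        true_volume_cm3 = tr$true_volume_cm3,
        shape_class = tr$shape_class,
        density_class = tr$density_class,
        longest_diameter_cm = tr$longest_diameter_cm,
        size_category = as.character(size_category(tr$longest_diameter_cm))
      )
    }))
  structure(list(phantoms = phantoms, manifest = manifest, config = config,
                 seed = seed),
            class = "phantom_cohort")
}

empty_manifest <- function() {
  tibble::tibble(
    scan_id = character(), seed = integer(), target_category = character(),
    d1_mm = numeric(), d2_mm = numeric(), d3_mm = numeric(),
    rotation_deg = numeric(), n_lobes = integer(), lobe_scale = numeric(),
    mean_hu = numeric(), background_hu = numeric(), hetero_sd_hu = numeric(),
    noise_sd_hu = numeric(), in_plane_spacing_mm = numeric(),
    slice_thickness_mm = numeric(), true_volume_cm3 = numeric(),
    shape_class = character(), density_class = integer(),
    longest_diameter_cm = numeric(), size_category = character()
  )
}

draw_cohort_specs <- function(config) {
  n <- config$n
  if (n == 0L) return(list())
  cats <- sample.int(4L, n, replace = TRUE, prob = config$size_proportions)
  cat_names <- c("<3", "3-4.9", "5-8", ">8")
  lapply(seq_len(n), function(i) {
    ci <- cats[i]
    rng <- config$diameter_ranges_cm[ci, ]
    d1 <- stats::runif(1, rng[1], rng[2]) * 10  # cm -> mm
    d2 <- d1 * stats::runif(1, config$axis_ratio_range[1],
                            config$axis_ratio_range[2])
    d3 <- d1 * stats::runif(1, config$axis_ratio_range[1],
                            config$axis_ratio_range[2])
    irregular <- stats::runif(1) < config$irregular_prob[ci]
    n_lobes <- if (irregular) {
      sample(seq(config$n_lobes_range[1], config$n_lobes_range[2]), 1L)
    } else 0L
    sp <- phantom_spec(
      diameters_mm = c(d1, d2, d3),
      rotation_deg = stats::runif(1, 0, 180),
      n_lobes = n_lobes,
      lobe_scale = stats::runif(1, config$lobe_scale_range[1],
                                config$lobe_scale_range[2]),
      lobe_depth = config$lobe_depth,
      mean_hu = config$mean_hu,
      hetero_sd_hu = stats::runif(1, config$hetero_sd_range_hu[1],
                                  config$hetero_sd_range_hu[2]),
      background_hu = config$background_hu,
      noise_sd_hu = config$noise_sd_hu,
      in_plane_spacing_mm = config$in_plane_spacing_mm,
      slice_thickness_mm = config$slice_thickness_mm,
      centre_offset_mm = c(
        stats::runif(2, -config$in_plane_spacing_mm / 2,
                     config$in_plane_spacing_mm / 2),
        stats::runif(1, -config$slice_thickness_mm / 2,
                     config$slice_thickness_mm / 2)
      ),
      seed = sample.int(.Machine$integer.max - 1L, 1L)
    )
    attr(sp, "target_category") <- cat_names[ci]
    sp
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> n=%d (seed %d)\n", length(x$phantoms), x$seed))
  if (nrow(x$manifest) > 0) {
    print(table(x$manifest$target_category, x$manifest$shape_class))
  }
  invisible(x)
}
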