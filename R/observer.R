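#' Simulated observer model
#'
#' A parametric stand-in for human measurement variation: multiplicative
#' log-normal error on the measured A and B diameters, random toggling of
#' thin end-slices in or out of the segmentation, and uniform jitter of
#' the HU window bounds. A model with all parameters zero reproduces the
#' direct (unperturbed) measurement bit-exactly. The defaults are tuned
#' only to land the intra- and interobserver ICCs in the ranges reported
#' for trained human observers, and reports should label them as such.
#'
#' @param diameter_error_sd Log-scale SD of the multiplicative error on A
#'   and B (0.03 is about a 3% caliper error).
#' @param slice_flip_prob Probability of dropping a slice whose
#'   haemorrhage area is below 10% of the maximum slice area.
#' @param threshold_jitter_hu Half-width (HU) of the uniform jitter added
#'   to both window bounds.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(diameter_error_sd = 0.03,
                           slice_flip_prob = 0.05,
                           threshold_jitter_hu = 1.5) {
  if (diameter_error_sd < 0 || threshold_jitter_hu < 0) {
    stop("error SDs must be >= 0", call. = FALSE)
  }
  if (slice_flip_prob < 0 || slice_flip_prob > 1) {
    stop("`slice_flip_prob` must be a probability", call. = FALSE)
  }
  structure(
    list(diameter_error_sd = diameter_error_sd,
         slice_flip_prob = slice_flip_prob,
         threshold_jitter_hu = threshold_jitter_hu),
    class = "observer_model"
  )
}

#' Measure a volume as a simulated observer
#'
#' Applies the observer model's perturbations - window jitter before
#' segmentation, thin-slice inclusion flips on the mask, diameter error on
#' A and B - then runs every volume-measurement method on the result.
#'
#' @param volume A [ct_volume()] or `ct_phantom`.
#' @param params Baseline [seg_params()].
#' @param model An [observer_model()].
#' @param seed Integer seed for this reading.
#' @param include_avc Include AVC where the scan permits it.
#' @return A tibble as from [measure_all()].
#' @export
simulate_observer <- function(volume, params, model = observer_model(),
                              seed = 1L, include_avc = TRUE) {
  if (inherits(volume, "ct_phantom")) volume <- volume$volume
  stopifnot(inherits(model, "observer_model"))
  withr::with_seed(seed, {
    jit <- stats::runif(2, -model$threshold_jitter_hu,
                        model$threshold_jitter_hu)
    p <- seg_params(params$hu_low + jit[1], params$hu_high + jit[2],
                    connectivity = params$connectivity,
                    seed_point = params$seed_point,
                    edit_mask = params$edit_mask,
                    fill_holes = params$fill_holes)
    mask <- segment_threshold(volume, p)
    if (model$slice_flip_prob > 0) {
      sa <- slice_areas(mask, volume)
      thin <- which(sa$area_cm2 > 0 & sa$area_cm2 < 0.1 * max(sa$area_cm2))
      for (k in thin) {
        if (stats::runif(1) < model$slice_flip_prob) {
          mask$voxels[k, , ] <- FALSE
        }
      }
      check_mask_nonempty(mask)
    }
    ab_scale <- exp(stats::rnorm(2, 0, model$diameter_error_sd))
    measure_all_from_mask(mask, volume, p, include_avc = include_avc,
                          ab_scale = ab_scale)
  })
}
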