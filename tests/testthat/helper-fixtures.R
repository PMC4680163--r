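# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Noise-free 20 mm sphere on a 1 mm isotropic grid.
sphere_phantom <- function() {
  fixture("sphere", function() {
    generate_phantom(phantom_spec(c(20, 20, 20), noise_sd_hu = 0,
                                  slice_thickness_mm = 1, seed = 7))
  })
}

# Noise-free axis-aligned 40 x 30 x 20 mm ellipsoid, 1 mm grid.
ellipsoid_phantom <- function() {
  fixture("ellipsoid", function() {
    generate_phantom(phantom_spec(c(40, 30, 20), noise_sd_hu = 0,
                                  slice_thickness_mm = 1, seed = 3))
  })
}

# The default 100-phantom cohort with direct (unperturbed) measurements,
# shared by the acceptance tests that probe cohort-level directions.
default_cohort_measurements <- function() {
  fixture("cohort_meas", function() {
    cohort <- generate_cohort(cohort_config(), seed = 20260901)
    seg <- seg_params(hu_low = 47.5, hu_high = 200, fill_holes = TRUE)
    wide <- dplyr::bind_rows(lapply(seq_along(cohort$phantoms), function(i) {
      m <- measure_all(cohort$phantoms[[i]], seg, include_avc = FALSE)
      m$scan_id <- cohort$manifest$scan_id[i]
      m
    }))
    wide <- tidyr::pivot_wider(
      dplyr::select(wide, scan_id, method, volume_cm3),
      names_from = method, values_from = volume_cm3
    )
    dplyr::left_join(
      wide,
      cohort$manifest[, c("scan_id", "true_volume_cm3", "shape_class",
                          "size_category")],
      by = "scan_id"
    )
  })
}

# Tiny volume with two disjoint cubic lesions (8 and 27 voxels).
two_blob_volume <- function() {
  vals <- array(20, dim = c(8, 16, 16))
  vals[2:4, 2:4, 2:4] <- 65    # larger blob
  vals[6:7, 10:11, 10:11] <- 65  # smaller blob
  ct_volume(vals, 1, rep(2, 8))
}
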