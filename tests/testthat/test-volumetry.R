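test_that("threshold segmentation recovers a noise-free sphere", {
  sphere <- sphere_phantom()
  # sampled-midpoint window: surface-unbiased, volume within 2% of 4.19 cm^3
  mask <- segment_threshold(sphere$volume, midpoint_window(sphere))
  vol <- sum(mask$voxels) / 1000  # 1 mm isotropic
  expect_equal(vol, 4 / 3 * pi, tolerance = 0.02)
  # the clinical 40-80 HU window cuts the partial-volume ramp below 0.5
  # occupancy and therefore dilates the surface: a bounded overestimate
  mask40 <- segment_threshold(sphere$volume, seg_params(40, 80))
  vol40 <- sum(mask40$voxels) / 1000
  expect_true(all(mask$voxels[mask40$voxels == FALSE] == FALSE))
  expect_gt(vol40, vol)
  expect_lt(vol40 / (4 / 3 * pi), 1.08)
})

test_that("segmentation errors carry the window and respect the seed", {
  sphere <- sphere_phantom()
  expect_error(segment_threshold(sphere$volume, seg_params(200, 300)),
               "no lesion in window \\[200, 300\\]")
  two <- two_blob_volume()
  seeded <- segment_threshold(two, seg_params(40, 80, seed_point = c(6, 10, 10)))
  expect_identical(sum(seeded$voxels), 8L)  # only the seeded small blob
  largest <- segment_threshold(two, seg_params(40, 80))
  expect_identical(sum(largest$voxels), 27L)  # defaults to largest component
  expect_error(avc_volume(two, seg_params(40, 80, seed_point = c(1, 1, 1)),
                          allow_variable_thickness = TRUE),
               "seed not in window")
})

test_that("edit masks override the threshold, include over exclude", {
  two <- two_blob_volume()
  inc <- array(FALSE, dim(two$values)); inc[1, 1, 1] <- TRUE
  exc <- array(FALSE, dim(two$values)); exc[3, 3, 3] <- TRUE
  m <- segment_threshold(two, seg_params(40, 80,
                                         edit_mask = list(include = inc,
                                                          exclude = exc)))
  expect_true(m$voxels[1, 1, 1])
  expect_false(m$voxels[3, 3, 3])
})

test_that("slice areas follow count times squared spacing", {
  vals <- array(0, dim = c(3, 14, 14))
  vals[2, 3:12, 3:12] <- 65
  vol <- ct_volume(vals, 1, rep(5, 3))
  mask <- lesion_mask(vals >= 40)
  sa <- slice_areas(mask, vol)
  expect_equal(sa$area_cm2, c(0, 1, 0))
  # sphere: unimodal profile peaking at the equator
  sphere <- sphere_phantom()
  smask <- segment_threshold(sphere$volume, midpoint_window(sphere))
  prof <- slice_areas(smask, sphere$volume)$area_cm2
  peak <- which.max(prof)
  expect_true(all(diff(prof[1:peak]) >= 0))
  expect_true(all(diff(prof[peak:length(prof)]) <= 0))
  expect_equal(largest_slice_morphometry(smask, sphere$volume)$slice_index,
               peak)
})

test_that("A and B measure the axial diameters of known shapes", {
  ell <- ellipsoid_phantom()
  mask <- segment_threshold(ell$volume, midpoint_window(ell))
  ab <- measure_A_B(mask, ell$volume)
  expect_equal(ab$A_cm, 4.0, tolerance = 0.1 / 4)   # within one voxel
  expect_equal(ab$B_cm, 3.0, tolerance = 0.1 / 3)
  expect_gte(ab$A_cm, ab$B_cm)

  rot <- generate_phantom(phantom_spec(c(50, 20, 20), rotation_deg = 45,
                                       noise_sd_hu = 0,
                                       slice_thickness_mm = 1, seed = 3))
  rmask <- segment_threshold(rot$volume, midpoint_window(rot))
  expect_equal(measure_A_B(rmask, rot$volume)$A_cm, 5.0, tolerance = 0.1 / 5)

  vals <- array(0, dim = c(3, 9, 9)); vals[2, 5, 5] <- 65
  single <- lesion_mask(vals >= 40)
  ab1 <- measure_A_B(single, ct_volume(vals, 1, rep(1, 3)))
  expect_equal(ab1$A_cm, 0.1)
  expect_equal(ab1$B_cm, 0.1)
  expect_identical(ab1$a_slice_index, 2L)
})

test_that("C follows the slice-sum rule, modified C the 25/75 weights", {
  vals <- array(0, dim = c(7, 8, 8))
  vals[2:6, 3:6, 3:6] <- 65
  mask <- lesion_mask(vals >= 40)
  expect_equal(c_standard(mask, ct_volume(vals, 1, rep(4, 7))), 2.0)  # 5 x 4 mm
  valsv <- array(0, dim = c(3, 8, 8)); valsv[1:3, 3:6, 3:6] <- 65
  maskv <- lesion_mask(valsv >= 40)
  expect_equal(c_standard(maskv, ct_volume(valsv, 1, c(4, 4, 8))), 1.6)
  empty <- lesion_mask(array(FALSE, dim = c(3, 8, 8)))
  expect_error(c_standard(empty, ct_volume(valsv * 0, 1, c(4, 4, 8))),
               "empty")

  # spelled-out example: weights (0, .5, 1, 1, 1, .5, 0)
  expect_equal(c_modified(c(1, 3, 8, 10, 8, 3, 1), rep(10, 7)), 4.0)
  # boundary areas at exactly 25% and 75% take weight 0.5
  expect_equal(c_modified(c(2.5, 7.5, 10), rep(10, 3)), 2.0)
  # equal areas: modified equals standard
  expect_equal(c_modified(rep(4, 5), rep(4, 5)),
               c_standard(mask, ct_volume(vals, 1, rep(4, 7))))
  # weights <= 1 make modified C never exceed standard C
  for (seed in 1:25) {
    areas <- withr::with_seed(seed, stats::runif(8, 0, 10))
    th <- withr::with_seed(seed + 100, stats::runif(8, 2, 8))
    expect_lte(c_modified(areas, th), sum(th[areas > 0]) / 10 + 1e-12)
  }
})

test_that("abc2 applies the half-ellipsoid formula and guards its inputs", {
  expect_equal(abc2(4, 3, 2), 12)
  expect_error(abc2(4, 0, 2), "positive")
  expect_error(abc2(3, 4, 2), "A must be the longest")
})

test_that("SAS volume is thickness-weighted planimetry", {
  vals <- array(0, dim = c(10, 14, 14))
  vals[1:10, 3:12, 3:12] <- 65
  vol <- ct_volume(vals, 1, rep(1, 10))
  mask <- lesion_mask(vals >= 40)
  expect_equal(sas_volume(mask, vol)$volume_cm3, 1.0)
  # uniform thickness: equals voxel count x voxel volume
  vol4 <- ct_volume(vals, 1, rep(4, 10))
  expect_equal(sas_volume(mask, vol4)$volume_cm3,
               sum(mask$voxels) * 1 * 1 * 4 / 1000)
  # slice relabelling leaves the volume unchanged
  perm <- withr::with_seed(1, sample(10))
  vol_p <- ct_volume(vals[perm, , ], 1, rep(4, 10))
  mask_p <- lesion_mask(mask$voxels[perm, , ])
  expect_equal(sas_volume(mask_p, vol_p)$volume_cm3,
               sas_volume(mask, vol4)$volume_cm3)
  # HU rescaling that preserves the window leaves the mask unchanged
  sphere <- sphere_phantom()
  m1 <- segment_threshold(sphere$volume, midpoint_window(sphere))
  shifted <- ct_volume(sphere$volume$values + 5, 1,
                       sphere$volume$slice_thicknesses_mm)
  m2 <- segment_threshold(shifted, seg_params(47.5 + 5, 200 + 5))
  expect_identical(m1$voxels, m2$voxels)
})

test_that("AVC matches SAS on uniform scans and refuses variable thickness", {
  sphere <- sphere_phantom()
  p <- midpoint_window(sphere)
  mask <- segment_threshold(sphere$volume, p)
  seedv <- which(mask$voxels, arr.ind = TRUE)[1, ]
  avc <- avc_volume(sphere$volume,
                    seg_params(p$hu_low, p$hu_high, seed_point = seedv))
  expect_equal(avc$volume_cm3, sas_volume(mask, sphere$volume)$volume_cm3,
               tolerance = 0.01)
  varth <- generate_phantom(phantom_spec(
    c(20, 18, 16), noise_sd_hu = 0,
    slice_thicknesses_mm = c(rep(4, 6), rep(8, 2)), centre_mm = c(20, 20, 16),
    grid_mm = c(40, 40), seed = 4))
  expect_error(
    avc_volume(varth$volume, seg_params(47.5, 200, seed_point = c(4, 20, 20))),
    "variable slice thickness unsupported"
  )
  got <- avc_volume(varth$volume,
                    seg_params(47.5, 200, seed_point = c(4, 20, 20)),
                    allow_variable_thickness = TRUE)
  expect_gt(got$volume_cm3, 0)
})

test_that("size categories use the printed half-open bins", {
  expect_identical(as.character(size_category(c(2.9, 3, 4.9, 5, 8, 8.01))),
                   c("<3", "3-4.9", "3-4.9", "5-8", "5-8", ">8"))
  expect_error(size_category(0), "positive")
})
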