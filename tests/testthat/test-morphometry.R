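test_that("segmentation recovers the exact phantom membership at zero noise", {
  spec <- tiny_spec(cytoplasm_ri = 1.356, medium_ri = 1.337)
  tom <- make_phantom(spec)
  mask <- segment_cell(tom, morphometry_config(tau_seg = 1.345))
  expect_identical(array(as.vector(mask), dim(mask)), tom$ri > 1.345)
  expect_identical(sum(mask), oracle_ellipsoid_count(spec))
})

test_that("a uniform volume raises a no-cell-found error", {
  tom <- tomogram(array(1.337, dim = c(8, 8, 8)), 0.2, 1.337)
  expect_error(segment_cell(tom), "no cell found")
})

test_that("noisy segmentation stays within 3% of the zero-noise count", {
  spec0 <- tiny_spec()
  n0 <- sum(segment_cell(make_phantom(spec0)))
  specn <- tiny_spec(noise_sd = 0.002)
  for (s in 1:3) {
    n <- sum(segment_cell(make_phantom(specn, seed = s)))
    expect_lt(abs(n - n0) / n0, 0.03)
  }
})

test_that("centre and radius follow their definitions", {
  m <- array(FALSE, dim = c(8, 8, 8))
  m[3, 4, 5] <- TRUE
  cr <- cell_center_radius(m)
  expect_equal(cr$center, c(3, 4, 5))
  expect_equal(cr$radius, 0)
  expect_error(cell_center_radius(array(FALSE, dim = c(4, 4, 4))), "empty mask")

  # symmetric sphere: centre within half a voxel of the configured centre
  spec <- tiny_spec()
  mask <- segment_cell(make_phantom(spec))
  expect_lt(max(abs(cell_center_radius(mask)$center - (dim(mask) + 1) / 2)), 0.5)

  # hemisphere: centre equals the brute-force coordinate mean
  hemi <- mask
  hemi[, , 1:16] <- FALSE
  co <- which(hemi, arr.ind = TRUE)
  expect_equal(cell_center_radius(hemi)$center, unname(colMeans(co)))
  # anisotropic spacing scales the radius
  expect_equal(cell_center_radius(m, spacing = c(2, 1, 1))$radius, 0)
})

test_that("volume is voxel count times voxel volume and scales accordingly", {
  m <- array(FALSE, dim = c(10, 10, 10))
  m[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  expect_equal(compute_volume(m, c(0.1, 0.1, 0.1)), 1.0)
  expect_equal(compute_volume(m, c(0.2, 0.2, 0.2)), 8.0)
  spec <- phantom_spec(cell_radius_um = 5, voxel_spacing_um = 0.2,
                       grid_shape = c(64, 64, 64))
  mask <- segment_cell(make_phantom(spec), morphometry_config(tau_seg = 1.345))
  V <- compute_volume(mask, spec$voxel_spacing_um)
  expect_lt(abs(V - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.01)
})

test_that("protein density follows the refraction-increment formula", {
  spec <- tiny_spec(cytoplasm_ri = 1.356, nucleus_ri = 1.356, medium_ri = 1.337)
  tom <- make_phantom(spec)
  mask <- segment_cell(tom)
  expect_equal(protein_density(tom, mask, morphometry_config(alpha = 0.19)), 10)
  # delta-n = 0 gives zero density
  tz <- tomogram(array(1.337, dim = c(4, 4, 4)), 0.2, 1.337)
  mz <- array(TRUE, dim = c(4, 4, 4))
  expect_equal(protein_density(tz, mz), 0)
  tneg <- tomogram(array(1.336, dim = c(4, 4, 4)) + 0.0005, 0.2, 1.337)
  expect_warning(protein_density(tneg, mz), "negative")
  expect_error(morphometry_config(alpha = 0), "alpha")
})

test_that("dry mass is C * V / 100", {
  expect_equal(dry_mass(10, 100), 10)
  expect_equal(dry_mass(10, 523.6), 52.36)
  expect_equal(dry_mass(0, 400), 0)
})

test_that("sectional RI features match pixel enumeration at zero noise", {
  spec <- tiny_spec(cytoplasm_ri = 1.36, nucleus_ri = 1.39)
  tom <- make_phantom(spec)
  mask <- segment_cell(tom)
  sf <- sectional_ri_features(tom, mask)
  expect_equal(sf$mean_nuclear_ri, 1.39)
  # oracle: enumerate in-mask pixels of the central plane
  z <- sf$section_index
  px <- tom$ri[z, , ][mask[z, , ]]
  expect_equal(sf$mean_overall_ri, mean(px))
  expect_equal(sf$nuclear_pixel_fraction, mean(px > 1.38))

  # all sub-threshold: nuclear feature absent, fraction zero
  low <- make_phantom(tiny_spec(cytoplasm_ri = 1.35, nucleus_ri = 1.36))
  lmask <- segment_cell(low)
  lf <- sectional_ri_features(low, lmask)
  expect_true(is.na(lf$mean_nuclear_ri))
  expect_equal(lf$nuclear_pixel_fraction, 0)
})

test_that("stored dry mass is exactly C * V / 100 and features are invariant to
           translation and axis-aligned rotation", {
  spec <- tiny_spec(noise_sd = 0.002)
  tom <- make_phantom(spec, seed = 9)
  f <- cell_morphometry(tom)
  expect_identical(f$dry_mass_pg, f$protein_density_gdl * f$volume_fl * 1e-2)

  off <- make_phantom(tiny_spec(noise_sd = 0, center_offset_vox = c(3, -2, 4)))
  ctr <- make_phantom(tiny_spec(noise_sd = 0))
  f_off <- cell_morphometry(off); f_ctr <- cell_morphometry(ctr)
  expect_equal(f_off$volume_fl, f_ctr$volume_fl)
  expect_equal(f_off$dry_mass_pg, f_ctr$dry_mass_pg)

  rot <- tomogram(aperm(ctr$ri, c(1, 3, 2)), ctr$voxel_spacing_um, ctr$medium_ri)
  f_rot <- cell_morphometry(rot)
  expect_equal(f_rot$volume_fl, f_ctr$volume_fl)
  expect_equal(f_rot$dry_mass_pg, f_ctr$dry_mass_pg)
})

test_that("raising the cytoplasm RI strictly raises density, mass and mean RI", {
  fs <- lapply(c(1.35, 1.356, 1.362), function(ri) {
    cell_morphometry(make_phantom(tiny_spec(cytoplasm_ri = ri)))
  })
  expect_true(all(diff(sapply(fs, `[[`, "protein_density_gdl")) > 0))
  expect_true(all(diff(sapply(fs, `[[`, "dry_mass_pg")) > 0))
  expect_true(all(diff(sapply(fs, `[[`, "mean_overall_ri")) > 0))
})

test_that("full-3D feature space measures RI over the whole mask", {
  spec <- tiny_spec(cytoplasm_ri = 1.36, nucleus_ri = 1.39)
  tom <- make_phantom(spec)
  f3 <- cell_morphometry(tom, morphometry_config(feature_space = "full_3d"))
  mask <- segment_cell(tom)
  expect_equal(f3$mean_overall_ri, mean(tom$ri[mask]))
})
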