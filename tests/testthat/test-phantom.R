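test_that("zero-noise phantom contains only the three configured RI values", {
  spec <- tiny_spec(cytoplasm_ri = 1.356, nucleus_ri = 1.39, medium_ri = 1.337)
  tom <- make_phantom(spec)
  expect_setequal(unique(as.vector(tom$ri)), c(1.337, 1.356, 1.39))
  # nucleus is concentric and interior
  expect_true(sum(tom$ri == 1.39) > 0)
  expect_true(sum(tom$ri == 1.356) > sum(tom$ri == 1.39))
})

test_that("phantom generation is deterministic given a seed", {
  spec <- tiny_spec(noise_sd = 0.003)
  a <- make_phantom(spec, seed = 7)
  b <- make_phantom(spec, seed = 7)
  expect_identical(a$ri, b$ri)
  c <- make_phantom(spec, seed = 8)
  expect_false(identical(a$ri, c$ri))
})

test_that("super-medium voxel count matches the brute-force lattice oracle", {
  set.seed(31)
  for (i in 1:4) {
    spec <- phantom_spec(cell_radius_um = runif(3, 2, 3.6),
                         voxel_spacing_um = runif(3, 0.25, 0.4),
                         grid_shape = c(36, 36, 36),
                         center_offset_vox = sample(-2:2, 3, replace = TRUE))
    tom <- make_phantom(spec)
    expect_identical(sum(tom$ri > spec$medium_ri), oracle_ellipsoid_count(spec))
  }
  # sphere volume approaches the analytic value
  sp5 <- phantom_spec(cell_radius_um = 5, voxel_spacing_um = 0.2,
                      grid_shape = c(64, 64, 64))
  n <- oracle_ellipsoid_count(sp5)
  expect_lt(abs(n * 0.2^3 - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.01)
})

test_that("a cell that does not fit the grid is a sizing error", {
  expect_error(phantom_spec(cell_radius_um = 10, voxel_spacing_um = 0.3,
                            grid_shape = c(32, 32, 32)),
               "grid too small")
  expect_error(phantom_spec(cell_radius_um = 3, voxel_spacing_um = 0.3,
                            grid_shape = c(32, 32, 32),
                            center_offset_vox = c(12, 0, 0)),
               "grid too small")
})

test_that("peripheral rim places elevated RI in the outer radial band", {
  spec <- tiny_spec(peripheral_weight = 1, rim_inner_fraction = 0.75,
                    nucleus_radius_fraction = 0.4)
  tom <- make_phantom(spec)
  # rim voxels take the nucleus RI at weight 1; they lie outside the nucleus
  u2 <- tomoshell:::phantom_radial2(spec)
  rim <- u2 <= 1 & u2 >= 0.75^2
  expect_true(all(tom$ri[rim] == spec$nucleus_ri))
  core <- u2 > spec$nucleus_radius_fraction^2 & u2 < 0.75^2
  expect_true(all(tom$ri[core] == spec$cytoplasm_ri))
})

test_that("covariate generation hits its target correlation", {
  base <- phantom_spec(cell_radius_um = 1.1, voxel_spacing_um = 0.35,
                       grid_shape = c(16, 16, 16))
  groups <- list(
    group_effect_spec("H", n_cells = 100, n_subjects = 100, subject_sd_ri = 0.002),
    group_effect_spec("T1", n_cells = 100, n_subjects = 100, ri_offset = 0.006,
                      subject_sd_ri = 0.002))
  covs <- list(clinical_covariate_spec("cpos", 0.9, 50, 20),
               clinical_covariate_spec("cneg", -0.8, 10, 4))
  ch <- make_cohort(groups, covs, base, seed = 21)
  subj <- unique(ch$table[, c("subject_id", "subject_mean_ri", "cpos", "cneg")])
  expect_equal(nrow(subj), 200)
  expect_lt(abs(cor(subj$subject_mean_ri, subj$cpos) - 0.9), 0.05)
  expect_lt(abs(cor(subj$subject_mean_ri, subj$cneg) + 0.8), 0.05)
})

test_that("an out-of-range target correlation is rejected", {
  expect_error(clinical_covariate_spec("bad", 1.2, 0, 1), "\\[-1, 1\\]")
})

test_that("cohorts are reproducible from the seed and carry group structure", {
  base <- phantom_spec(cell_radius_um = 2, voxel_spacing_um = 0.35,
                       grid_shape = c(24, 24, 24), noise_sd = 0.002)
  groups <- list(group_effect_spec("H", n_cells = 6, n_subjects = 3),
                 group_effect_spec("T1", n_cells = 6, n_subjects = 3,
                                   radius_scale = 1.25, ri_offset = 0.006))
  a <- make_cohort(groups, base = base, seed = 5)
  b <- make_cohort(groups, base = base, seed = 5)
  expect_identical(a$table, b$table)
  expect_identical(a$tomograms[["cell00001"]]$ri, b$tomograms[["cell00001"]]$ri)
  expect_error(make_cohort(groups[1], base = base, seed = 1), "at least 2 groups")
  # configured T1 enlargement is visible in extracted volumes
  feats <- extract_features(a$tomograms)
  vt1 <- mean(feats$volume_fl[feats$group == "T1"])
  vh <- mean(feats$volume_fl[feats$group == "H"])
  expect_gt(vt1, vh)
})
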