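test_that("raw format round-trips bit-identically once written", {
  tom <- make_phantom(tiny_spec(noise_sd = 0.002), seed = 3, cell_id = "c1",
                      labels = list(group = "H", subject_id = "s1"))
  d <- withr::local_tempdir()
  write_tomogram(tom, d, format = "raw")
  a <- read_tomogram(file.path(d, "c1.raw"))
  write_tomogram(a, d, format = "raw")
  b <- read_tomogram(file.path(d, "c1.json"))
  expect_identical(a$ri, b$ri)
  # float32 storage is within single precision of the original
  expect_lt(max(abs(a$ri - tom$ri)), 1e-6)
  expect_identical(a$voxel_spacing_um, tom$voxel_spacing_um)
  expect_identical(a$medium_ri, tom$medium_ri)
  expect_identical(a$labels$group, "H")
})

test_that("TIFF format round-trips volume and metadata to quantization accuracy", {
  tom <- make_phantom(tiny_spec(noise_sd = 0.002), seed = 4, cell_id = "c2")
  d <- withr::local_tempdir()
  write_tomogram(tom, d, format = "tiff")
  back <- read_tomogram(file.path(d, "c2.tif"))
  expect_equal(back$ri, tom$ri, tolerance = 1e-9)
  expect_identical(dim(back$ri), dim(tom$ri))
  expect_identical(back$cell_id, "c2")
})

test_that("a sidecar missing a required key is an error naming the key", {
  tom <- make_phantom(tiny_spec(), cell_id = "c3")
  d <- withr::local_tempdir()
  write_tomogram(tom, d, format = "tiff")
  meta <- jsonlite::read_json(file.path(d, "c3.json"))
  meta$medium_ri <- NULL
  jsonlite::write_json(meta, file.path(d, "c3.json"), auto_unbox = TRUE)
  expect_error(read_tomogram(file.path(d, "c3.tif")), "medium_ri")
  file.remove(file.path(d, "c3.json"))
  expect_error(read_tomogram(file.path(d, "c3.tif")), "sidecar")
})

test_that("a page count that contradicts the declared shape is an error", {
  tom <- make_phantom(phantom_spec(cell_radius_um = 1, voxel_spacing_um = 0.4,
                                   grid_shape = c(12, 12, 12)), cell_id = "c4")
  d <- withr::local_tempdir()
  write_tomogram(tom, d, format = "tiff")
  meta <- jsonlite::read_json(file.path(d, "c4.json"), simplifyVector = TRUE)
  meta$shape <- c(13, 12, 12)
  jsonlite::write_json(meta, file.path(d, "c4.json"), auto_unbox = TRUE)
  expect_error(read_tomogram(file.path(d, "c4.tif")), "shape mismatch")
})

test_that("QC keeps a centred cell and rejects crowded or truncated fields", {
  ok <- make_phantom(tiny_spec(), cell_id = "good")
  # two disjoint cells of similar size in one volume
  two <- make_phantom(phantom_spec(cell_radius_um = 1.6, voxel_spacing_um = 0.3,
                                   grid_shape = c(40, 40, 40),
                                   center_offset_vox = c(-10, 0, 0)),
                      cell_id = "pair")
  second <- make_phantom(phantom_spec(cell_radius_um = 1.6, voxel_spacing_um = 0.3,
                                      grid_shape = c(40, 40, 40),
                                      center_offset_vox = c(10, 0, 0)))
  two$ri <- pmax(two$ri, second$ri)
  # a cell pushed against the border
  ri <- make_phantom(tiny_spec(), cell_id = "edge")$ri
  shifted <- array(ri[1, 1, 1], dim = dim(ri))
  shifted[1:20, , ] <- ri[13:32, , ]  # push foreground onto the z = 1 face
  edge <- tomogram(shifted, c(0.3, 0.3, 0.3), medium_ri = 1.337, cell_id = "edge")
  # nothing but medium
  blank <- tomogram(array(1.337, dim = c(16, 16, 16)), 0.3, 1.337, cell_id = "blank")

  res <- qc_filter(list(ok, two, edge, blank))
  expect_named(res$kept, "good")
  expect_setequal(res$rejected$cell_id, c("pair", "edge", "blank"))
  expect_match(res$rejected$reason[res$rejected$cell_id == "pair"], "multiple components")
  expect_match(res$rejected$reason[res$rejected$cell_id == "edge"], "border contact")
  expect_match(res$rejected$reason[res$rejected$cell_id == "blank"], "foreground fraction")
  # pure function: same verdicts on a second call
  res2 <- qc_filter(list(ok, two, edge, blank))
  expect_identical(res$rejected, res2$rejected)
  # empty input is an empty result, not an error
  expect_identical(qc_filter(list())$rejected$cell_id, character(0))
})
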