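set.seed(42)

test_that("CT series round-trips voxels, geometry and metadata", {
  vol <- image_volume(array(sample(-1000:2000, 24 * 24 * 3, TRUE),
                            c(24, 24, 3)),
                      origin = c(-30, -30), pixel_spacing = c(2.5, 2.5),
                      slice_positions = c(-6, 0, 6), modality = "MV",
                      acquisition_date = as.Date("2013-05-02"),
                      machine_id = "B")
  d <- withr::local_tempdir()
  write_ct_series(vol, d)
  v2 <- read_ct_series(d)
  expect_identical(v2$voxels, vol$voxels)
  expect_equal(v2$origin, vol$origin)
  expect_equal(v2$pixel_spacing, vol$pixel_spacing)
  expect_equal(v2$slice_positions, vol$slice_positions)
  expect_identical(v2$modality, "MV")
  expect_identical(v2$machine_id, "B")
  expect_identical(v2$acquisition_date, as.Date("2013-05-02"))
})

test_that("slices are sorted by z regardless of file order on disk", {
  vol <- image_volume(array(rep(1:4, each = 16), c(4, 4, 4)),
                      origin = c(0, 0), pixel_spacing = c(1, 1),
                      slice_positions = c(0, 6, 12, 18))
  d <- withr::local_tempdir()
  write_ct_series(vol, d)
  # shuffle on disk by renaming: reverse the slice file names
  files <- sort(list.files(d, full.names = TRUE))
  tmp <- file.path(d, "zz.tmp")
  file.rename(files[1], tmp)
  file.rename(files[4], files[1])
  file.rename(tmp, files[4])
  v2 <- read_ct_series(d)
  expect_equal(v2$slice_positions, c(0, 6, 12, 18))
  expect_identical(v2$voxels, vol$voxels)
})

test_that("reader rejects inconsistent series", {
  vol <- image_volume(array(0, c(4, 4, 2)), origin = c(0, 0),
                      pixel_spacing = c(1, 1), slice_positions = c(0, 6))
  # missing position attribute
  d1 <- withr::local_tempdir()
  write_ct_series(vol, d1)
  f <- sort(list.files(d1, full.names = TRUE))[1]
  e <- voxcalc:::dcm_read(f)
  e <- Filter(function(el) !(el$group == 0x0020 && el$element == 0x0032), e)
  voxcalc:::dcm_write(e, f)
  expect_error(read_ct_series(d1), "position")
  # mixed frames of reference
  d2 <- withr::local_tempdir()
  write_ct_series(vol, d2)
  vol2 <- vol; vol2$frame_of_reference <- "FOR.other"
  vol2$slice_positions <- c(12, 18)
  d2b <- withr::local_tempdir()
  write_ct_series(vol2, d2b)
  file.copy(list.files(d2b, full.names = TRUE)[1],
            file.path(d2, "extra.dcm"))
  expect_error(read_ct_series(d2), "frames of reference")
  # non-uniform in-plane spacing across slices
  d3 <- withr::local_tempdir()
  write_ct_series(vol, d3)
  f3 <- sort(list.files(d3, full.names = TRUE))[2]
  e3 <- voxcalc:::dcm_read(f3)
  for (i in seq_along(e3))
    if (e3[[i]]$group == 0x0028 && e3[[i]]$element == 0x0030)
      e3[[i]]$value <- c(2, 2)
  voxcalc:::dcm_write(e3, f3)
  expect_error(read_ct_series(d3), "spacing")
})

test_that("registration tags round-trip and defaults follow the contract", {
  vol <- water_volume(slices = 2)
  d <- withr::local_tempdir()
  write_ct_series(vol, d, reg = registration(1.2, -3, 5, 0.4))
  r <- read_registration(read_ct_series(d))
  expect_equal(c(r$dx, r$dy, r$dz, r$roll), c(1.2, -3, 5, 0.4))
  expect_true(r$usable)

  # skip tag present -> unusable
  d2 <- withr::local_tempdir()
  write_ct_series(vol, d2, reg = registration(0, 0, 0, 0, usable = FALSE))
  expect_false(read_registration(read_ct_series(d2))$usable)

  # roll tag absent -> roll 0 with a warning
  d3 <- withr::local_tempdir()
  write_ct_series(vol, d3, reg = registration(1, 2, 3, 0.5))
  for (f in list.files(d3, full.names = TRUE)) {
    e <- voxcalc:::dcm_read(f)
    e <- Filter(function(el) !(el$group == 0x0071 && el$element == 0x1004),
                e)
    voxcalc:::dcm_write(e, f)
  }
  expect_warning(r3 <- read_registration(read_ct_series(d3)), "roll")
  expect_equal(r3$roll, 0)
  expect_equal(r3$dz, 3)

  # missing shift tags -> error naming the fraction
  d4 <- withr::local_tempdir()
  write_ct_series(vol, d4)
  expect_error(read_registration(read_ct_series(d4)), "fraction")
})

test_that("RTDOSE round-trips within the 16-bit scaling quantum", {
  set.seed(7)
  cube <- dose_cube(array(runif(16 * 16 * 3, 0, 2.2), c(16, 16, 3)),
                    origin = c(-10, -10), pixel_spacing = c(3, 3),
                    slice_positions = c(0, 6, 12), downsample_factor = 2)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dose(cube, f)
  c2 <- read_dose(f)
  expect_lt(max(abs(c2$dose - cube$dose)) / max(cube$dose), 2^-15)
  expect_equal(c2$origin, cube$origin)
  expect_equal(c2$pixel_spacing, cube$pixel_spacing)
  expect_equal(c2$slice_positions, cube$slice_positions)
  expect_identical(c2$downsample_factor, 2L)

  zero <- dose_cube(array(0, c(4, 4, 2)), c(0, 0), c(1, 1), c(0, 6))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_dose(zero, f2)
  expect_identical(read_dose(f2)$dose, zero$dose)

  expect_error(dose_cube(array(-1, c(2, 2, 1)), c(0, 0), c(1, 1), 0),
               "non-negative")
})

test_that("structure sets round-trip vertices and slice assignment", {
  cs <- contour_set(list(
    list(z = 0, vertices = regular_polygon(10, c(0, 60), 12)),
    list(z = 6, vertices = regular_polygon(11, c(1, 61), 12)),
    list(z = 12, vertices = rbind(c(-5, 55), c(5, 55), c(5, 65), c(-5, 65)))),
    structure_name = "Rectum")
  f <- withr::local_tempfile(fileext = ".dcm")
  write_structure_set(cs, f)
  cs2 <- read_structure_set(f)
  expect_identical(cs2$structure_name, "Rectum")
  expect_equal(contour_zs(cs2), c(0, 6, 12))
  for (i in 1:3)
    expect_lt(max(abs(cs2$contours[[i]]$vertices -
                        cs$contours[[i]]$vertices)), 0.01)
})

test_that("degenerate polygons are rejected by the container", {
  expect_error(contour_set(list(list(z = 0,
                                     vertices = rbind(c(0, 0), c(1, 1))))),
               ">= 3")
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_error(contour_set(list(list(z = 0, vertices = sq))), "closed")
})
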