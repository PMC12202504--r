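test_that("write/read round-trip preserves values, spacing and origin", {
  set.seed(7)
  g <- image_grid(array(rnorm(10 * 9 * 8, 0, 100), c(10, 9, 8)),
                  spacing = c(0.7, 0.7, 0.625), origin = c(-12, 5.5, 30))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(g, f)
  g2 <- load_volume(f)
  expect_lt(max(abs(g2$values - g$values)), 1e-4)
  expect_lt(max(abs(g2$spacing - g$spacing)), 1e-4)
  expect_lt(max(abs(g2$origin - g$origin)), 1e-4)

  m <- binary_mask(g$values > 50, grid = g)
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, fm)
  m2 <- load_mask(fm)
  expect_identical(m2$values, m$values)
})

test_that("degenerate headers and payloads are rejected with informative errors", {
  expect_error(load_volume("does/not/exist.nii"), "not found")
  # non-positive spacing is rejected at the geometry level; the NIfTI
  # reader itself sanitises a zero pixdim on disk (patched at header offset
  # 80 here), so a loaded volume must always carry positive spacing
  expect_error(image_grid(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)),
               "spacing")
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4))), f)
  con <- file(f, "r+b")
  seek(con, 80, rw = "write")
  writeBin(0, con, size = 4)
  close(con)
  g_or_err <- tryCatch(load_volume(f), error = function(e) e)
  if (inherits(g_or_err, "image_grid")) {
    expect_true(all(g_or_err$spacing > 0))
  } else {
    expect_match(conditionMessage(g_or_err), "pixdim")
  }
  # 4-D with singleton trailing axis squeezes; real 4-D rejected
  f4 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 1))), f4)
  expect_identical(dim(load_volume(f4)$values), c(4L, 4L, 4L))
  f4b <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 2))), f4b)
  expect_error(load_volume(f4b), "3-D")
  expect_error(image_grid(array(Inf, c(2, 2, 2))), "finite")
})

test_that("alignment check passes within tolerance and names mismatching axes", {
  g <- image_grid(array(0, c(8, 8, 5)), spacing = c(1, 1, 2))
  ok <- check_aligned(g, binary_mask(array(FALSE, c(8, 8, 5)),
                                     spacing = c(1, 1, 2)))
  expect_true(ok$ok)
  # spacing differing below the 1e-4 mm tolerance still passes
  near <- check_aligned(g, binary_mask(array(FALSE, c(8, 8, 5)),
                                       spacing = c(1, 1, 2 + 1e-6)))
  expect_true(near$ok)
  # one extra slice fails, naming axis 3
  bad <- check_aligned(g, binary_mask(array(FALSE, c(8, 8, 6)),
                                      spacing = c(1, 1, 2)))
  expect_false(bad$ok)
  expect_match(bad$failures, "axis 3", all = FALSE)
})

test_that("exclude_region clears exactly the boxed voxels and is idempotent", {
  m <- array(FALSE, c(6, 6, 6))
  m[2:4, 2:4, 2:4] <- TRUE            # 27 voxels
  bm <- binary_mask(m)
  # half-open 0-based box covering a 2x2x1 corner of the cube: 4 voxels
  box <- list(lo = c(1, 1, 1), hi = c(3, 3, 2))
  out <- exclude_region(bm, box)
  expect_equal(sum(out$values), 27 - 4)
  expect_equal(sum(bm$values), 27)    # input untouched
  # idempotent and monotone
  out2 <- exclude_region(out, box)
  expect_identical(out2$values, out$values)
  expect_true(all(out$values <= bm$values))
  # whole-lattice box empties the mask; degenerate box changes nothing
  expect_equal(sum(exclude_region(bm, list(lo = c(0, 0, 0),
                                           hi = c(6, 6, 6)))$values), 0)
  expect_identical(exclude_region(bm, list(lo = c(2, 2, 2),
                                           hi = c(2, 5, 5)))$values,
                   bm$values)
  expect_error(exclude_region(bm, list(lo = c(10, 0, 0), hi = c(12, 3, 3))),
               "outside")
})

test_that("centerline arc-length matches geometry for straight and helical tubes", {
  # straight tube: arc-length equals slice spacing times (slices - 1)
  m <- array(FALSE, c(9, 9, 12))
  m[4:6, 4:6, ] <- TRUE
  bm <- binary_mask(m, spacing = c(0.7, 0.7, 0.625))
  cl <- centerline(bm)
  expect_equal(max(cl$arclength_mm), 0.625 * 11, tolerance = 1e-12)
  # full z-extent of a 40-slice grid at 0.625 mm is 25 mm of arc
  m2 <- array(FALSE, c(6, 6, 40)); m2[3, 3, ] <- TRUE
  cl2 <- centerline(binary_mask(m2, spacing = c(0.7, 0.7, 0.625)))
  expect_equal(max(cl2$arclength_mm), 40 * 0.625 - 0.625, tolerance = 1e-12)
  # helical tube: arc-length strictly exceeds the z-extent and matches the
  # brute-force polyline length of the centroid path
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 24),
                                  centerline = "helical",
                                  helix_radius_mm = 4, helix_pitch_mm = 24,
                                  lumen_radius_mm = 2.5,
                                  wall_thickness_mm = 1))
  clh <- centerline(ph$mask)
  z_extent <- max(clh$z_mm) - min(clh$z_mm)
  expect_gt(max(clh$arclength_mm), z_extent)
  pts <- as.matrix(clh[, c("x_mm", "y_mm", "z_mm")])
  expect_equal(max(clh$arclength_mm), sum(sqrt(rowSums(diff(pts)^2))),
               tolerance = 1e-12)
})

test_that("crop_range keeps exactly the slices inside the arc-length window", {
  m <- array(FALSE, c(9, 9, 30))
  m[4:6, 4:6, ] <- TRUE
  g <- image_grid(array(rnorm(9 * 9 * 30), c(9, 9, 30)))
  bm <- binary_mask(m)
  # straight tube, 1 mm z-spacing: [0, 10] keeps 11 slices
  cr <- crop_range(g, bm, 0, 10)
  expect_identical(cr$slices, 1:11)
  expect_identical(dim(cr$grid$values), c(9L, 9L, 11L))
  expect_identical(cr$grid$values[, , 1], g$values[, , 1])
  # full-range crop is the identity
  full <- crop_range(g, bm, 0, 1e6)
  expect_identical(full$grid$values, g$values)
  expect_true(all(cr$mask$values <= bm$values[, , 1:11]))
  expect_error(crop_range(g, bm, 500, 600), "no slice")
  expect_error(crop_range(g, binary_mask(array(FALSE, c(9, 9, 30))), 0, 10),
               "empty")
})
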