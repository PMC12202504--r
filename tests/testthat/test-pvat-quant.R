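test_that("distance map equals brute force on small random lattices", {
  set.seed(11)
  cases <- list(
    list(d = c(9, 8, 7), sp = c(0.7, 1.1, 2.0), p = 0.08),
    list(d = c(12, 12, 12), sp = c(1, 1, 1), p = 0.03),
    list(d = c(16, 16, 16), sp = c(0.5, 0.5, 0.625), p = 0.01),
    list(d = c(7, 13, 5), sp = c(2, 0.4, 1.3), p = 0.15))
  for (cs in cases) {
    m <- array(runif(prod(cs$d)) < cs$p, dim = cs$d)
    m[ceiling(cs$d[1] / 2), ceiling(cs$d[2] / 2), ceiling(cs$d[3] / 2)] <- TRUE
    bm <- binary_mask(m, spacing = cs$sp)
    expect_lt(max(abs(surface_distance_map(bm) -
                        brute_force_distance(m, cs$sp))), 1e-9)
  }
})

test_that("distance metric respects neighbours and anisotropy", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  d_iso <- surface_distance_map(binary_mask(m, spacing = c(1, 1, 1)))
  expect_equal(d_iso[4, 4, 4], 0)
  expect_equal(d_iso[5, 4, 4], 1)
  expect_equal(d_iso[5, 5, 4], sqrt(2))
  expect_equal(d_iso[5, 5, 5], sqrt(3))
  d_ani <- surface_distance_map(binary_mask(m, spacing = c(1, 1, 2)))
  expect_equal(d_ani[4, 4, 5], 2)     # coarse-axis neighbour is 2 mm away
  expect_equal(d_ani[5, 4, 4], 1)
  expect_error(surface_distance_map(binary_mask(array(FALSE, c(3, 3, 3)))),
               "empty")
})

test_that("ring extraction matches enumeration and honours boundary rules", {
  m <- array(FALSE, c(27, 27, 27)); m[14, 14, 14] <- TRUE
  bm <- binary_mask(m)
  dist <- surface_distance_map(bm)
  rings <- extract_rings(dist, ring_spec(), bm)
  # brute-force enumeration of center distances for a single-voxel mask
  idx <- which(array(TRUE, c(27, 27, 27)), arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(idx, 2, c(14, 14, 14))^2))
  expect_equal(sum(rings$close$values), sum(r >= 2 & r <= 5))
  expect_equal(sum(rings$distant$values), sum(r >= 10 & r <= 12))
  # rings disjoint, mask voxels excluded
  expect_equal(sum(rings$close$values & rings$distant$values), 0)
  expect_false(rings$close$values[14, 14, 14])
  # touching intervals: a voxel at exactly the shared boundary is close-only
  touching <- ring_spec(2, 5, 5, 10)
  rt <- extract_rings(dist, touching, bm)
  at5 <- which(dist == 5)             # e.g. offsets (3,4,0) and (0,0,5)
  expect_gt(length(at5), 0)
  expect_true(all(rt$close$values[at5]))
  expect_false(any(rt$distant$values[at5]))
  expect_error(ring_spec(5, 2), "close_lo")
  expect_error(ring_spec(2, 5, 4, 12), "distant_lo")
})

test_that("fat filter applies inclusive HU bounds over the region", {
  vals <- array(0, c(4, 1, 1))
  vals[, 1, 1] <- c(-200, -100, -30, 0)
  g <- image_grid(vals)
  region <- binary_mask(array(TRUE, c(4, 1, 1)))
  fat <- fat_filter(g, region)
  expect_identical(as.vector(fat$values), c(FALSE, TRUE, TRUE, FALSE))
  # region entirely outside the window -> empty fat mask is allowed
  g2 <- image_grid(array(40, c(4, 1, 1)))
  expect_equal(sum(fat_filter(g2, region)$values), 0)
  # monotone in the window: enlarging it never loses voxels
  set.seed(3)
  g3 <- image_grid(array(rnorm(5^3, -80, 80), c(5, 5, 5)))
  region3 <- binary_mask(array(TRUE, c(5, 5, 5)))
  narrow <- fat_filter(g3, region3, fat_window(-120, -60))
  wide <- fat_filter(g3, region3, fat_window(-180, -30))
  expect_true(all(narrow$values <= wide$values))
  expect_error(fat_window(-30, -180), "lo_hu")
})

test_that("indices follow their defining identities and flag empty masks", {
  # constructed two-ring volume: close at -70, distant at -80
  vals <- array(0, c(6, 1, 1))
  vals[1:3, 1, 1] <- -70; vals[4:6, 1, 1] <- -80
  g <- image_grid(vals)
  close <- binary_mask(array(c(rep(TRUE, 3), rep(FALSE, 3)), c(6, 1, 1)))
  distant <- binary_mask(array(c(rep(FALSE, 3), rep(TRUE, 3)), c(6, 1, 1)))
  m <- pvat_indices(g, close, distant)
  expect_equal(m$hu_delta, 10)
  expect_equal(m$hu_ratio, 0.875)
  expect_true(m$valid)
  # identities hold exactly
  expect_identical(m$hu_delta, m$hu_close - m$hu_distant)
  expect_identical(m$hu_ratio, m$hu_close / m$hu_distant)
  # identical rings give the identity measurement
  m2 <- pvat_indices(g, close, close)
  expect_equal(m2$hu_delta, 0)
  expect_equal(m2$hu_ratio, 1)
  # an empty fat mask flags the measurement invalid, never silent zeros
  empty <- binary_mask(array(FALSE, c(6, 1, 1)))
  m3 <- pvat_indices(g, close, empty)
  expect_false(m3$valid)
  expect_true(is.na(m3$hu_delta))
})

test_that("volumetric thickness matches slab geometry and scales with volume", {
  # thin wide slab in the lattice middle; fat fills the close ring on both
  # flat faces (4 voxel layers at d = 2..5 mm per face)
  d <- c(30, 30, 14)
  m <- array(FALSE, d); m[, , 7:8] <- TRUE
  bm <- binary_mask(m)
  dist <- surface_distance_map(bm)
  rings <- extract_rings(dist, ring_spec(), bm)
  qc <- thickness_qc(rings$close, rings$close, bm)
  # exact slab arithmetic: fat volume 2*900*4 mm^3, exposed surface
  # 2*900 + perimeter*height = 2040 mm^2 -> 7200/2040 mm
  expect_equal(qc$thick_close_mm, 7200 / 2040, tolerance = 1e-12)
  # at or above the nominal 3 mm ring width: QC passes at the 3 mm threshold
  expect_true(qc$qc_pass)
  # halving the fat at fixed surface halves the thickness
  half <- rings$close$values
  half[, , seq(2, d[3], 2)] <- FALSE
  bm_half <- binary_mask(half)
  qc_half <- thickness_qc(bm_half, bm_half, bm)
  ratio <- sum(half) / sum(rings$close$values)
  expect_equal(qc_half$thick_close_mm, qc$thick_close_mm * ratio,
               tolerance = 1e-12)
  # no fat at all -> zero thickness, QC fails
  none <- binary_mask(array(FALSE, d))
  qc0 <- thickness_qc(none, none, bm)
  expect_equal(qc0$thick_close_mm, 0)
  expect_false(qc0$qc_pass)
  expect_error(thickness_qc(none, none, none), "empty")
})

test_that("measurements are invariant under joint translation", {
  ph <- small_phantom(shape = c(44, 44, 12))
  m1 <- measure_pvat(ph$grid, ph$mask)
  # shift volume and mask together by 2 voxels in x (wrap-free region)
  shift <- function(a, fill) {
    out <- array(fill, dim = dim(a))
    out[3:dim(a)[1], , ] <- a[1:(dim(a)[1] - 2), , ]
    out
  }
  g2 <- image_grid(shift(ph$grid$values, 20), spacing = ph$grid$spacing)
  m2v <- shift(ph$mask$values, FALSE)
  m2 <- measure_pvat(g2, binary_mask(m2v, spacing = ph$mask$spacing))
  expect_equal(m2$hu_close, m1$hu_close, tolerance = 1e-9)
  expect_equal(m2$hu_distant, m1$hu_distant, tolerance = 1e-9)
  expect_equal(m2$n_fat_close, m1$n_fat_close)
})
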