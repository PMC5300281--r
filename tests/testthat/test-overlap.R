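test_that("Jaccard index hits the exact endpoints and is symmetric", {
  s <- fxSphere10()
  g <- buildGrid(s, spacing = 1, margin = 2)
  expect_identical(jaccardIndex(s, s, g), 1)

  far <- transformSurface(s, rigidFromAxisAngle(c(0, 0, 1), 0, c(40, 0, 0)))
  g2 <- buildGrid(list(s, far), spacing = 1, margin = 2)
  expect_identical(jaccardIndex(s, far, g2), 0)
  expect_identical(jaccardIndex(s, far, g2), jaccardIndex(far, s, g2))

  mid <- transformSurface(s, rigidFromAxisAngle(c(0, 0, 1), 0, c(10, 0, 0)))
  g3 <- buildGrid(list(s, mid), spacing = 1, margin = 2)
  j <- jaccardIndex(s, mid, g3)
  expect_identical(j, jaccardIndex(mid, s, g3))
  expect_true(j > 0 && j < 1)
})

test_that("two-sphere overlap approaches the analytic lens value", {
  # spheres of radius r with centers r apart: lens/union = 5/27 exactly
  a <- extractSurface(rasterize(shapeSpec("sphere", radii = 8), c(23, 23, 23)))
  b <- extractSurface(rasterize(shapeSpec("sphere", center = c(8, 0, 0),
                                          radii = 8), c(23, 23, 23)))
  g <- buildGrid(list(a, b), spacing = 0.5, margin = 2)
  expect_equal(jaccardIndex(a, b, g), 5 / 27, tolerance = 0.02)
})

test_that("regional Jaccard respects the ROI constraint and 0/0 is missing", {
  s <- fxSphere10()
  shifted <- transformSurface(s, rigidFromAxisAngle(c(0, 0, 1), 0, c(5, 0, 0)))
  roiAll <- boxSurface(c(-15, -15, -15), c(20, 15, 15))
  g <- buildGrid(list(s, shifted, roiAll), spacing = 1, margin = 2)

  # ROI containing A and B entirely: constraint inactive
  expect_identical(regionalJaccard(s, shifted, roiAll, g),
                   jaccardIndex(s, shifted, g))
  # identical surfaces within any intersecting ROI
  roiHalf <- boxSurface(c(-15, -15, -15), c(0.123, 15, 15))
  expect_identical(regionalJaccard(s, s, roiHalf, g), 1)
  # disjoint ROI: undefined, not zero
  roiFar <- boxSurface(c(30, -5, -5), c(40, 5, 5))
  gf <- buildGrid(list(s, shifted, roiFar), spacing = 1, margin = 2)
  expect_warning(val <- regionalJaccard(s, shifted, roiFar, gf), "undefined")
  expect_true(is.na(val))
})

test_that("regional volumes count only the ROI-constrained interior", {
  s <- fxSphere10fine()
  g <- buildGrid(s, spacing = 0.25, margin = 2)
  whole <- boxSurface(c(-12, -12, -12), c(12, 12, 12))
  expect_equal(regionalVolume(s, whole, g), gridVolume(occupancy(s, g)),
               tolerance = 1e-12)
  # half-space through the center: each half near half the analytic volume
  left <- boxSurface(c(-12, -12, -12), c(0, 12, 12))
  right <- boxSurface(c(0, -12, -12), c(12, 12, 12))
  vHalf <- 2 / 3 * pi * 10^3
  expect_equal(regionalVolume(s, left, g), vHalf, tolerance = 0.02)
  expect_equal(regionalVolume(s, right, g), vHalf, tolerance = 0.02)
  far <- boxSurface(c(30, -5, -5), c(40, 5, 5))
  gf <- buildGrid(list(s, far), spacing = 0.5, margin = 2)
  expect_identical(regionalVolume(s, far, gf), 0)
})

test_that("comparePair is consistent with the standalone metrics", {
  a <- fxSphere10()
  b <- transformSurface(a, rigidFromAxisAngle(c(0, 0, 1), 0, c(4, 0, 0)))
  rec <- comparePair(a, b, spacing = 0.5)
  g <- buildGrid(list(a, b), spacing = 0.5, margin = 2)
  expect_identical(rec@globalJaccard, jaccardIndex(a, b, g))
  expect_identical(rec@volumeA, gridVolume(occupancy(a, g)))

  # identical pair: all defined metrics are 1
  slabs <- list(lowx = boxSurface(c(-12.01, -12.02, -12.03), c(-3.3, 12, 12)),
                midx = boxSurface(c(-3.3, -12.02, -12.03), c(3.3, 12, 12)),
                hix = boxSurface(c(3.3, -12.02, -12.03), c(12.3, 12, 12)))
  rec2 <- comparePair(a, a, regions = slabs, spacing = 1)
  expect_identical(rec2@globalJaccard, 1)
  expect_true(all(rec2@regionalJaccard == 1))

  # slab regions tiling the bounding region: regional volumes sum to global
  expect_equal(sum(rec2@regionalVolumeA), rec2@volumeA, tolerance = 1e-3)
  df <- as.data.frame(rec2)
  expect_true(all(c("jacc_global", "jacc_midx", "vol_A_total", "vol_B_hix",
                    "mesh_vol_A") %in% names(df)))
})

test_that("overlap metrics are invariant under a common translation", {
  a <- fxSphere10()
  b <- transformSurface(a, rigidFromAxisAngle(c(0, 0, 1), 0, c(6, 0, 0)))
  g <- buildGrid(list(a, b), spacing = 1, margin = 2)
  j0 <- jaccardIndex(a, b, g)
  shift <- c(1.23, -0.5, 4.07)
  tshift <- rigidFromAxisAngle(c(1, 0, 0), 0, shift)
  g2 <- new("SampleGrid", origin = g@origin + shift, spacing = g@spacing,
            dims = g@dims)
  expect_identical(jaccardIndex(transformSurface(a, tshift),
                                transformSurface(b, tshift), g2), j0)
})
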