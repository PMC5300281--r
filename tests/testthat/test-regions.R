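test_that("long-axis split reproduces requested volume fractions", {
  mask <- rasterize(shapeSpec("ellipsoid", radii = c(20, 8, 8)),
                    c(93, 45, 45), voxelSize = 0.5)
  rs <- splitLongAxis(mask, c(0.35, 0.45, 0.20))
  # PCA long axis of an x-aligned ellipsoid is x
  expect_gt(abs(regionAxis(rs)[1]), 0.999)
  lab <- voxels(rs@labels)
  cnt <- tabulate(lab[lab > 0], 3)
  expect_identical(sum(cnt), sum(voxels(mask) != 0L))   # exact partition
  # an axis-aligned ellipsoid has whole voxel layers sharing one projection
  # value, so cuts land between layers: fractions are met to within half a
  # layer (absolute), not better
  frac <- cnt / sum(cnt)
  expect_lt(abs(frac[1] - 0.35), 0.02)
  expect_lt(abs(frac[2] - 0.45), 0.02)
  expect_lt(abs(frac[3] - 0.20), 0.02)
  # an oblique ellipsoid (generic orientation, no projection ties) meets the
  # fractions essentially exactly
  maskO <- rasterize(shapeSpec("ellipsoid", radii = c(20, 8, 8)),
                     c(95, 65, 65), voxelSize = 0.5,
                     rotation = rigidFromAxisAngle(c(0.2, 0.5, 1), 30))
  rsO <- splitLongAxis(maskO, c(0.35, 0.45, 0.20))
  labO <- voxels(rsO@labels)
  fracO <- tabulate(labO[labO > 0], 3) / sum(labO > 0)
  expect_lt(abs(fracO[1] / 0.35 - 1), 0.001)
  expect_lt(abs(fracO[2] / 0.45 - 1), 0.001)
  expect_lt(abs(fracO[3] / 0.20 - 1), 0.001)
  # anterior occupies the high end of the axis
  ctr <- vapply(1:3, function(l) {
    idx <- which(lab == l)
    mean(applyTransform(mask@affine, arrayInd(idx, dim(lab)) - 1L) %*%
           regionAxis(rs))
  }, 0)
  expect_true(ctr[1] > ctr[2] && ctr[2] > ctr[3])
})

test_that("uniform bar is cut at equal length fractions", {
  vox <- array(0L, c(34, 8, 8)); vox[3:32, 3:6, 3:6] <- 1L
  rs <- splitLongAxis(LabelVolume(vox), c(1, 1, 1) / 3)
  # bar spans 30 voxels; cuts at 1/3 and 2/3 of its length (+-1 voxel layer)
  expect_equal(diff(rs@cuts), 10, tolerance = 0.1)
  cnt <- tabulate(voxels(rs@labels)[voxels(rs@labels) > 0], 3)
  expect_true(all(abs(cnt / sum(cnt) - 1 / 3) < 0.04))
})

test_that("degenerate masks fail or warn as documented", {
  few <- array(0L, c(5, 5, 5)); few[2:3, 2, 2] <- 1L
  expect_error(splitLongAxis(LabelVolume(few)), "fewer than 10")
  iso <- rasterize(shapeSpec("sphere", radii = 6), c(17, 17, 17))
  expect_warning(splitLongAxis(iso), "isotropic")
})

test_that("orientAxis flips labels with the hint and is idempotent", {
  mask <- rasterize(shapeSpec("ellipsoid", radii = c(15, 6, 6)), c(37, 17, 17))
  rs <- splitLongAxis(mask)
  same <- orientAxis(rs, regionAxis(rs))
  expect_identical(regionAxis(same), regionAxis(rs))
  expect_identical(regionSurfaces(same), regionSurfaces(rs))

  flip <- orientAxis(rs, -regionAxis(rs))
  expect_identical(regionAxis(flip), -regionAxis(rs))
  expect_identical(vertices(regionSurfaces(flip)$anterior),
                   vertices(regionSurfaces(rs)$posterior))
  expect_identical(regionSurfaces(orientAxis(flip, regionAxis(flip))),
                   regionSurfaces(flip))  # idempotent
  expect_error(orientAxis(rs, c(0, 1, 0)), "perpendicular")
})

test_that("region occupancies partition the mask pointwise", {
  mask <- rasterize(shapeSpec("ellipsoid", radii = c(15, 6, 6)), c(37, 17, 17))
  rs <- splitLongAxis(mask)
  whole <- extractSurface(mask)
  g <- buildGrid(c(unname(regionSurfaces(rs)), list(whole)), spacing = 0.5)
  ro <- regionOccupancy(rs, g)
  expect_false(any(ro$anterior & ro$middle))
  expect_false(any(ro$anterior & ro$posterior))
  expect_false(any(ro$middle & ro$posterior))
  uni <- ro$anterior | ro$middle | ro$posterior
  raw <- occupancy(regionSurfaces(rs)$anterior, g)@flags |
    occupancy(regionSurfaces(rs)$middle, g)@flags |
    occupancy(regionSurfaces(rs)$posterior, g)@flags
  expect_identical(uni, raw)
  # region volumes account for the whole mask volume up to the rim sliver
  wf <- occupancy(whole, g)@flags
  expect_lt(sum(xor(uni, wf)) / sum(wf), 0.01)
})

test_that("mapToSubject transforms surfaces, axis and cuts coherently", {
  mask <- rasterize(shapeSpec("ellipsoid", radii = c(15, 6, 6)), c(37, 17, 17))
  rs <- splitLongAxis(mask)
  expect_identical(vertices(regionSurfaces(mapToSubject(rs, diag(4)))$middle),
                   vertices(regionSurfaces(rs)$middle))

  sc <- diag(c(2, 2, 2, 1))
  rs2 <- mapToSubject(rs, sc)
  expect_equal(meshVolume(regionSurfaces(rs2)$anterior),
               8 * meshVolume(regionSurfaces(rs)$anterior), tolerance = 1e-9)
  expect_equal(rs2@cuts, 2 * rs@cuts, tolerance = 1e-9)

  aff <- diag(4); aff[1:3, 1:3] <- matrix(c(1.1, 0.2, 0, -0.1, 0.9, 0.05,
                                            0, 0.1, 1.2), 3, 3)
  aff[1:3, 4] <- c(5, -3, 2)
  back <- mapToSubject(mapToSubject(rs, aff), solve(aff))
  expect_equal(vertices(regionSurfaces(back)$middle),
               vertices(regionSurfaces(rs)$middle), tolerance = 1e-6)
  expect_error(mapToSubject(rs, matrix(0, 4, 4)), "invertible")
})

test_that("splitting commutes with rigid motion of the mask", {
  # oblique mask: generic projections, so no voxel layer sits exactly on a
  # cut where floating-point noise could flip it
  mask <- rasterize(shapeSpec("ellipsoid", radii = c(15, 6, 6)), c(41, 41, 41),
                    rotation = rigidFromAxisAngle(c(0.1, 0.4, 1), 20))
  rot <- rigidFromAxisAngle(c(0, 0, 1), 30, c(4, -2, 1))
  moved <- LabelVolume(voxels(mask), transformMatrix(rot) %*% mask@affine)
  rs <- splitLongAxis(mask)
  rsM <- splitLongAxis(moved)
  # cut positions along the axis are rotation-invariant (up to the voxel
  # layers whose tied projections are split by floating-point noise)
  expect_equal(rsM@cuts, rs@cuts, tolerance = 1e-6)
  cnt <- tabulate(voxels(rs@labels)[voxels(rs@labels) > 0], 3)
  cntM <- tabulate(voxels(rsM@labels)[voxels(rsM@labels) > 0], 3)
  expect_lt(max(abs(cnt - cntM)) / sum(cnt), 0.001)
  # axis co-rotates (up to sign convention)
  ax <- transformMatrix(rot)[1:3, 1:3] %*% regionAxis(rs)
  expect_equal(abs(sum(ax * regionAxis(rsM))), 1, tolerance = 1e-9)
})
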