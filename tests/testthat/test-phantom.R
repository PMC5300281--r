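test_that("rasterization labels exactly the voxel centers inside the shape", {
  vol <- rasterize(shapeSpec("sphere", radii = 10), c(27, 27, 27))
  # brute-force enumeration oracle: integer centers with x^2+y^2+z^2 < 100
  g <- expand.grid(x = -13:13, y = -13:13, z = -13:13)
  expect_identical(sum(voxels(vol) == 1L),
                   sum(g$x^2 + g$y^2 + g$z^2 < 100))

  # tiny sphere centered on a voxel center -> exactly one voxel
  tiny <- rasterize(shapeSpec("sphere", radii = 0.1), c(7, 7, 7))
  expect_identical(sum(voxels(tiny) == 1L), 1L)

  # ellipsoid with equal radii is the same shape as the sphere
  ell <- rasterize(shapeSpec("ellipsoid", radii = c(10, 10, 10)), c(27, 27, 27))
  expect_identical(voxels(ell), voxels(vol))

  # determinism
  expect_identical(voxels(rasterize(shapeSpec("sphere", radii = 10), c(27, 27, 27))),
                   voxels(vol))
})

test_that("rasterization refuses shapes that do not fit and names the axis", {
  expect_error(rasterize(shapeSpec("sphere", radii = 10), c(12, 27, 27)), "x")
  expect_error(rasterize(shapeSpec("ellipsoid", radii = c(5, 5, 14)), c(27, 27, 27)), "z")
})

test_that("back-to-back pairs honour the perturbation and noise contract", {
  # identity + no noise is idempotent
  p0 <- makePair(shapeSpec("sphere", radii = 8), c(23, 23, 23))
  expect_identical(voxels(p0$a), voxels(p0$b))
  expect_identical(transformMatrix(p0$truth), diag(4))

  # the pair of identical volumes has Jaccard exactly 1
  sa <- extractSurface(p0$a); sb <- extractSurface(p0$b)
  g <- buildGrid(list(sa, sb), spacing = 0.5)
  expect_identical(jaccardIndex(sa, sb, g), 1)

  # noise flips only 6-neighbourhood boundary voxels, reproducibly
  p1 <- makePair(shapeSpec("sphere", radii = 8), c(23, 23, 23),
                 flipRate = 0.2, seed = 11)
  p2 <- makePair(shapeSpec("sphere", radii = 8), c(23, 23, 23),
                 flipRate = 0.2, seed = 11)
  expect_identical(voxels(p1$b), voxels(p2$b))
  changed <- which(voxels(p1$b) != voxels(p0$b))
  expect_gt(length(changed), 0)
  bnd <- MeshOverlap:::.boundaryVoxels(voxels(p0$b))
  expect_true(all(changed %in% bnd))

  # a known translation is returned as ground truth
  tr <- rigidFromAxisAngle(c(0, 0, 1), 0, c(2, 0, 0))
  p3 <- makePair(shapeSpec("sphere", radii = 8), c(27, 27, 27),
                 perturbation = tr)
  expect_identical(transformMatrix(p3$truth), transformMatrix(tr))
  # translated rasterization = shifted voxel pattern for integer shifts
  expect_identical(sum(voxels(p3$b)), sum(voxels(p3$a)))
  expect_error(makePair(shapeSpec("sphere", radii = 8), c(23, 23, 23),
                        flipRate = 0.7), "flipRate")
})

test_that("simulated observation tables reproduce the injected mixed model", {
  # all coefficients and sds zero -> constant intercept
  t0 <- simulateObservations(designSpec(nPerGroup = 2,
                                        effects = list(intercept = 3)))
  expect_true(all(t0$response == 3))
  expect_equal(nrow(t0), 8 * 3 * 2 * 2 * 3)

  # deterministic cell means differ by exactly the injected coefficients
  eff <- list(intercept = 1, region = c(Posterior = -0.4),
              "group:method" = c(AD.Manual = 0.25))
  t1 <- simulateObservations(designSpec(nPerGroup = 2, effects = eff))
  base <- t1$response[t1$region == "Anterior" & !(t1$group == "AD" & t1$method == "Manual")]
  expect_true(all(base == 1))
  expect_true(all(t1$response[t1$region == "Posterior" &
                              !(t1$group == "AD" & t1$method == "Manual")] == 0.6))
  expect_true(all(t1$response[t1$region == "Anterior" & t1$group == "AD" &
                              t1$method == "Manual"] == 1.25))

  # residual-only noise has unit variance within Monte-Carlo error
  v <- vapply(1:6, function(s) {
    var(simulateObservations(designSpec(nPerGroup = 5,
                                        effects = list(intercept = 0),
                                        residualSD = 1, seed = s))$response)
  }, 0)
  expect_lt(abs(mean(v) - 1), 0.25)

  # reproducible under seed; different across seeds
  a <- simulateObservations(designSpec(nPerGroup = 3, residualSD = 1, seed = 5))
  b <- simulateObservations(designSpec(nPerGroup = 3, residualSD = 1, seed = 5))
  c <- simulateObservations(designSpec(nPerGroup = 3, residualSD = 1, seed = 6))
  expect_identical(a$response, b$response)
  expect_false(identical(a$response, c$response))

  # unknown term names the valid ones
  expect_error(simulateObservations(designSpec(effects = list(intercept = 0,
                                                              cohort = c(x = 1)))),
               "valid terms")
})
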