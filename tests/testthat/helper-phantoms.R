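# Shared phantom fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# sphere r = 10 mm rasterized at 1 mm voxels
fxSphere10 <- function() fxMemo("sphere10", function() {
  extractSurface(rasterize(shapeSpec("sphere", radii = 10), c(27, 27, 27)))
})

# sphere r = 10 mm rasterized at 0.5 mm voxels (convergence studies)
fxSphere10fine <- function() fxMemo("sphere10f", function() {
  extractSurface(rasterize(shapeSpec("sphere", radii = 10), c(53, 53, 53),
                           voxelSize = 0.5))
})

# asymmetric elongated bent-tube phantom (tube r 4, arc r 15, 60 deg)
fxBentTube <- function() fxMemo("bentTube", function() {
  extractSurface(rasterize(shapeSpec("bent_tube", radii = c(4, 15, 4),
                                     bendAngle = 60),
                           dims = c(47, 31, 17)))
})

# axis-aligned closed box surface (12 triangles, outward-oriented)
boxSurface <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  tr <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
              c(1, 2, 5), c(2, 6, 5), c(2, 4, 6), c(4, 8, 6),
              c(4, 3, 8), c(3, 7, 8), c(3, 1, 7), c(1, 5, 7))
  TriSurface(v, tr)
}

# effects list of the reference "true" volume model (group, method,
# hemisphere, timepoint, region mains + group:region + method:region),
# every non-reference coefficient at least 3x the residual sd of 0.05
trueVolumeEffects <- function() list(
  intercept = 1.2,
  group = c(CTRL = 0.3, MCIN = 0.2, MCIP = 0.15),
  method = c(FreeSurfer = 0.15, Manual = -0.15),
  hemisphere = c(Right = 0.15),
  timepoint = c(M12 = -0.15),
  region = c(Middle = 0.2, Posterior = -0.3),
  "group:region" = c(CTRL.Middle = 0.15, MCIN.Middle = -0.15,
                     MCIP.Middle = 0.2, CTRL.Posterior = 0.2,
                     MCIN.Posterior = -0.2, MCIP.Posterior = 0.15),
  "method:region" = c(FreeSurfer.Middle = 0.15, Manual.Middle = -0.2,
                      FreeSurfer.Posterior = 0.2, Manual.Posterior = 0.15))

trueVolumeTerms <- function() c("method", "group", "hemisphere", "region",
                          "timepoint", "group:region", "method:region")
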