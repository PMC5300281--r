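## Synthetic phantoms: analytic shapes with known volumes, perturbed
## back-to-back pairs, and factorial observation tables drawn from a known
## mixed model. These define the ground truth against which every downstream
## stage is tested.

#' Analytic shape specification for phantom rasterization
#'
#' Three shape families are supported. `sphere` and `ellipsoid` have
#' closed-form volumes; `bent_tube` is a sphere swept along a circular arc
#' (tube radius `radii[1]`, arc radius `radii[2]`, arc angle `bendAngle`
#' degrees), giving an elongated, curved shape with a well-defined long axis
#' and no rotational symmetry about it.
#'
#' @slot kind one of `"sphere"`, `"ellipsoid"`, `"bent_tube"`.
#' @slot center world-mm centre.
#' @slot radii mm triple; sphere uses the first entry only, bent_tube uses
#'   `(tube radius, arc radius, unused)`.
#' @slot bendAngle arc angle in degrees (bent_tube only), in \[0, 90\].
#' @slot label positive integer label written into rasterized volumes.
#' @export
setClass("ShapeSpec",
  representation(kind = "character", center = "numeric", radii = "numeric",
                 bendAngle = "numeric", label = "integer"))

setValidity("ShapeSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("sphere", "ellipsoid", "bent_tube"))
    msg <- c(msg, "kind must be sphere, ellipsoid or bent_tube")
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (length(object@radii) != 3L || any(object@radii <= 0))
    msg <- c(msg, "radii must be a positive mm triple")
  if (object@bendAngle < 0 || object@bendAngle > 90)
    msg <- c(msg, "bendAngle must lie in [0, 90] degrees")
  if (object@label < 1L) msg <- c(msg, "label must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a ShapeSpec
#'
#' @param kind `"sphere"`, `"ellipsoid"` or `"bent_tube"`.
#' @param center world-mm centre (default origin).
#' @param radii mm triple (a scalar is recycled).
#' @param bendAngle arc angle in degrees (bent_tube only).
#' @param label integer label (default 1).
#' @return A [ShapeSpec-class].
#' @examples
#' shapeSpec("sphere", radii = 10)
#' shapeSpec("bent_tube", radii = c(4, 15, 0), bendAngle = 60)
#' @export
shapeSpec <- function(kind, center = c(0, 0, 0), radii = c(1, 1, 1),
                      bendAngle = 0, label = 1L) {
  radii <- rep_len(as.numeric(radii), 3L)
  new("ShapeSpec", kind = kind, center = as.numeric(center), radii = radii,
      bendAngle = as.numeric(bendAngle), label = as.integer(label))
}

setMethod("show", "ShapeSpec", function(object) {
  cat("ShapeSpec:", object@kind, "at (",
      paste(signif(object@center, 4), collapse = ", "),
      "), radii (", paste(signif(object@radii, 4), collapse = ", "), ")")
  if (object@kind == "bent_tube") cat(", bend", object@bendAngle, "deg")
  cat(", label", object@label, "\n")
})

#' Analytic inside test for a shape
#'
#' @param shape a [ShapeSpec-class].
#' @param points N x 3 matrix of world coordinates (mm).
#' @return logical vector: point strictly inside the shape.
#' @export
insideShape <- function(shape, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  p <- sweep(points, 2, shape@center)
  switch(shape@kind,
    sphere = rowSums(p^2) < shape@radii[1]^2,
    ellipsoid = rowSums(sweep(p, 2, shape@radii, "/")^2) < 1,
    bent_tube = {
      ## arc of radius radii[2] in the x-y plane, spanning
      ## [-bendAngle/2, +bendAngle/2] around the +x direction
      half <- shape@bendAngle / 2 * pi / 180
      phi <- pmin(pmax(atan2(p[, 2], p[, 1]), -half), half)
      ax <- shape@radii[2] * cos(phi)
      ay <- shape@radii[2] * sin(phi)
      (p[, 1] - ax)^2 + (p[, 2] - ay)^2 + p[, 3]^2 < shape@radii[1]^2
    })
}

## analytic axis-aligned bounding box of a shape (world mm)
.shapeBBox <- function(shape) {
  ext <- switch(shape@kind,
    sphere = rep(shape@radii[1], 3),
    ellipsoid = shape@radii,
    bent_tube = {
      half <- shape@bendAngle / 2 * pi / 180
      rc <- shape@radii[2]; rt <- shape@radii[1]
      ## arc spans x in [rc*cos(half), rc], y in [-rc*sin(half), rc*sin(half)]
      ## bbox relative to center is asymmetric in x; return symmetric cover
      c(rc + rt, rc * sin(half) + rt, rt)
    })
  rbind(shape@center - ext, shape@center + ext)
}

#' Rasterize an analytic shape onto a voxel grid
#'
#' A voxel receives the shape's label iff its world-space centre lies strictly
#' inside the analytic shape (binary label maps, no partial volume). The
#' returned affine maps 0-based voxel indices to world mm; the grid is centred
#' on the shape centre.
#'
#' @param shape a [ShapeSpec-class].
#' @param dims integer voxel dimensions triple.
#' @param voxelSize mm triple (a scalar is recycled).
#' @param rotation optional rotation of the shape about its centre before
#'   rasterization (a [RigidTransform-class] or 3x3 rotation matrix); real
#'   anatomy is oblique to the scanner axes, and an oblique phantom avoids
#'   the projection-value ties an axis-aligned shape produces.
#' @return A [LabelVolume-class].
#' @examples
#' v <- rasterize(shapeSpec("sphere", radii = 5), dims = c(16, 16, 16))
#' sum(voxels(v) == 1L)
#' @export
rasterize <- function(shape, dims, voxelSize = c(1, 1, 1), rotation = NULL) {
  stopifnot(is(shape, "ShapeSpec"))
  dims <- as.integer(rep_len(dims, 3L))
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  R <- NULL
  if (!is.null(rotation)) {
    R <- if (is(rotation, "RigidTransform")) transformMatrix(rotation)[1:3, 1:3]
      else as.matrix(rotation)
    stopifnot(all(dim(R) == c(3, 3)), max(abs(crossprod(R) - diag(3))) < 1e-6)
  }
  ## grid centred on the shape centre
  origin <- shape@center - (dims - 1) / 2 * voxelSize
  affine <- diag(c(voxelSize, 1))
  affine[1:3, 4] <- origin
  bb <- .shapeBBox(shape)
  if (!is.null(R)) {
    if (shape@kind %in% c("sphere", "ellipsoid")) {
      ## exact support function of a rotated ellipsoid
      rr <- if (shape@kind == "sphere") rep(shape@radii[1], 3) else shape@radii
      ext <- sqrt(rowSums(sweep(R, 2, rr, "*")^2))
      bb <- rbind(shape@center - ext, shape@center + ext)
    } else {
      ## conservative: rotated corners of the raw bounding box
      corn <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
      corn <- sweep(sweep(corn, 2, shape@center) %*% t(R), 2, shape@center, "+")
      bb <- rbind(apply(corn, 2, min), apply(corn, 2, max))
    }
  }
  lo <- origin - voxelSize / 2
  hi <- origin + (dims - 0.5) * voxelSize
  margin <- 2 * voxelSize
  bad <- which(bb[1, ] < lo + margin | bb[2, ] > hi - margin)
  if (length(bad))
    stop("shape exceeds grid bounds (with 2-voxel margin) along axis ",
         paste(c("x", "y", "z")[bad], collapse = ", "))
  ctr <- as.matrix(expand.grid(x = origin[1] + (seq_len(dims[1]) - 1) * voxelSize[1],
                               y = origin[2] + (seq_len(dims[2]) - 1) * voxelSize[2],
                               z = origin[3] + (seq_len(dims[3]) - 1) * voxelSize[3]))
  if (!is.null(R))   # a centre is inside the rotated shape iff its back-
    ctr <- sweep(sweep(ctr, 2, shape@center) %*% R, 2, shape@center, "+")
  inside <- insideShape(shape, ctr)
  vox <- array(0L, dims)
  vox[inside] <- shape@label
  LabelVolume(vox, affine)
}

#' Generate a back-to-back phantom pair with known ground-truth transform
#'
#' Emulates two same-session acquisitions of one structure: the second volume
#' is the analytic shape moved by a known small rigid transform, re-rasterized
#' on the same grid, with optional boundary noise (voxels having at least one
#' opposite-valued 6-neighbour are flipped independently at `flipRate`).
#'
#' @param shape a [ShapeSpec-class].
#' @param dims,voxelSize passed to [rasterize()].
#' @param perturbation a [RigidTransform-class] mapping volume-1 space to
#'   volume-2 space (default identity).
#' @param flipRate boundary voxel flip probability in \[0, 0.5).
#' @param seed integer seed for the boundary noise.
#' @return list with elements `a`, `b` ([LabelVolume-class]) and `truth`
#'   (the [RigidTransform-class] used).
#' @export
makePair <- function(shape, dims, voxelSize = c(1, 1, 1),
                     perturbation = rigidTransform(diag(4)),
                     flipRate = 0, seed = 1L) {
  stopifnot(is(perturbation, "RigidTransform"))
  if (flipRate < 0 || flipRate >= 0.5)
    stop("flipRate must lie in [0, 0.5)")
  a <- rasterize(shape, dims, voxelSize)
  ## voxel centre c is inside the moved shape iff T^{-1} c is inside the shape
  dims <- dim(a@voxels)
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  world <- applyTransform(a@affine, idx)
  backMapped <- applyTransform(solve(transformMatrix(perturbation)), world)
  vox <- array(0L, dims)
  vox[insideShape(shape, backMapped)] <- shape@label
  if (flipRate > 0) {
    bnd <- .boundaryVoxels(vox)
    rng <- .seededRNG(seed)
    flip <- bnd[rng(length(bnd)) < flipRate]
    vox[flip] <- ifelse(vox[flip] == 0L, shape@label, 0L)
  }
  list(a = a, b = LabelVolume(vox, a@affine), truth = perturbation)
}

## linear indices of voxels with >= 1 opposite-valued 6-neighbour
.boundaryVoxels <- function(vox) {
  d <- dim(vox)
  b <- vox != 0L
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- b
  shift <- function(di, dj, dk)
    pad[2:(d[1] + 1) + di, 2:(d[2] + 1) + dj, 2:(d[3] + 1) + dk]
  diff6 <- (b != shift(1, 0, 0)) | (b != shift(-1, 0, 0)) |
           (b != shift(0, 1, 0)) | (b != shift(0, -1, 0)) |
           (b != shift(0, 0, 1)) | (b != shift(0, 0, -1))
  which(diff6)
}

## isolated uniform RNG stream (does not disturb the global .Random.seed)
.seededRNG <- function(seed) {
  state <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  state$s <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", state$s, globalenv())
    u <- runif(n)
    state$s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    u
  }
}

## ---------------------------------------------------------------------------
## Factorial observation tables
## ---------------------------------------------------------------------------

.defaultLevels <- list(
  group = c("CTRL", "MCIN", "MCIP", "AD"),
  method = c("Manual", "FIRST", "FreeSurfer"),
  hemisphere = c("Left", "Right"),
  timepoint = c("BL", "M12"),
  region = c("Anterior", "Middle", "Posterior"))

.factorNames <- names(.defaultLevels)

#' Design specification for simulated observation tables
#'
#' Defines a balanced factorial design: `nPerGroup` subjects in each group
#' level, fully crossed with method, hemisphere, timepoint and region.
#' Responses are drawn from a Gaussian linear mixed model with the stated
#' fixed effects, a per-subject random intercept, and i.i.d. residual noise.
#'
#' Fixed effects are supplied as a named list. `intercept` is a scalar; every
#' other element is named by a term (e.g. `"group"`, `"group:region"`, factors
#' in the order group, method, hemisphere, timepoint, region) and contains a
#' named numeric vector of per-level (or per-level-combination, names joined
#' with `"."`) additive contributions. Levels not named contribute 0, so
#' leaving the alphabetically first level out reproduces treatment coding.
#'
#' @slot nPerGroup subjects per group level.
#' @slot levels named list of factor levels.
#' @slot effects named list of true fixed-effect contributions.
#' @slot subjectSD standard deviation of the subject random intercept.
#' @slot residualSD residual standard deviation.
#' @slot seed integer RNG seed.
#' @export
setClass("DesignSpec",
  representation(nPerGroup = "integer", levels = "list", effects = "list",
                 subjectSD = "numeric", residualSD = "numeric",
                 seed = "integer"))

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (!identical(names(object@levels), .factorNames))
    msg <- c(msg, paste("levels must be named:",
                        paste(.factorNames, collapse = ", ")))
  if (object@subjectSD < 0 || object@residualSD < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DesignSpec
#'
#' Defaults mirror the study design the package's statistics are aimed at:
#' 20 subjects in each of four diagnostic groups, three segmentation methods,
#' two hemispheres, two timepoints and three regions.
#'
#' @param nPerGroup subjects per group (default 20).
#' @param levels named list of factor levels (default: the standard design).
#' @param effects named list of true effects (see [DesignSpec-class]).
#' @param subjectSD,residualSD standard deviations (cm^3 scale by default).
#' @param seed integer seed.
#' @return A [DesignSpec-class].
#' @examples
#' ds <- designSpec(effects = list(intercept = 1.2,
#'                                 group = c(AD = -0.2)),
#'                  residualSD = 0.05, seed = 7)
#' head(simulateObservations(ds))
#' @export
designSpec <- function(nPerGroup = 20L, levels = .defaultLevels,
                       effects = list(intercept = 0), subjectSD = 0,
                       residualSD = 0, seed = 1L) {
  new("DesignSpec", nPerGroup = as.integer(nPerGroup), levels = levels,
      effects = effects, subjectSD = subjectSD, residualSD = residualSD,
      seed = as.integer(seed))
}

## canonical term name: factors sorted in design order, joined by ":"
.canonicalTerm <- function(term, levels) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (!all(parts %in% names(levels))) return(NA_character_)
  paste(parts[order(match(parts, names(levels)))], collapse = ":")
}

#' Simulate a factorial observation table from a known mixed model
#'
#' One record per subject x method x hemisphere x timepoint x region cell.
#' The response is the intercept plus the specified fixed-effect
#' contributions plus a subject random intercept plus Gaussian residual
#' noise, reproducible under the design's seed.
#'
#' @param design a [DesignSpec-class].
#' @return `data.frame` with columns `subject`, `group`, `method`,
#'   `hemisphere`, `timepoint`, `region`, `response`; factor levels sorted
#'   alphabetically (the reference-level convention of the model module).
#' @export
simulateObservations <- function(design) {
  stopifnot(is(design, "DesignSpec"))
  lv <- design@levels
  nsub <- design@nPerGroup * length(lv$group)
  subjects <- sprintf("S%03d", seq_len(nsub))
  subjGroup <- rep(lv$group, each = design@nPerGroup)
  tab <- expand.grid(subject = subjects, method = lv$method,
                     hemisphere = lv$hemisphere, timepoint = lv$timepoint,
                     region = lv$region, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  tab$group <- subjGroup[match(tab$subject, subjects)]
  tab <- tab[c("subject", "group", "method", "hemisphere", "timepoint",
               "region")]

  eff <- design@effects
  mu <- rep(0, nrow(tab))
  for (nm in names(eff)) {
    if (nm == "intercept") { mu <- mu + eff[[nm]]; next }
    canon <- .canonicalTerm(nm, lv)
    if (is.na(canon))
      stop("unknown effect term '", nm, "'; valid terms are 'intercept' and ",
           "colon-joined combinations of: ", paste(names(lv), collapse = ", "))
    parts <- strsplit(canon, ":", fixed = TRUE)[[1]]
    key <- do.call(paste, c(tab[parts], sep = "."))
    contrib <- eff[[nm]][key]
    contrib[is.na(contrib)] <- 0
    mu <- mu + as.numeric(contrib)
  }

  rng <- .seededEnv(design@seed)
  subjInt <- rng$rnorm(nsub, 0, design@subjectSD)
  resid <- rng$rnorm(nrow(tab), 0, design@residualSD)
  tab$response <- mu + subjInt[match(tab$subject, subjects)] + resid
  for (f in .factorNames) tab[[f]] <- factor(tab[[f]], levels = sort(lv[[f]]))
  tab$subject <- factor(tab$subject)
  tab
}

## seeded normal draws isolated from the global RNG
.seededEnv <- function(seed) {
  state <- new.env()
  withCallingHandlers({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(as.integer(seed))
    state$s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, warning = function(w) invokeRestart("muffleWarning"))
  list(rnorm = function(n, mean = 0, sd = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", state$s, globalenv())
    x <- rnorm(n, mean, sd)
    state$s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  })
}
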