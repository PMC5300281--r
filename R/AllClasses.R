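#' @import methods
#' @importFrom stats prcomp quantile rnorm runif sd setNames anova AIC logLik
#'   as.formula model.matrix predict pchisq var terms
#' @importFrom utils read.csv write.csv head tail
#' @exportMethod show
NULL

## ---------------------------------------------------------------------------
## LabelVolume
## ---------------------------------------------------------------------------

#' Labelled 3D volume with a voxel-to-world affine
#'
#' A `LabelVolume` holds an integer 3D label map together with the 4x4 affine
#' matrix mapping 0-based voxel indices to world coordinates in millimetres,
#' exactly as stored in a NIfTI header. It is the raw form in which
#' segmentations enter the pipeline.
#'
#' @slot voxels integer 3D array of labels (0 = background).
#' @slot affine 4x4 numeric matrix; `world = affine %*% c(i, j, k, 1)` with
#'   0-based indices `i, j, k`.
#'
#' @export
setClass("LabelVolume",
  representation(voxels = "array", affine = "matrix"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (any(dim(object@voxels) < 1L))
    msg <- c(msg, "all array dimensions must be >= 1")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels integer 3D array.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix. Defaults to
#'   identity (1 mm isotropic voxels at the origin).
#' @return A [LabelVolume-class] object.
#' @examples
#' v <- LabelVolume(array(0L, c(4, 4, 4)))
#' dim(voxels(v))
#' @export
LabelVolume <- function(voxels, affine = diag(4)) {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, affine = affine)
}

#' @describeIn LabelVolume-class the label array.
#' @param x a `LabelVolume`.
#' @export
voxels <- function(x) x@voxels

#' @describeIn LabelVolume-class the 4x4 voxel-to-world affine.
#' @export
volAffine <- function(x) x@affine

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  labs <- sort(unique(as.vector(object@voxels)))
  labs <- labs[labs != 0L]
  cat("LabelVolume", paste(d, collapse = " x "),
      "voxels;", length(labs), "label(s)")
  if (length(labs) && length(labs) <= 8) cat(":", paste(labs, collapse = ", "))
  cat("\n  voxel size (mm):",
      paste(signif(sqrt(colSums(object@affine[1:3, 1:3]^2)), 4), collapse = " x "),
      "\n")
})

## ---------------------------------------------------------------------------
## TriSurface
## ---------------------------------------------------------------------------

#' Closed triangulated surface in world millimetres
#'
#' Vertices and triangles of a (possibly multi-component) closed, oriented
#' mesh. Triangle winding is counter-clockwise seen from outside the enclosed
#' volume, so the signed divergence-theorem volume of an outer component is
#' positive and a nested cavity component contributes negatively.
#'
#' @slot vertices N x 3 numeric matrix of world coordinates (mm).
#' @slot triangles M x 3 integer matrix of 1-based vertex indices.
#' @slot components integer vector of length M assigning each triangle to a
#'   connected component (1-based).
#'
#' @export
setClass("TriSurface",
  representation(vertices = "matrix", triangles = "matrix",
                 components = "integer"))

setValidity("TriSurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be N x 3")
  if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be M x 3")
  if (nrow(object@triangles) > 0) {
    if (min(object@triangles) < 1L || max(object@triangles) > nrow(object@vertices))
      msg <- c(msg, "triangle vertex indices out of range")
    if (length(object@components) != nrow(object@triangles))
      msg <- c(msg, "components must have one entry per triangle")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TriSurface
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param triangles M x 3 integer matrix of 1-based vertex indices.
#' @param components optional integer component id per triangle; computed
#'   from vertex connectivity when omitted.
#' @return A [TriSurface-class] object.
#' @export
TriSurface <- function(vertices, triangles, components = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (is.null(components))
    components <- .triangleComponents(vertices, triangles)
  new("TriSurface", vertices = vertices, triangles = triangles,
      components = as.integer(components))
}

#' @describeIn TriSurface-class vertex coordinate matrix.
#' @param x a `TriSurface`.
#' @export
vertices <- function(x) x@vertices

#' @describeIn TriSurface-class triangle index matrix.
#' @export
triangles <- function(x) x@triangles

#' @describeIn TriSurface-class number of connected components.
#' @export
nComponents <- function(x) {
  if (length(x@components) == 0L) 0L else max(x@components)
}

setMethod("show", "TriSurface", function(object) {
  cat("TriSurface:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles,",
      nComponents(object), "component(s)\n")
  if (nrow(object@vertices)) {
    bb <- apply(object@vertices, 2, range)
    cat("  bbox (mm): [", paste(signif(bb[1, ], 4), collapse = ", "), "] - [",
        paste(signif(bb[2, ], 4), collapse = ", "), "]\n")
  }
})

## connected components of triangles through shared vertices
.triangleComponents <- function(vertices, triangles) {
  if (nrow(triangles) == 0L) return(integer())
  ed <- rbind(triangles[, c(1, 2), drop = FALSE],
              triangles[, c(2, 3), drop = FALSE],
              triangles[, c(3, 1), drop = FALSE])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(vertices) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comp <- memb[triangles[, 1]]
  as.integer(match(comp, sort(unique(comp))))
}

## ---------------------------------------------------------------------------
## SampleGrid / Occupancy
## ---------------------------------------------------------------------------

#' Regular sampling lattice used to count points inside surfaces
#'
#' Axis-aligned, isotropic lattice of world-space points. Counting lattice
#' points inside a surface approximates its volume; shared lattices make
#' Jaccard ratios well defined.
#'
#' @slot origin world coordinate (mm) of the first lattice point.
#' @slot spacing isotropic lattice spacing (mm).
#' @slot dims integer triple of lattice dimensions.
#' @export
setClass("SampleGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer"))

setValidity("SampleGrid", function(object) {
  msg <- character()
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be a positive integer triple")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SampleGrid", function(object) {
  cat("SampleGrid:", paste(object@dims, collapse = " x "), "points,",
      "spacing", object@spacing, "mm, origin (",
      paste(signif(object@origin, 5), collapse = ", "), ")\n")
})

#' @describeIn SampleGrid-class lattice spacing in mm.
#' @param x a `SampleGrid`.
#' @export
gridSpacing <- function(x) x@spacing

#' @describeIn SampleGrid-class lattice dimensions.
#' @export
gridDims <- function(x) x@dims

#' @describeIn SampleGrid-class total number of lattice points.
#' @export
gridSize <- function(x) prod(as.numeric(x@dims))

#' Inside/outside flags of a sampling lattice for one surface
#'
#' @slot grid the [SampleGrid-class] the flags refer to.
#' @slot flags logical array (grid dims); `TRUE` = point inside the surface.
#' @export
setClass("Occupancy",
  representation(grid = "SampleGrid", flags = "array"))

setMethod("show", "Occupancy", function(object) {
  cat("Occupancy:", sum(object@flags), "of", gridSize(object@grid),
      "points inside (spacing", object@grid@spacing, "mm)\n")
})

## ---------------------------------------------------------------------------
## RigidTransform
## ---------------------------------------------------------------------------

#' Rigid-body transform as a 4x4 homogeneous matrix
#'
#' The rotation block must be orthonormal with determinant +1 (within 1e-6)
#' and the last row (0, 0, 0, 1).
#'
#' @slot matrix 4x4 homogeneous transform matrix (translation in mm).
#' @export
setClass("RigidTransform", representation(matrix = "matrix"))

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  if (!all(dim(m) == c(4L, 4L))) return("matrix must be 4x4")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-6)
    return("last row must be (0, 0, 0, 1)")
  r <- m[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > 1e-6)
    return("rotation block is not orthonormal (R'R != I within 1e-6)")
  if (abs(det(r) - 1) > 1e-6)
    return("rotation block must have determinant +1")
  TRUE
})

#' Construct a RigidTransform from a 4x4 matrix
#'
#' @param matrix 4x4 homogeneous matrix with orthonormal rotation block.
#' @return A [RigidTransform-class] object.
#' @examples
#' rigidTransform(diag(4))
#' @export
rigidTransform <- function(matrix) new("RigidTransform", matrix = matrix)

#' @describeIn RigidTransform-class the 4x4 matrix.
#' @param x a `RigidTransform`.
#' @export
transformMatrix <- function(x) {
  if (is(x, "RigidTransform")) x@matrix else x
}

#' @describeIn RigidTransform-class the translation component (mm triple).
#' @export
translationVector <- function(x) transformMatrix(x)[1:3, 4]

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: rotation", signif(rotationTotal(object), 6),
      "deg, translation", signif(translationTotal(object), 6), "mm\n")
})

## ---------------------------------------------------------------------------
## RegionSet
## ---------------------------------------------------------------------------

#' Anterior/middle/posterior partition of a mask along its long axis
#'
#' Holds the three region surfaces in order along the long axis, the axis
#' itself, the two cut positions (projections onto the axis, relative to
#' `axisOrigin`), and the partitioned label volume it was derived from.
#'
#' @slot surfaces list of three [TriSurface-class]: anterior, middle, posterior.
#' @slot axis unit vector (world mm) of the long axis, pointing anterior.
#' @slot axisOrigin centroid (world mm) used as projection origin.
#' @slot cuts two increasing scalars: cut positions along the axis.
#' @slot labels region label volume (1 = anterior, 2 = middle, 3 = posterior).
#' @slot provenance free-text provenance (template id, transform id).
#' @export
setClass("RegionSet",
  representation(surfaces = "list", axis = "numeric", axisOrigin = "numeric",
                 cuts = "numeric", labels = "LabelVolume",
                 provenance = "character"))

setValidity("RegionSet", function(object) {
  msg <- character()
  if (length(object@surfaces) != 3L ||
      !all(vapply(object@surfaces, is, TRUE, "TriSurface")))
    msg <- c(msg, "surfaces must be a list of three TriSurface objects")
  if (length(object@axis) != 3L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "axis must be a unit 3-vector")
  if (length(object@cuts) != 2L || diff(object@cuts) < 0)
    msg <- c(msg, "cuts must be two increasing scalars")
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionSet-class named list of the three region surfaces.
#' @param x a `RegionSet`.
#' @export
regionSurfaces <- function(x) {
  setNames(x@surfaces, c("anterior", "middle", "posterior"))
}

#' @describeIn RegionSet-class the long-axis unit vector.
#' @export
regionAxis <- function(x) x@axis

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet: anterior/middle/posterior along axis (",
      paste(signif(object@axis, 4), collapse = ", "),
      "), cuts at", paste(signif(object@cuts, 5), collapse = " and "),
      "mm\n  provenance:", object@provenance, "\n")
})

## ---------------------------------------------------------------------------
## CircleReport
## ---------------------------------------------------------------------------

#' Full-circle registration consistency report
#'
#' Summaries of the residual matrix of a closed registration cycle: the
#' translation norm, the rotation angle extracted from the trace of the
#' rotation block, and (optionally) the Jaccard consistency of a reference
#' surface with its residual-transformed copy.
#'
#' @slot residual the residual [RigidTransform-class] of the cycle.
#' @slot translationTotal residual translation norm (mm).
#' @slot rotationTotal residual rotation angle (degrees, in \[0, 180\]).
#' @slot consistency Jaccard between surface and transformed surface
#'   (`NA` when no surface was supplied).
#' @slot registrationError `1 - consistency`.
#' @slot circleId identifier of the cycle.
#' @export
setClass("CircleReport",
  representation(residual = "RigidTransform", translationTotal = "numeric",
                 rotationTotal = "numeric", consistency = "numeric",
                 registrationError = "numeric", circleId = "character"))

setMethod("show", "CircleReport", function(object) {
  cat("CircleReport", object@circleId, "\n",
      " translation_total:", signif(object@translationTotal, 6), "mm\n",
      " rotation_total:   ", signif(object@rotationTotal, 6), "deg\n")
  if (!is.na(object@consistency))
    cat("  consistency:      ", signif(object@consistency, 6),
        "(error", signif(object@registrationError, 6), ")\n")
})

#' Convert a CircleReport to a one-row data frame
#'
#' @param x a [CircleReport-class].
#' @param ... unused.
#' @return a one-row `data.frame` with the QC quantities.
#' @export
setMethod("as.data.frame", "CircleReport", function(x, ...) {
  data.frame(circle_id = x@circleId,
             translation_total_mm = x@translationTotal,
             rotation_total_deg = x@rotationTotal,
             consistency = x@consistency,
             registration_error = x@registrationError,
             stringsAsFactors = FALSE)
})
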