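## Long-axis partition of a mask into anterior / middle / posterior regions.
## The long axis is the first principal axis of the world coordinates of the
## mask voxels; cut planes perpendicular to it are placed at volume
## quantiles, so the requested volume fractions are met by construction (up
## to one voxel layer of discretization). Region meshes are built by masking
## voxels before meshing, which keeps them watertight and keeps region
## occupancies an exact partition on any grid.

#' Split a mask into three regions along its long axis
#'
#' The axis is the first principal component of the voxel world coordinates.
#' Cut planes perpendicular to the axis are placed between voxel projection
#' values so that the cumulative volume fractions match `fractions`
#' (anterior, middle, posterior) as closely as possible; the anterior region
#' occupies the high end of the axis. Each sub-mask is converted to a
#' watertight surface with [extractSurface()].
#'
#' @param mask a non-empty [LabelVolume-class] (all non-zero voxels are mask).
#' @param fractions positive triple `(anterior, middle, posterior)` summing
#'   to 1 (default `c(0.35, 0.45, 0.20)`).
#' @param provenance free-text provenance tag.
#' @return A [RegionSet-class].
#' @examples
#' mask <- rasterize(shapeSpec("ellipsoid", radii = c(20, 8, 8)), c(47, 23, 23))
#' rs <- splitLongAxis(mask)
#' regionAxis(rs)
#' @export
splitLongAxis <- function(mask, fractions = c(0.35, 0.45, 0.20),
                          provenance = "mask") {
  stopifnot(is(mask, "LabelVolume"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive numbers summing to 1")
  sel <- which(mask@voxels != 0L)
  if (length(sel) < 10L)
    stop("mask has fewer than 10 voxels; long axis undefined")
  idx <- arrayInd(sel, dim(mask@voxels)) - 1L
  world <- applyTransform(mask@affine, idx)
  pc <- prcomp(world, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] / pc$sdev[2] < 1.2)
    warning("mask is nearly isotropic (axis variance ratio < 1.2); ",
            "long axis chosen by fixed eigenvector ordering")
  axis <- pc$rotation[, 1]
  ## deterministic sign: largest-magnitude entry positive
  axis <- axis * sign(axis[which.max(abs(axis))])
  centroid <- colMeans(world)
  proj <- drop(sweep(world, 2, centroid) %*% axis)

  ## volume-quantile cuts between distinct projection values; cumulative
  ## fractions from the posterior (low) end are (posterior, posterior+middle)
  uq <- sort(unique(proj))
  csum <- cumsum(tabulate(match(proj, uq), length(uq))) / length(proj)
  pickCut <- function(target) {
    i <- which.min(abs(csum[-length(csum)] - target))
    (uq[i] + uq[i + 1]) / 2
  }
  c1 <- pickCut(fractions[3])                    # posterior | middle
  c2 <- pickCut(fractions[3] + fractions[2])     # middle | anterior
  regionOf <- 1L + (proj > c1) + (proj > c2)     # 1 post, 2 mid, 3 ant

  lab <- array(0L, dim(mask@voxels))
  lab[sel] <- c(3L, 2L, 1L)[regionOf]            # 1 ant, 2 mid, 3 post
  labels <- LabelVolume(lab, mask@affine)
  surfaces <- lapply(1:3, function(l) extractSurface(labels, l))
  new("RegionSet", surfaces = surfaces, axis = axis, axisOrigin = centroid,
      cuts = c(c1, c2), labels = labels, provenance = provenance)
}

#' Fix the anterior direction of a region set
#'
#' Phantoms (and template masks) carry no anatomy, so the anterior direction
#' is a convention: given a rough anterior-pointing hint, the axis is flipped
#' if needed so that it points anterior (positive dot product with the
#' hint), and the anterior/posterior labels are swapped accordingly.
#' Idempotent.
#'
#' @param regions a [RegionSet-class].
#' @param anteriorHint world-mm direction roughly pointing anterior; must
#'   not be nearly perpendicular to the axis (|cosine| > 0.1).
#' @return the (possibly relabelled) [RegionSet-class].
#' @export
orientAxis <- function(regions, anteriorHint) {
  stopifnot(is(regions, "RegionSet"))
  hint <- as.numeric(anteriorHint)
  hint <- hint / sqrt(sum(hint^2))
  d <- sum(regions@axis * hint)
  if (abs(d) <= 0.1)
    stop("anterior hint is nearly perpendicular to the long axis ",
         "(|cosine| = ", signif(abs(d), 3), "); supply a better hint")
  if (d >= 0) return(regions)
  lab <- regions@labels
  vox <- lab@voxels
  swapped <- vox
  swapped[vox == 1L] <- 3L
  swapped[vox == 3L] <- 1L
  new("RegionSet",
      surfaces = regions@surfaces[c(3, 2, 1)],
      axis = -regions@axis, axisOrigin = regions@axisOrigin,
      cuts = sort(-regions@cuts),
      labels = LabelVolume(swapped, lab@affine),
      provenance = regions@provenance)
}

#' Map a region set into subject space
#'
#' Applies an (affine, not necessarily rigid) template-to-subject transform
#' to the region surfaces, axis and cuts. Disjointness and anterior/middle/
#' posterior ordering are preserved.
#'
#' @param regions a [RegionSet-class].
#' @param templateToSubject invertible 4x4 matrix (e.g. from
#'   [readFlirtMatrix()]) or [RigidTransform-class].
#' @return the transformed [RegionSet-class].
#' @export
mapToSubject <- function(regions, templateToSubject) {
  stopifnot(is(regions, "RegionSet"))
  m <- transformMatrix(templateToSubject)
  if (!all(dim(m) == c(4, 4)) || abs(det(m)) < 1e-12)
    stop("templateToSubject must be an invertible 4x4 matrix")
  surfaces <- lapply(regions@surfaces, transformSurface, t = m)
  ctr <- drop(applyTransform(m, matrix(regions@axisOrigin, 1)))
  ax <- drop(m[1:3, 1:3] %*% regions@axis)
  ax <- ax / sqrt(sum(ax^2))
  cutPts <- applyTransform(m, matrix(regions@axisOrigin, 2, 3, byrow = TRUE) +
                                outer(regions@cuts, regions@axis))
  cuts <- drop(sweep(cutPts, 2, ctr) %*% ax)
  if (cuts[1] > cuts[2]) {     # linear part reversed the axis: keep ordering
    ax <- -ax
    cuts <- sort(-cuts)
  }
  new("RegionSet", surfaces = surfaces, axis = ax, axisOrigin = ctr,
      cuts = cuts, labels = regions@labels,
      provenance = paste0(regions@provenance, " (mapped)"))
}

#' Mutually exclusive region occupancies on a shared grid
#'
#' Raw occupancies of adjacent voxelized region meshes can both claim a
#' lattice point that falls exactly on their shared cut wall (the on-surface
#' rule classifies it inside both). This helper resolves such ties with a
#' fixed anterior > middle > posterior priority so the three flag arrays
#' partition their union pointwise.
#'
#' @param regions a [RegionSet-class].
#' @param grid a [SampleGrid-class] enclosing all three region surfaces.
#' @return named list of three logical arrays (`anterior`, `middle`,
#'   `posterior`), pairwise disjoint.
#' @export
regionOccupancy <- function(regions, grid) {
  s <- regionSurfaces(regions)
  ant <- occupancy(s$anterior, grid)@flags
  mid <- occupancy(s$middle, grid)@flags & !ant
  post <- occupancy(s$posterior, grid)@flags & !(ant | mid)
  list(anterior = ant, middle = mid, posterior = post)
}
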