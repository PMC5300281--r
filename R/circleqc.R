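## Full-circle registration consistency QC. Multiplying all transforms
## around a closed cycle of images should give the identity; the residual
## matrix RM quantifies the accumulated registration error as a translation
## norm, a rotation angle, and (through a reference surface) a Jaccard
## consistency index whose complement is the registration error.

#' Build a rigid transform from axis-angle rotation and translation
#'
#' Rodrigues rotation about a (not necessarily unit) axis through the
#' origin, followed by a translation.
#'
#' @param axis rotation axis (3-vector, any non-zero length).
#' @param angleDeg rotation angle in degrees.
#' @param translation mm triple (default none).
#' @return A [RigidTransform-class].
#' @examples
#' rigidFromAxisAngle(c(0, 0, 1), 90, c(1, 0, 0))
#' @export
rigidFromAxisAngle <- function(axis, angleDeg, translation = c(0, 0, 0)) {
  u <- as.numeric(axis)
  n <- sqrt(sum(u^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  u <- u / n
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- as.numeric(translation)
  rigidTransform(m)
}

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class] or 4x4 matrix.
#' @return the inverse [RigidTransform-class].
#' @export
invertRigid <- function(t) {
  m <- transformMatrix(t)
  inv <- diag(4)
  inv[1:3, 1:3] <- t(m[1:3, 1:3])
  inv[1:3, 4] <- -t(m[1:3, 1:3]) %*% m[1:3, 4]
  rigidTransform(inv)
}

#' Compose a registration circle into its residual matrix
#'
#' Multiplies the transforms in the given order (first element leftmost,
#' matching the residual-matrix convention `RM = T1 x T2 x T3`). For an
#' exactly consistent closed cycle the result is the identity; deviations
#' from identity are the accumulated registration error.
#'
#' @param transforms ordered list (length >= 2) of [RigidTransform-class]
#'   objects or 4x4 rigid matrices.
#' @return the residual [RigidTransform-class].
#' @export
composeCircle <- function(transforms) {
  if (length(transforms) < 2L)
    stop("a circle needs at least 2 transforms")
  mats <- vector("list", length(transforms))
  for (i in seq_along(transforms)) {
    mats[[i]] <- tryCatch(transformMatrix(rigidTransform(transformMatrix(transforms[[i]]))),
      error = function(e)
        stop("transform ", i, " is not a valid rigid transform: ",
             conditionMessage(e)))
  }
  rm <- Reduce(`%*%`, mats)
  tryCatch(rigidTransform(rm),
    error = function(e)
      stop("composed circle drifted from rigidity: ", conditionMessage(e)))
}

#' Residual translation norm of a transform
#'
#' Euclidean norm of the translation component, in mm.
#'
#' @param rm a [RigidTransform-class] or 4x4 rigid matrix.
#' @return translation norm (mm).
#' @export
translationTotal <- function(rm) {
  sqrt(sum(transformMatrix(rm)[1:3, 4]^2))
}

#' Residual rotation angle of a transform
#'
#' The rotation angle extracted from the trace of the 3x3 rotation block:
#' `acos((trace(R) - 1) / 2)`, in degrees, with the arccos argument clamped
#' to \[-1, 1\] against floating-point drift in near-identity products.
#'
#' @param rm a [RigidTransform-class] or 4x4 rigid matrix.
#' @return rotation angle in degrees, in \[0, 180\].
#' @export
rotationTotal <- function(rm) {
  r <- transformMatrix(rm)[1:3, 1:3]
  arg <- (sum(diag(r)) - 1) / 2
  acos(pmin(1, pmax(-1, arg))) * 180 / pi
}

#' Jaccard consistency of a surface under a residual transform
#'
#' Overlap between a reference surface and its copy mapped through the
#' residual matrix, on a shared grid; 1 for a perfectly consistent circle.
#' `1 - consistency` quantifies the registration error. Note that shapes
#' with rotational symmetry (e.g. spheres rotated about their centre) are
#' blind to the corresponding rotation component.
#'
#' @param surface a watertight [TriSurface-class].
#' @param rm residual [RigidTransform-class] or 4x4 rigid matrix.
#' @param spacing grid spacing in mm (default 0.5).
#' @param margin grid margin in mm (default 2).
#' @return consistency fraction in \[0, 1\].
#' @export
consistency <- function(surface, rm, spacing = 0.5, margin = 2) {
  moved <- transformSurface(surface, rm)
  grid <- buildGrid(list(surface, moved), spacing = spacing, margin = margin)
  jaccardIndex(surface, moved, grid)
}

#' Full-circle QC report for one registration cycle
#'
#' Composes the cycle, extracts the translation and rotation residuals and,
#' when a reference surface is supplied, the Jaccard consistency.
#'
#' @param transforms ordered list of rigid transforms forming a closed cycle.
#' @param surface optional reference [TriSurface-class] for the consistency
#'   index.
#' @param spacing,margin grid parameters for [consistency()].
#' @param circleId identifier recorded in the report.
#' @return A [CircleReport-class].
#' @export
fullCircle <- function(transforms, surface = NULL, spacing = 0.5, margin = 2,
                       circleId = "circle") {
  rm <- composeCircle(transforms)
  cons <- NA_real_
  if (!is.null(surface))
    cons <- consistency(surface, rm, spacing = spacing, margin = margin)
  new("CircleReport", residual = rm,
      translationTotal = translationTotal(rm),
      rotationTotal = rotationTotal(rm),
      consistency = cons, registrationError = 1 - cons,
      circleId = circleId)
}

#' The four standard circles of a two-timepoint back-to-back session
#'
#' For a session with scans BL-A, BL-B, M12-A and M12-B, evaluates the four
#' standard registration circles. `transforms` is a named list of measured
#' rigid transforms with names `"SRC>DST"` (mapping SRC-space points into
#' DST space), e.g. `"BLB>BLA"`; when a needed direction was not measured,
#' the inverse of the opposite direction is used.
#'
#' @param transforms named list of [RigidTransform-class], names `"SRC>DST"`
#'   with scan ids among `BLA`, `BLB`, `M12A`, `M12B`.
#' @param surface optional reference surface for the consistency index.
#' @param spacing,margin grid parameters for [consistency()].
#' @return named list of four [CircleReport-class] objects.
#' @export
sessionCircles <- function(transforms, surface = NULL, spacing = 0.5,
                           margin = 2) {
  get <- function(src, dst) {
    key <- paste0(src, ">", dst); rev <- paste0(dst, ">", src)
    if (!is.null(transforms[[key]])) rigidTransform(transformMatrix(transforms[[key]]))
    else if (!is.null(transforms[[rev]])) invertRigid(transforms[[rev]])
    else stop("no transform for ", key, " (nor its inverse) supplied")
  }
  ## chain entries are (src, dst) pairs; the rightmost transform of each
  ## product is applied first, so each chain walks a closed scan cycle
  circles <- list(
    circle1 = list(c("M12B", "BLA"), c("M12A", "M12B"), c("BLA", "M12A")),
    circle2 = list(c("M12A", "BLA"), c("BLB", "M12A"), c("BLA", "BLB")),
    circle3 = list(c("M12B", "BLA"), c("BLB", "M12B"), c("BLA", "BLB")),
    circle4 = list(c("M12A", "M12B"), c("BLB", "M12A"), c("M12B", "BLB")))
  out <- lapply(names(circles), function(cid) {
    chain <- lapply(circles[[cid]], function(p) get(p[1], p[2]))
    fullCircle(chain, surface = surface, spacing = spacing, margin = margin,
               circleId = cid)
  })
  setNames(out, names(circles))
}
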