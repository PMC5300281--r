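## Case-table construction for the marching-cubes variant used by
## extractSurface(). Node values are binary (0/1) and the iso-level is 0.5,
## so every surface/edge crossing sits at an edge midpoint. For each of the
## 256 corner patterns the iso-contour is built face by face (marching
## squares with a fixed rule for the ambiguous diagonal case: positive
## corners are kept separate), the directed face segments are chained into
## closed loops on the cube surface, and each loop is fan-triangulated.
## Because the face rule depends only on the shared face, adjacent cubes
## always agree on the contour there, which makes the mesh watertight by
## construction -- the property the classic table set lacks for binary data.
##
## Loops are oriented as the boundary of the positive patch of the cube
## surface (positive region to the left, seen from outside the cube), so the
## cap triangles consistently face away from the positive (interior) region.

## corner k (1..8) has offsets .mcCorner[k, ] with bit index cx + 2 cy + 4 cz
.mcCorner <- as.matrix(expand.grid(cx = 0:1, cy = 0:1, cz = 0:1))

.mcBuildEdges <- function() {
  lo <- NULL; axis <- integer(); lookup <- matrix(0L, 8, 8)
  id <- 0L
  for (a in 1:3) {
    for (k in 1:8) {
      if (.mcCorner[k, a] == 0L) {
        other <- .mcCorner[k, ]; other[a] <- 1L
        k2 <- 1L + sum(other * c(1L, 2L, 4L))
        id <- id + 1L
        lo <- rbind(lo, .mcCorner[k, ])
        axis <- c(axis, a)
        lookup[k, k2] <- id; lookup[k2, k] <- id
      }
    }
  }
  list(lo = lo, axis = axis, lookup = lookup,
       mid = lo + 0.5 * diag(3)[axis, , drop = FALSE])
}

.mcEdges <- .mcBuildEdges()

## the 6 faces with corner ids in counter-clockwise order seen from outside
.mcBuildFaces <- function() {
  faces <- list()
  nxt <- c(2L, 3L, 1L)
  for (a in 1:3) for (s in 0:1) {
    ids <- which(.mcCorner[, a] == s)
    p <- nxt[a]; q <- nxt[p]
    if (s == 1L) uv <- .mcCorner[ids, c(p, q), drop = FALSE]
    else uv <- .mcCorner[ids, c(q, p), drop = FALSE]
    ## cyclic CCW order in the (u, v) frame: (0,0), (1,0), (1,1), (0,1)
    ord <- order(match(paste(uv[, 1], uv[, 2]), c("0 0", "1 0", "1 1", "0 1")))
    faces[[length(faces) + 1L]] <- list(corners = ids[ord],
                                        uv = uv[ord, , drop = FALSE])
  }
  faces
}

.mcFaces <- .mcBuildFaces()

## directed segments (edge-id pairs) of the iso-contour on one face
.mcFaceSegments <- function(face, vals) {
  fc <- face$corners; uv <- face$uv
  v <- vals[fc]
  np <- sum(v)
  if (np == 0L || np == 4L) return(NULL)
  cyc <- c(1:4, 1)
  crossEdge <- integer(); crossPt <- NULL; adjTo <- NULL
  for (i in 1:4) {
    a <- cyc[i]; b <- cyc[i + 1]
    if (v[a] != v[b]) {
      crossEdge <- c(crossEdge, .mcEdges$lookup[fc[a], fc[b]])
      crossPt <- rbind(crossPt, (uv[a, ] + uv[b, ]) / 2)
      adjTo <- rbind(adjTo, c(a, b))
    }
  }
  orient <- function(i1, i2, pos) {
    ## direct q1 -> q2 so that the positive corner `pos` is on the left
    d <- crossPt[i2, ] - crossPt[i1, ]
    w <- uv[pos, ] - crossPt[i1, ]
    if (d[1] * w[2] - d[2] * w[1] > 0) c(crossEdge[i1], crossEdge[i2])
    else c(crossEdge[i2], crossEdge[i1])
  }
  segs <- list()
  if (np == 2L && v[1] == v[3]) {
    ## diagonal ambiguity: one corner-cutting segment per positive corner
    for (cpos in which(v == 1L)) {
      idx <- which(adjTo[, 1] == cpos | adjTo[, 2] == cpos)
      segs[[length(segs) + 1L]] <- orient(idx[1], idx[2], cpos)
    }
  } else {
    cpos <- which(v == 1L)[1]
    if (np == 2L) {
      segs[[1]] <- orient(1, 2, cpos)
    } else {
      cut <- if (np == 1L) which(v == 1L) else which(v == 0L)
      idx <- which(adjTo[, 1] == cut | adjTo[, 2] == cut)
      ref <- if (np == 1L) cut else ((cut + 1L) %% 4L) + 1L  # opposite corner
      segs[[1]] <- orient(idx[1], idx[2], ref)
    }
  }
  segs
}

## chain directed segments into closed loops of edge ids
.mcChainLoops <- function(segs) {
  if (!length(segs)) return(list())
  from <- vapply(segs, `[`, 0L, 1L)
  to <- vapply(segs, `[`, 0L, 2L)
  stopifnot(!anyDuplicated(from), !anyDuplicated(to),
            setequal(from, to))
  used <- rep(FALSE, length(segs))
  loops <- list()
  for (s in seq_along(segs)) {
    if (used[s]) next
    loop <- from[s]; cur <- s
    repeat {
      used[cur] <- TRUE
      nxt <- match(to[cur], from)
      if (nxt == s) break
      loop <- c(loop, from[nxt]); cur <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

## build the full 256-pattern table; entries: tri (m x 3 refs, refs 1..12 are
## edge midpoints, 13.. loop centroids), cent (k x 3 centroid offsets)
.mcBuildTable <- function() {
  table <- vector("list", 256L)
  for (p in 0:255) {
    vals <- as.integer(bitwAnd(p, c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)) > 0)
    segs <- list()
    for (f in .mcFaces) segs <- c(segs, .mcFaceSegments(f, vals))
    loops <- .mcChainLoops(segs)
    tri <- NULL; cent <- NULL
    for (loop in loops) {
      n <- length(loop)
      if (n == 3L) {
        tri <- rbind(tri, loop)
      } else {
        cent <- rbind(cent, colMeans(.mcEdges$mid[loop, , drop = FALSE]))
        cref <- 12L + nrow(cent)
        nxt <- c(2:n, 1L)
        tri <- rbind(tri, cbind(cref, loop, loop[nxt]))
      }
    }
    if (!is.null(tri)) {
      dimnames(tri) <- NULL
      storage.mode(tri) <- "integer"
    }
    table[[p + 1L]] <- list(tri = tri, cent = cent)
  }
  ## orientation sanity: pattern with only corner 1 positive must face away
  ## from that corner
  t1 <- table[[2L]]$tri
  v <- .mcEdges$mid[t1[1, ], ]
  nrm <- crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ])
  if (sum(nrm * (colMeans(v) - .mcCorner[1, ])) < 0) {
    for (p in seq_along(table)) {
      if (!is.null(table[[p]]$tri))
        table[[p]]$tri <- table[[p]]$tri[, c(1, 3, 2), drop = FALSE]
    }
  }
  table
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.mcCache <- new.env(parent = emptyenv())

.mcTable <- function() {
  if (is.null(.mcCache$table)) .mcCache$table <- .mcBuildTable()
  .mcCache$table
}
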