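## Readers and writers for the standard formats at the pipeline boundary:
## NIfTI label volumes (via RNifti), FLIRT-style 4x4 ASCII transforms, PLY
## and STL meshes, and CSV observation tables. Voxel indices are 0-based
## and world coordinates follow the NIfTI affine exactly; FLIRT matrices
## are applied in world-mm space as given -- supply world-space matrices
## (no FSL scaled-voxel reinterpretation is performed).

#' Read a NIfTI label volume
#'
#' The image must be 3D with an invertible affine; values must be integers
#' (within 1e-6, then rounded).
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @return A [LabelVolume-class].
#' @export
readLabelVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D label image, got ", length(d), "D: ", path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  if (abs(det(aff)) < 1e-12) stop("non-invertible affine in ", path)
  v <- as.array(img)
  r <- round(v)
  if (max(abs(v - r)) > 1e-6)
    stop("non-integer label values in ", path,
         " (max deviation ", signif(max(abs(v - r)), 3), ")")
  LabelVolume(array(as.integer(r), d), aff)
}

#' Write a label volume as NIfTI
#'
#' @param vol a [LabelVolume-class].
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  img <- RNifti::asNifti(vol@voxels)
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a FLIRT-style 4x4 ASCII transform
#'
#' Four rows of four whitespace-separated numbers; the last row must be
#' (0, 0, 0, 1) within 1e-6. The matrix is interpreted in world-mm space.
#'
#' @param path transform file.
#' @param rigid require a rigid transform (orthonormal rotation block);
#'   when `FALSE` (default) any affine is accepted.
#' @return a 4x4 matrix, or a [RigidTransform-class] when `rigid = TRUE`.
#' @export
readFlirtMatrix <- function(path, rigid = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4L)
    stop("expected 4 matrix rows in ", path, ", found ", length(lines))
  rows <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 4L || anyNA(vals))
      stop("malformed matrix row in ", path, ": '", l, "'")
    vals
  })
  m <- do.call(rbind, rows)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("last row of ", path, " is not (0, 0, 0, 1)")
  if (rigid) rigidTransform(m) else m
}

#' Write a transform in FLIRT-style 4x4 ASCII
#'
#' @param t a [RigidTransform-class] or 4x4 matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFlirtMatrix <- function(t, path) {
  m <- transformMatrix(t)
  stopifnot(all(dim(m) == c(4, 4)))
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "  ")),
             path)
  invisible(path)
}

#' Write a surface as ASCII PLY
#'
#' @param surface a [TriSurface-class] (vertex units mm).
#' @param path output `.ply` file.
#' @return `path`, invisibly.
#' @export
writeSurfacePLY <- function(surface, path) {
  stopifnot(is(surface, "TriSurface"))
  v <- surface@vertices; tr <- surface@triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(paste(3L, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY surface
#'
#' Minimal reader for the files produced by [writeSurfacePLY()] (ASCII,
#' x/y/z vertex properties, triangular faces).
#'
#' @param path `.ply` file.
#' @return A [TriSurface-class].
#' @export
readSurfacePLY <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("not an ASCII PLY file: ", path)
  hdrEnd <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[hdrEnd + seq_len(nv)]
  v <- matrix(as.numeric(unlist(strsplit(vl, " "))), ncol = 3, byrow = TRUE)
  fl <- lines[hdrEnd + nv + seq_len(nf)]
  f <- matrix(as.integer(unlist(strsplit(fl, " "))), ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3L)) stop("non-triangular face in ", path)
  TriSurface(v, f[, 2:4] + 1L)
}

#' Write a surface as binary STL
#'
#' @param surface a [TriSurface-class].
#' @param path output `.stl` file.
#' @return `path`, invisibly.
#' @export
writeSurfaceSTL <- function(surface, path) {
  stopifnot(is(surface, "TriSurface"))
  v <- surface@vertices; tr <- surface@triangles
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "MeshOverlap binary STL"))
  writeBin(hdr[1:80], con)
  writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  for (i in seq_len(nrow(tr))) {
    writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c3[i, ])), con,
             size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

## provenance header lines written at the top of CSV artifacts
.artifactHeader <- function(seed = NULL, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("MeshOverlap")),
                  error = function(e) "dev")
  h <- paste0("# MeshOverlap ", ver)
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  if (!is.null(config)) h <- c(h, paste0("# config: ", config))
  h
}

#' Write an observation table (or any data frame artifact) as CSV
#'
#' A `#`-prefixed provenance header (tool version, optional seed and
#' config) precedes the CSV body; [readObservationTable()] skips it.
#'
#' @param table `data.frame`.
#' @param path output `.csv` file.
#' @param seed,config optional provenance fields.
#' @return `path`, invisibly.
#' @export
writeObservationTable <- function(table, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.artifactHeader(seed, config), con)
  write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observation table written by [writeObservationTable()]
#'
#' @param path `.csv` file (comment lines starting with `#` are skipped).
#' @return `data.frame`.
#' @export
readObservationTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write circle QC reports as JSON
#'
#' @param reports a [CircleReport-class] or list of them.
#' @param path output `.json` file.
#' @param seed optional provenance seed.
#' @return `path`, invisibly.
#' @export
writeCircleReports <- function(reports, path, seed = NULL) {
  if (is(reports, "CircleReport")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, as.data.frame))
  ver <- tryCatch(as.character(utils::packageVersion("MeshOverlap")),
                  error = function(e) "dev")
  obj <- list(tool = "MeshOverlap", version = ver, reports = rows)
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
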