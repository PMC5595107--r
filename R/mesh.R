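#' Triangle mesh
#'
#' Construct a named triangle surface mesh. Coordinates are in millimeters,
#' right-handed axes; face winding is counter-clockwise seen from outside, so
#' face normals of a closed mesh point outward.
#'
#' @param name Identifier for the structure the mesh represents.
#' @param vertices Numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces Integer matrix, one row per triangle, 1-based vertex indices.
#' @param drop_degenerate Drop zero-area faces (with a message) instead of
#'   failing.
#' @return An object of class `triangle_mesh` with elements `name`,
#'   `vertices`, `faces`.
#' @export
triangle_mesh <- function(name, vertices, faces, drop_degenerate = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) == 0 || nrow(faces) == 0)
    stop("empty mesh: '", name, "' has no vertices or faces", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("mesh '", name, "' has non-finite coordinates", call. = FALSE)
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("mesh '", name, "' has face indices out of range", call. = FALSE)
  area2 <- .face_areas2(vertices, faces)
  degen <- area2 <= .Machine$double.eps * 100
  if (any(degen)) {
    if (!drop_degenerate)
      stop("mesh '", name, "' has ", sum(degen), " degenerate face(s)",
           call. = FALSE)
    message("dropped ", sum(degen), " degenerate face(s) from mesh '",
            name, "'")
    faces <- faces[!degen, , drop = FALSE]
    if (nrow(faces) == 0)
      stop("empty mesh: all faces of '", name, "' were degenerate",
           call. = FALSE)
  }
  structure(list(name = name, vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

# Twice the face areas (norm of the edge cross product).
.face_areas2 <- function(vertices, faces) {
  A <- vertices[faces[, 1], , drop = FALSE]
  B <- vertices[faces[, 2], , drop = FALSE]
  C <- vertices[faces[, 3], , drop = FALSE]
  sqrt(rowSums(.cross_rows(B - A, C - A)^2))
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Corner matrices (A, B, C) for all faces of a mesh.
mesh_corners <- function(mesh) {
  list(A = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       B = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       C = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight (closed and consistently oriented) when every directed
#' edge appears exactly once and its reverse also appears exactly once. Closed
#' meshes admit a well-defined inside/outside, which the crossing classifier
#' relies on.
#'
#' @param mesh A [triangle_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(ed[, 1], ed[, 2])
  rkey <- paste(ed[, 2], ed[, 1])
  !anyDuplicated(key) && all(rkey %in% key)
}

# Axis-aligned box mesh with outward-facing triangles.
box_mesh <- function(name, lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]),
                             y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # vertex order from expand.grid: index = 1 + ix + 2*iy + 4*iz (ix,iy,iz in 0:1)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = hi (normal +z)
    c(1, 2, 5), c(2, 6, 5),   # y = lo (normal -y)
    c(3, 7, 4), c(4, 7, 8),   # y = hi (normal +y)
    c(1, 5, 3), c(3, 5, 7),   # x = lo (normal -x)
    c(2, 4, 6), c(4, 8, 6))   # x = hi (normal +x)
  triangle_mesh(name, v, f)
}

# Closed cylinder mesh around an axis (point `center`, unit `axis`), with
# `half_length` to each cap, triangulated with `n_seg` segments. Outward
# orientation.
cylinder_mesh <- function(name, center, axis, radius, half_length, n_seg = 24) {
  axis <- .unit3(axis)
  # orthonormal frame
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit3(.cross3(axis, ref))
  w <- .cross3(axis, u)
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  ring <- outer(cos(ang), u) + outer(sin(ang), w)
  c1 <- center - half_length * axis
  c2 <- center + half_length * axis
  ring1 <- .rep_row(c1, n_seg) + radius * ring
  ring2 <- .rep_row(c2, n_seg) + radius * ring
  v <- rbind(ring1, ring2, c1, c2)
  i <- seq_len(n_seg)
  j <- c(seq_len(n_seg - 1) + 1, 1)          # next index around the ring
  side <- rbind(cbind(i, j, n_seg + i),
                cbind(j, n_seg + j, n_seg + i))
  cap1 <- cbind(2 * n_seg + 1, j, i)          # bottom cap faces -axis
  cap2 <- cbind(2 * n_seg + 2, n_seg + i, n_seg + j)  # top cap faces +axis
  triangle_mesh(name, v, rbind(side, cap1, cap2))
}

.mesh_bbox <- function(mesh) {
  list(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

#' Load a triangle mesh from disk
#'
#' Reads Wavefront OBJ (vertices and faces only) or binary STL. STL vertices
#' are welded exactly after the float32 round-trip. Degenerate (zero-area)
#' faces are dropped with a message.
#'
#' @param path File path.
#' @param format `"obj"` or `"stl"`; default guesses from the extension.
#' @param name Structure name; defaults to the file base name.
#' @return A [triangle_mesh()].
#' @export
load_mesh <- function(path, format = c("auto", "obj", "stl"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "stl"))
      stop("unknown mesh format for '", path, "'; pass format explicitly",
           call. = FALSE)
    format <- ext
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (format == "obj") read_obj(path, name) else read_stl(path, name)
}

#' @rdname load_mesh
#' @param mesh A [triangle_mesh()] to write.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("o %s", mesh$name), con)
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    stop("empty mesh: no vertices/faces in OBJ file ", path, call. = FALSE)
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  # face entries may be i, i/j, i//k or i/j/k; keep the leading vertex index
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) {
    idx <- as.integer(sub("/.*$", "", x))
    if (length(idx) != 3)
      stop("only triangular OBJ faces are supported", call. = FALSE)
    idx
  }))
  triangle_mesh(name, v, f, drop_degenerate = TRUE)
}

#' @rdname load_mesh
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC(mesh$name, width = -80))[1:80]
  header[is.na(header)] <- as.raw(0)
  writeBin(header, con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  co <- mesh_corners(mesh)
  nrm <- .cross_rows(co$B - co$A, co$C - co$A)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(c(nrm[i, ], co$A[i, ], co$B[i, ], co$C[i, ]), con,
             size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

read_stl <- function(path, name) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 84)
    stop("empty mesh: STL file ", path, " too short", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (nf < 1) stop("empty mesh: STL file has no facets", call. = FALSE)
  tri <- matrix(NA_real_, nf, 9)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("truncated STL file: ", path, call. = FALSE)
    readBin(con, "integer", 1, size = 2, endian = "little")
    tri[i, ] <- rec[4:12]
  }
  # weld identical float32 vertices
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uk <- !duplicated(key)
  verts <- pts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- cbind(idx[seq_len(nf)], idx[nf + seq_len(nf)], idx[2 * nf + seq_len(nf)])
  triangle_mesh(name, verts, faces, drop_degenerate = TRUE)
}
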