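#' Triangle surface mesh
#'
#' Lightweight container for a labelled triangle mesh. Coordinates are in
#' millimetres in the knee world frame: x = anterior, y = proximal,
#' z = lateral (right knee).
#'
#' @param vertices numeric matrix, n x 3 (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices, consistently
#'   oriented so triangle normals point outwards.
#' @param label single string naming the body or part.
#' @return An object of class `klx_mesh`.
#' @export
klx_mesh <- function(vertices, faces, label) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, label = as.character(label)),
            class = "klx_mesh")
}

#' @export
print.klx_mesh <- function(x, ...) {
  cat(sprintf("<klx_mesh '%s': %d vertices, %d faces>\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# --- rigid transforms (4x4 homogeneous) ----------------------------------

#' Rigid transform from rotation and translation
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return 4x4 homogeneous transform matrix.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the world axes, angle in degrees.
#' @param deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @name rotations
NULL

#' @rdname rotations
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rotations
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rotations
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis through a point
#'
#' @param axis length-3 direction (need not be unit).
#' @param point length-3 point the axis passes through (mm).
#' @param deg rotation angle, degrees, right-handed about `axis`.
#' @return 4x4 homogeneous transform.
#' @export
rotation_about <- function(axis, point, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  rigid_transform(R, as.numeric(point - R %*% point))
}

#' Apply a rigid transform
#'
#' @param x a `klx_mesh` or an n x 3 point matrix.
#' @param T 4x4 homogeneous transform.
#' @return object of the same type, transformed.
#' @export
transform_points <- function(x, T) {
  R <- T[1:3, 1:3]; t <- T[1:3, 4]
  if (is.matrix(x)) return(sweep(x %*% t(R), 2, -t))
  sweep(matrix(x, ncol = 3) %*% t(R), 2, -t)[1, ]
}

#' @rdname transform_points
#' @export
transform_mesh <- function(x, T) {
  x$vertices <- transform_points(x$vertices, T)
  x
}

# --- mesh IO --------------------------------------------------------------

#' Write a mesh as binary STL
#'
#' @param mesh a `klx_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", substr(paste0("kneelax ", mesh$label), 1, 79)))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  V <- mesh$vertices; F <- mesh$faces
  for (i in seq_len(nf)) {
    v <- V[F[i, ], , drop = FALSE]
    n <- pracma_cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, t(v))), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL mesh
#'
#' Vertices are welded by exact coordinate match.
#' @param path STL file path.
#' @param label label for the returned mesh (defaults to file name).
#' @return a `klx_mesh`.
#' @export
read_stl <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  tri <- matrix(0, nf, 9)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    tri[i, ] <- rec[4:12]
  }
  pts <- matrix(as.vector(t(tri)), ncol = 3, byrow = TRUE)
  key <- apply(round(pts, 6), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  klx_mesh(verts, faces, label %||% basename(path))
}

#' Write a mesh as ASCII PLY
#'
#' @inheritParams write_stl
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("comment kneelax part:", mesh$label),
    paste("element vertex", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 9),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @inheritParams read_stl
#' @export
read_ply <- function(path, label = NULL) {
  lines <- readLines(path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("not a PLY file: ", path)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  cmt <- grep("^comment kneelax part:", hdr, value = TRUE)
  if (is.null(label) && length(cmt))
    label <- trimws(sub("^comment kneelax part:", "", cmt[1]))
  body <- lines[-seq_len(hdr_end)]
  verts <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE), ncol = 4, byrow = TRUE)
  klx_mesh(verts, fl[, 2:4, drop = FALSE] + 1L, label %||% basename(path))
}

# cross product (avoid pulling pracma in just for this)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Write all parts of a knee geometry to a directory
#'
#' One file per labelled part, in the requested format.
#' @param geometry a named list of `klx_mesh` (e.g. from [make_knee_geometry()]).
#' @param dir output directory (created if absent).
#' @param format `"stl"` (binary) or `"ply"` (ASCII).
#' @return tibble with columns `label`, `path`.
#' @export
write_geometry <- function(geometry, dir, format = c("stl", "ply")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meshes <- Filter(function(m) inherits(m, "klx_mesh"), geometry)
  paths <- purrr::map_chr(meshes, function(m) {
    p <- file.path(dir, paste0(m$label, ".", format))
    if (format == "stl") write_stl(m, p) else write_ply(m, p)
    p
  })
  tibble::tibble(label = purrr::map_chr(meshes, "label"), path = unname(paths))
}
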