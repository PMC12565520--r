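# Triangle-mesh container, validation, volume, and STL / landmark IO.

#' Triangle surface mesh of a (proximal) tibia
#'
#' Lightweight container for a watertight, consistently outward-oriented
#' triangle mesh in mm. The mesh is the object the virtual osteotomy is
#' performed on; fragments produced by slicing are again `tibial_mesh`
#' objects.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices; outward
#'   orientation (counter-clockwise seen from outside).
#' @param validate check watertightness and positive volume (default `TRUE`).
#' @return an object of class `tibial_mesh`.
#' @seealso [validate_mesh()], [mesh_volume()], [slice_mesh()]
#' @export
tibial_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "tibial_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate a mesh for watertightness and orientation
#'
#' A mesh is accepted when every undirected edge is shared by exactly two
#' faces, with opposite directions (consistent orientation), and the signed
#' enclosed volume is positive. No repair is attempted: silent repair would
#' invalidate downstream volume-conservation guarantees.
#'
#' @param mesh a [tibial_mesh()].
#' @return the mesh, invisibly; errors with a named defect otherwise.
#' @export
validate_mesh <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  if (any(f < 1L) || any(f > nv)) stop("mesh defect: face index out of range", call. = FALSE)
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("mesh defect: degenerate face (repeated vertex)", call. = FALSE)
  # directed edges; key = from * (nv+1) + to
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  key <- from * (nv + 1) + to
  if (anyDuplicated(key))
    stop("mesh defect: duplicated directed edge (inconsistent orientation or doubled face)",
         call. = FALSE)
  rkey <- to * (nv + 1) + from
  if (!all(key %in% rkey))
    stop("mesh defect: boundary edge found - mesh is not watertight", call. = FALSE)
  vol <- mesh_volume_signed(mesh)
  if (vol <= 0)
    stop("mesh defect: non-positive enclosed volume (inward orientation?)", call. = FALSE)
  invisible(mesh)
}

mesh_volume_signed <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' Signed divergence-theorem (summed signed tetrahedra) volume; exact for
#' polyhedra up to floating point.
#'
#' @param mesh a [tibial_mesh()].
#' @param validate verify watertightness first (default `TRUE`).
#' @return volume in mm^3 (positive).
#' @export
mesh_volume <- function(mesh, validate = TRUE) {
  if (validate) validate_mesh(mesh)
  mesh_volume_signed(mesh)
}

#' @export
print.tibial_mesh <- function(x, ...) {
  cat(sprintf("<tibial_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# ---- landmark set ------------------------------------------------------

#' Anatomical landmark annotation for a tibial mesh
#'
#' The minimal landmark set from which the anatomical frame is built:
#' the medial and lateral plateau edge points, the joint center, and the
#' anterior direction.
#'
#' @param medial_plateau_edge,lateral_plateau_edge 3D points (mm) on the
#'   plateau rim.
#' @param joint_center 3D point (mm), origin of the anatomical frame.
#' @param anterior_direction unit 3-vector, anterior (+AP).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(medial_plateau_edge, lateral_plateau_edge,
                         joint_center, anterior_direction) {
  lm <- structure(list(
    medial_plateau_edge = as.numeric(medial_plateau_edge),
    lateral_plateau_edge = as.numeric(lateral_plateau_edge),
    joint_center = as.numeric(joint_center),
    anterior_direction = unitize(as.numeric(anterior_direction))
  ), class = "landmark_set")
  ml <- lm$lateral_plateau_edge - lm$medial_plateau_edge
  if (vnorm(ml) < 1e-9)
    stop("medial and lateral plateau edge points must be distinct", call. = FALSE)
  if (vnorm(cross3(unitize(ml), lm$anterior_direction)) < 1e-6)
    stop("anterior_direction must not be parallel to the medial-lateral direction",
         call. = FALSE)
  lm
}

# ---- STL IO ------------------------------------------------------------

#' Write a mesh to STL
#'
#' @param mesh a [tibial_mesh()].
#' @param path output file path.
#' @param format `"ascii"` (default) or `"binary"`; binary STL stores
#'   single-precision floats, so round-trips preserve coordinates to
#'   single precision only.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-30] <- 1
  nrm <- nrm / len
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid cwhto", con)
    tri <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      nrm[, 1], nrm[, 2], nrm[, 3],
      a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], c_[, 1], c_[, 2], c_[, 3])
    writeLines(tri, con)
    writeLines("endsolid cwhto", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("cwhto binary STL", width = 80, flag = "-"))
    writeBin(header[seq_len(80)], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    dat <- t(cbind(nrm, a, b, c_))  # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(dat[, i], con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Read a mesh from STL
#'
#' Reads ASCII or binary STL (auto-detected), merges coincident vertices,
#' and verifies watertightness. STL stores a triangle soup, so vertex
#' merging uses exact coordinate identity after the single-precision
#' round-trip.
#'
#' @param path STL file path.
#' @param validate verify watertightness (default `TRUE`); a missing or
#'   doubled triangle raises a validation error naming the defect.
#' @return a [tibial_mesh()].
#' @export
read_mesh <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 5L)
  close(con)
  tri <- if (identical(rawToChar(head), "solid") && is_ascii_stl(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
  soup_to_mesh(tri, validate = validate)
}

is_ascii_stl <- function(path) {
  # binary STLs may also start with "solid"; require a "facet" token in text
  txt <- tryCatch(readLines(path, n = 20L, warn = FALSE), error = function(e) "")
  any(grepl("facet", txt, fixed = TRUE))
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3", call. = FALSE)
  nums <- vapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]),
                 numeric(3))
  matrix(as.numeric(nums), ncol = 3L, byrow = TRUE)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  # 12 little-endian floats + 2 attribute bytes per facet
  out <- matrix(0, nrow = nf * 3L, ncol = 3L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    out[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], ncol = 3L, byrow = TRUE)
  }
  out
}

# Collapse a triangle soup (3m x 3 matrix, consecutive triples) into an
# indexed mesh by exact-coordinate vertex identity.
soup_to_mesh <- function(tri, validate = TRUE) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uidx <- !duplicated(key)
  verts <- tri[uidx, , drop = FALSE]
  map <- match(key, key[uidx])
  faces <- matrix(map, ncol = 3L, byrow = TRUE)
  tibial_mesh(verts, faces, validate = validate)
}

# ---- landmark IO -------------------------------------------------------

#' Write / read landmark annotations (JSON)
#'
#' Schema: a JSON object with keys `medial_plateau_edge`,
#' `lateral_plateau_edge`, `joint_center` (3-element arrays, mm) and
#' `anterior_direction` (unit 3-vector).
#'
#' @param landmarks a [landmark_set()].
#' @param path file path.
#' @return `write_landmarks`: `path` invisibly; `read_landmarks`: a
#'   [landmark_set()]. A missing key raises a schema error.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("medial_plateau_edge", "lateral_plateau_edge",
                "joint_center", "anterior_direction")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("landmark schema error: missing key(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  landmark_set(obj$medial_plateau_edge, obj$lateral_plateau_edge,
               obj$joint_center, obj$anterior_direction)
}
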