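# Low-level vector, plane and polygon helpers shared by the mesh engine.
# Conventions: 3D points are length-3 numeric vectors or n x 3 matrices,
# all lengths in mm; angles are degrees at user-facing interfaces and
# radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors
#'
#' Numerically stable angle via `atan2(||a x b||, a.b)`; accurate near 0 and
#' pi where `acos` loses precision.
#'
#' @param a,b numeric length-3 vectors.
#' @return angle in radians, in `[0, pi]`.
#' @keywords internal
angle_between <- function(a, b) {
  atan2(vnorm(cross3(a, b)), sum(a * b))
}

#' Construct a plane from a point and a normal
#'
#' @param point a 3D point on the plane (mm).
#' @param normal plane normal; normalized internally.
#' @return an object of class `cwhto_plane` with fields `point`, `normal`
#'   (unit) and `offset` (`normal . point`).
#' @export
plane3 <- function(point, normal) {
  n <- unitize(as.numeric(normal))
  p <- as.numeric(point)
  stopifnot(length(p) == 3L)
  structure(list(point = p, normal = n, offset = sum(n * p)),
            class = "cwhto_plane")
}

# Signed distances of points (n x 3 matrix) from a plane.
plane_distance <- function(plane, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  drop(pts %*% plane$normal) - plane$offset
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula. Rotation is right-handed about `axis`.
#'
#' @param axis rotation axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- unitize(as.numeric(axis))
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rigid transform (rotation about a point)
#'
#' @param R 3 x 3 rotation matrix.
#' @param center point the rotation pivots about.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(R, center = c(0, 0, 0)) {
  structure(list(R = R, center = as.numeric(center)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param pts a 3D point or an n x 3 matrix of points.
#' @param vector logical; if `TRUE` the translation part is dropped
#'   (for direction vectors / normals).
#' @return transformed points with the input's shape.
#' @export
apply_transform <- function(transform, pts, vector = FALSE) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, ncol = 3L)
  out <- if (vector) {
    pts %*% t(transform$R)
  } else {
    sweep(sweep(pts, 2L, transform$center) %*% t(transform$R),
          2L, transform$center, `+`)
  }
  if (single) drop(out) else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$R), transform$center)
}

# ---- 2D polygon helpers ------------------------------------------------
# Polygons are lists of rings; each ring a list(x =, y =) closed implicitly.

# Signed shoelace area of one ring (positive = counter-clockwise).
ring_area_signed <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

polygon_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  sum(vapply(rings, function(r) abs(ring_area_signed(r)), numeric(1)))
}

# First moment of area about the y axis: integral of x over the polygon.
# Exact shoelace-style formula per ring, summed over rings.
polygon_moment_x <- function(rings) {
  if (length(rings) == 0L) return(0)
  m <- 0
  for (ring in rings) {
    x <- ring$x; y <- ring$y
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    cr <- x[j] * y - x * y[j]
    m <- m + abs(sum((x[j] + x) * cr) / 6)  # per-ring orientation-free
  }
  m
}

# Boolean intersection area of two ring-lists via polyclip (Vatti; robust
# for identical and touching polygons).
polygon_intersection_area <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  res <- polyclip::polyclip(a, b, op = "intersection",
                            fillA = "nonzero", fillB = "nonzero")
  polygon_area(res)
}

# Clip a ring-list to the half-plane x <= x0 (used for the medial portion
# of a cut face).
polygon_clip_halfplane <- function(rings, x0, side = c("le", "ge")) {
  side <- match.arg(side)
  if (length(rings) == 0L) return(list())
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  pad <- max(diff(range(xs)), diff(range(ys)), 1) * 2
  box <- if (side == "le") {
    list(x = c(min(xs) - pad, x0, x0, min(xs) - pad),
         y = c(min(ys) - pad, min(ys) - pad, max(ys) + pad, max(ys) + pad))
  } else {
    list(x = c(x0, max(xs) + pad, max(xs) + pad, x0),
         y = c(min(ys) - pad, min(ys) - pad, max(ys) + pad, max(ys) + pad))
  }
  polyclip::polyclip(rings, list(box), op = "intersection",
                     fillA = "nonzero", fillB = "nonzero")
}

# x-intervals of a ring-list cut by the horizontal line y = y0.
# Returns a 2-column matrix of (xmin, xmax) interval pairs (possibly none).
polygon_line_intervals <- function(rings, y0) {
  xs <- numeric(0)
  for (ring in rings) {
    x <- ring$x; y <- ring$y
    n <- length(x)
    j <- c(2:n, 1L)
    crosses <- (y < y0 & y[j] >= y0) | (y >= y0 & y[j] < y0)
    if (any(crosses)) {
      i <- which(crosses)
      t <- (y0 - y[i]) / (y[j][i] - y[i])
      xs <- c(xs, x[i] + t * (x[j][i] - x[i]))
    }
  }
  if (length(xs) < 2L) return(matrix(numeric(0), ncol = 2L))
  xs <- sort(xs)
  k <- seq(1L, 2L * (length(xs) %/% 2L), by = 2L)
  cbind(xs[k], xs[k + 1L])
}

# Ear-clipping triangulation of one simple ring. Returns an integer matrix
# (n-2) x 3 of vertex indices into the ring. Assumes a simple polygon;
# orientation handled internally.
ear_clip <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 3L) stop("degenerate ring with fewer than 3 vertices", call. = FALSE)
  idx <- seq_len(n)
  if (ring_area_signed(ring) < 0) idx <- rev(idx)  # force CCW
  tris <- matrix(0L, nrow = n - 2L, ncol = 3L)
  nt <- 0L
  guard <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[if (k == 1L) m else k - 1L]
      i1 <- idx[k]
      i2 <- idx[if (k == m) 1L else k + 1L]
      ax <- x[i1] - x[i0]; ay <- y[i1] - y[i0]
      bx <- x[i2] - x[i1]; by <- y[i2] - y[i1]
      cr <- ax * by - ay * bx
      if (cr <= 1e-14 * (abs(ax * by) + abs(ay * bx) + 1e-30)) next  # reflex/degenerate
      # ear test: no other vertex strictly inside triangle (i0, i1, i2)
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others)) {
        px <- x[others]; py <- y[others]
        d1 <- (x[i1] - x[i0]) * (py - y[i0]) - (y[i1] - y[i0]) * (px - x[i0])
        d2 <- (x[i2] - x[i1]) * (py - y[i1]) - (y[i2] - y[i1]) * (px - x[i1])
        d3 <- (x[i0] - x[i2]) * (py - y[i2]) - (y[i0] - y[i2]) * (px - x[i2])
        eps <- -1e-12 * max(abs(c(d1, d2, d3)), 1)
        if (any(d1 > eps & d2 > eps & d3 > eps)) next
      }
      nt <- nt + 1L
      tris[nt, ] <- c(i0, i1, i2)
      idx <- idx[-k]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      # fall back: clip the least-reflex corner to guarantee termination on
      # nearly-degenerate rings (collinear runs from sliced flat facets)
      guard <- guard + 1L
      if (guard > n) stop("ear clipping failed: ring may be self-intersecting",
                          call. = FALSE)
      nt <- nt + 1L
      tris[nt, ] <- c(idx[length(idx)], idx[1L], idx[2L])
      idx <- idx[-1L]
    }
  }
  nt <- nt + 1L
  tris[nt, ] <- idx
  tris[seq_len(nt), , drop = FALSE]
}
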