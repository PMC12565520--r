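# Plane sectioning of watertight triangle meshes with cross-section capping.
#
# Algorithm: vertices are classified by signed plane distance with snapping
# of near-zero distances (on-plane vertices belong to both fragments, and a
# whole-triangle membership rule sends purely tangent triangles to the
# front side). Edge-plane intersection points are computed once per
# undirected edge so that the two fragments share bit-identical vertices,
# which keeps both outputs exactly watertight and makes volume conservation
# hold to floating-point accuracy. The cross-section chords are chained
# into closed loops, oriented, ear-clipped, and the resulting cap triangles
# attached to both fragments with opposite windings.

# In-plane orthonormal chart: list(origin, e1, e2) with e1 x e2 = normal.
plane_chart <- function(plane, origin = NULL, u_axis = NULL) {
  n <- plane$normal
  if (is.null(u_axis)) {
    seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u_axis <- cross3(seed, n)
  }
  e1 <- unitize(u_axis - sum(u_axis * n) * n)
  e2 <- cross3(n, e1)
  if (is.null(origin)) origin <- plane$point
  # project origin onto the plane so the chart is exactly in-plane
  origin <- origin - (sum(origin * n) - plane$offset) * n
  list(origin = as.numeric(origin), e1 = e1, e2 = e2, normal = n)
}

chart_project <- function(chart, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  rel <- sweep(pts, 2L, chart$origin)
  cbind(u = drop(rel %*% chart$e1), v = drop(rel %*% chart$e2))
}

chart_unproject <- function(chart, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2L)
  sweep(outer(uv[, 1], chart$e1) + outer(uv[, 2], chart$e2), 2L,
        chart$origin, `+`)
}

#' Planar cut face
#'
#' The capped cross-section produced by [slice_mesh()], expressed as closed
#' 2D polygon rings in an orthonormal chart of the cutting plane.
#'
#' @param plane the cutting plane.
#' @param chart the in-plane chart (origin, `e1`, `e2`).
#' @param rings list of rings, each `list(x =, y =)` in chart coordinates.
#' @return object of class `cut_face` with an `area` field (mm^2).
#' @export
cut_face <- function(plane, chart, rings) {
  structure(list(plane = plane, chart = chart, rings = rings,
                 area = polygon_area(rings)),
            class = "cut_face")
}

#' @export
print.cut_face <- function(x, ...) {
  cat(sprintf("<cut_face> %d ring(s), area %.2f mm^2\n", length(x$rings), x$area))
  invisible(x)
}

# Split-classification shared by slice_mesh and mesh_plane_section.
classify_vertices <- function(mesh, plane) {
  d <- plane_distance(plane, mesh$vertices)
  scale <- max(1, max(abs(mesh$vertices)))
  eps <- 1e-7 * scale
  s <- integer(length(d))
  s[d > eps] <- 1L
  s[d < -eps] <- -1L
  d[s == 0L] <- 0
  list(d = d, s = s)
}

#' Slice a watertight mesh with a plane
#'
#' Cuts `mesh` into the fragment on the positive-normal side (`front`) and
#' the negative side (`back`), both re-capped with the planar cross-section
#' so that each fragment is again watertight. The sum of the fragment
#' volumes equals the input volume to floating-point accuracy.
#'
#' @param mesh a [tibial_mesh()] (watertight).
#' @param plane a [plane3()].
#' @param chart optional in-plane chart for the returned [cut_face()];
#'   defaults to an arbitrary orthonormal chart at the plane point.
#' @param validate validate the input mesh first (default `TRUE`).
#' @return list with `front`, `back` ([tibial_mesh()]) and `face`
#'   ([cut_face()]).
#' @export
slice_mesh <- function(mesh, plane, chart = NULL, validate = TRUE) {
  if (validate) validate_mesh(mesh)
  cl <- classify_vertices(mesh, plane)
  s <- cl$s; d <- cl$d
  f <- mesh$faces
  if (all(s >= 0L) || all(s <= 0L))
    stop("geometry error: plane does not intersect the mesh interior", call. = FALSE)

  smat <- matrix(s[f], ncol = 3L)
  has_pos <- rowSums(smat == 1L) > 0L
  has_neg <- rowSums(smat == -1L) > 0L
  mixed <- has_pos & has_neg
  front_only <- !has_neg           # all >= 0 (tangent faces go front)
  back_only <- !has_pos & has_neg  # all <= 0 with a strict negative

  nv <- nrow(mesh$vertices)
  # --- intersection points, one per crossing undirected edge
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  ekey <- lo * (nv + 1) + hi
  keep <- !duplicated(ekey)
  lo <- lo[keep]; hi <- hi[keep]; ekey <- ekey[keep]
  crossing <- s[lo] * s[hi] == -1L
  xlo <- lo[crossing]; xhi <- hi[crossing]
  t <- d[xlo] / (d[xlo] - d[xhi])
  newpts <- mesh$vertices[xlo, , drop = FALSE] +
    t * (mesh$vertices[xhi, , drop = FALSE] - mesh$vertices[xlo, , drop = FALSE])
  verts <- rbind(mesh$vertices, newpts)
  xid <- seq_len(sum(crossing)) + nv
  names(xid) <- as.character(ekey[crossing])

  front_faces <- f[front_only, , drop = FALSE]
  back_faces <- f[back_only, , drop = FALSE]
  chords_a <- integer(0); chords_b <- integer(0)

  # chords contributed by back-side faces with an on-plane edge
  if (any(back_only)) {
    bof <- f[back_only, , drop = FALSE]
    bos <- matrix(s[bof], ncol = 3L)
    two0 <- which(rowSums(bos == 0L) == 2L)
    for (i in two0) {
      z <- bof[i, bos[i, ] == 0L]
      chords_a <- c(chords_a, z[1]); chords_b <- c(chords_b, z[2])
    }
  }

  # --- split mixed faces by walking the triangle boundary
  fl <- vector("list", sum(mixed)); bl <- vector("list", sum(mixed))
  mix_idx <- which(mixed)
  for (k in seq_along(mix_idx)) {
    tri <- f[mix_idx[k], ]
    fp <- integer(0); bp <- integer(0); shared <- integer(0)
    for (j in 1:3) {
      vi <- tri[j]; vn <- tri[if (j == 3L) 1L else j + 1L]
      if (s[vi] >= 0L) fp <- c(fp, vi)
      if (s[vi] <= 0L) bp <- c(bp, vi)
      if (s[vi] == 0L) shared <- c(shared, vi)
      if (s[vi] * s[vn] == -1L) {
        key <- as.character(min(vi, vn) * (nv + 1) + max(vi, vn))
        ip <- xid[[key]]
        fp <- c(fp, ip); bp <- c(bp, ip); shared <- c(shared, ip)
      }
    }
    if (length(shared) == 2L) {
      chords_a <- c(chords_a, shared[1]); chords_b <- c(chords_b, shared[2])
    }
    if (length(fp) >= 3L)
      fl[[k]] <- cbind(fp[1], fp[2:(length(fp) - 1L)], fp[3:length(fp)])
    if (length(bp) >= 3L)
      bl[[k]] <- cbind(bp[1], bp[2:(length(bp) - 1L)], bp[3:length(bp)])
  }
  front_faces <- rbind(front_faces, do.call(rbind, fl))
  back_faces <- rbind(back_faces, do.call(rbind, bl))

  # --- chain chords into closed loops
  keep <- chords_a != chords_b
  loops <- chain_chords(chords_a[keep], chords_b[keep])
  if (is.null(chart)) chart <- plane_chart(plane)

  rings <- vector("list", length(loops))
  front_caps <- vector("list", length(loops))
  back_caps <- vector("list", length(loops))
  for (k in seq_along(loops)) {
    loop <- loops[[k]]
    uv <- chart_project(chart, verts[loop, , drop = FALSE])
    ring <- list(x = uv[, 1], y = uv[, 2])
    if (ring_area_signed(ring) < 0) {           # orient CCW in the chart
      loop <- rev(loop)
      ring <- list(x = rev(ring$x), y = rev(ring$y))
    }
    rings[[k]] <- ring
    tri <- ear_clip(ring)
    cap <- matrix(loop[tri], ncol = 3L)
    back_caps[[k]] <- cap                        # CCW => normal +n, outward for back
    front_caps[[k]] <- cap[, c(1L, 3L, 2L), drop = FALSE]
  }
  front_faces <- rbind(front_faces, do.call(rbind, front_caps))
  back_faces <- rbind(back_faces, do.call(rbind, back_caps))

  list(front = compact_mesh(verts, front_faces),
       back = compact_mesh(verts, back_faces),
       face = cut_face(plane, chart, rings))
}

# Chain undirected chord segments (index pairs) into closed vertex loops.
chain_chords <- function(a, b) {
  if (length(a) == 0L)
    stop("geometry error: empty cross-section", call. = FALSE)
  # adjacency map vertex -> chord indices
  m <- length(a)
  adj <- split(rep(seq_len(m), 2L), c(a, b))
  deg <- lengths(adj)
  if (any(deg != 2L))
    stop("geometry error: cross-section chords do not form closed loops",
         call. = FALSE)
  used <- logical(m)
  loops <- list()
  for (start in seq_len(m)) {
    if (used[start]) next
    loop <- c(a[start], b[start])
    used[start] <- TRUE
    repeat {
      tail <- loop[length(loop)]
      cand <- adj[[as.character(tail)]]
      nxt <- cand[!used[cand]]
      if (length(nxt) == 0L) break
      nxt <- nxt[1L]
      used[nxt] <- TRUE
      nextv <- if (a[nxt] == tail) b[nxt] else a[nxt]
      if (nextv == loop[1L]) break
      loop <- c(loop, nextv)
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  if (length(loops) == 0L)
    stop("geometry error: degenerate cross-section", call. = FALSE)
  loops
}

compact_mesh <- function(verts, faces) {
  used <- sort(unique(as.integer(faces)))
  map <- integer(nrow(verts))
  map[used] <- seq_along(used)
  tibial_mesh(verts[used, , drop = FALSE],
              matrix(map[faces], ncol = 3L), validate = FALSE)
}

# Cross-section of a mesh by a plane without building fragments: returns
# the section rings as 3D point loops (list of n x 3 matrices).
mesh_plane_section <- function(mesh, plane) {
  cl <- classify_vertices(mesh, plane)
  s <- cl$s; d <- cl$d
  f <- mesh$faces
  if (all(s >= 0L) || all(s <= 0L))
    stop("geometry error: plane does not intersect the mesh interior", call. = FALSE)
  nv <- nrow(mesh$vertices)
  ea <- c(f[, 1], f[, 2], f[, 3]); eb <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  ekey <- lo * (nv + 1) + hi
  keep <- !duplicated(ekey)
  lo <- lo[keep]; hi <- hi[keep]; ekey <- ekey[keep]
  crossing <- s[lo] * s[hi] == -1L
  xlo <- lo[crossing]; xhi <- hi[crossing]
  t <- d[xlo] / (d[xlo] - d[xhi])
  newpts <- mesh$vertices[xlo, , drop = FALSE] +
    t * (mesh$vertices[xhi, , drop = FALSE] - mesh$vertices[xlo, , drop = FALSE])
  verts <- rbind(mesh$vertices, newpts)
  xid <- seq_len(sum(crossing)) + nv
  names(xid) <- as.character(ekey[crossing])

  smat <- matrix(s[f], ncol = 3L)
  has_pos <- rowSums(smat == 1L) > 0L
  has_neg <- rowSums(smat == -1L) > 0L
  chords_a <- integer(0); chords_b <- integer(0)
  for (fi in which(has_pos & has_neg)) {
    tri <- f[fi, ]
    shared <- integer(0)
    for (j in 1:3) {
      vi <- tri[j]; vn <- tri[if (j == 3L) 1L else j + 1L]
      if (s[vi] == 0L) shared <- c(shared, vi)
      if (s[vi] * s[vn] == -1L) {
        key <- as.character(min(vi, vn) * (nv + 1) + max(vi, vn))
        shared <- c(shared, xid[[key]])
      }
    }
    if (length(shared) == 2L) {
      chords_a <- c(chords_a, shared[1]); chords_b <- c(chords_b, shared[2])
    }
  }
  for (fi in which(!has_pos & has_neg)) {
    tri <- f[fi, ]
    z <- tri[s[tri] == 0L]
    if (length(z) == 2L) {
      chords_a <- c(chords_a, z[1]); chords_b <- c(chords_b, z[2])
    }
  }
  keep <- chords_a != chords_b
  loops <- chain_chords(chords_a[keep], chords_b[keep])
  lapply(loops, function(loop) verts[loop, , drop = FALSE])
}
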