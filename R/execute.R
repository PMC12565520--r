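# Plan execution: cutting, wedge extraction, closure, non-overlap metrics.

#' Execute an osteotomy plan on a mesh
#'
#' Slices the tibia with the proximal plane, then slices the remainder with
#' the distal plane. The resected wedge is the region distal to the
#' proximal cut and proximal to the distal cut; because the two planes
#' cross along the hinge axis, this region lies lateral of the hinge
#' automatically, and for the hybrid techniques the distal fragment keeps
#' its original proximal-plane surface medial of the hinge. The three
#' fragment volumes sum to the input volume to floating-point accuracy.
#'
#' Cut faces are charted with the hinge point at the origin and +u along
#' the medial-to-lateral chord, so u > 0 is lateral of the hinge.
#'
#' @param mesh a [tibial_mesh()].
#' @param plan an [plan_osteotomy()] result.
#' @param validate validate the input mesh (default `TRUE`).
#' @return list with meshes `proximal_fragment`, `wedge`,
#'   `distal_fragment`, faces `proximal_face`, `distal_face`
#'   ([cut_face()]), and `volumes` (named: original, proximal, wedge,
#'   distal, conservation_error as a relative error).
#' @export
execute_plan <- function(mesh, plan, validate = TRUE) {
  stopifnot(inherits(plan, "osteotomy_plan"))
  prox <- plan$proximal_plane
  dist <- plan$distal_plane
  if (plan$kerf > 0) {
    k <- plan$kerf / 2
    prox <- plane3(prox$point + k * prox$normal, prox$normal)
    dist <- plane3(dist$point - k * dist$normal, dist$normal)
  }
  chart_p <- plane_chart(prox, origin = plan$hinge_point, u_axis = plan$chord_dir)
  s1 <- slice_mesh(mesh, prox, chart = chart_p, validate = validate)
  u_d <- drop(rotation_about_axis(plan$hinge_axis, deg2rad(plan$theta)) %*%
                plan$chord_dir)
  chart_d <- plane_chart(dist, origin = plan$hinge_point, u_axis = u_d)
  s2 <- slice_mesh(s1$back, dist, chart = chart_d, validate = FALSE)

  v_orig <- mesh_volume_signed(mesh)
  v_prox <- mesh_volume_signed(s1$front)
  v_wedge <- mesh_volume_signed(s2$front)
  v_dist <- mesh_volume_signed(s2$back)
  cons <- abs(v_prox + v_wedge + v_dist - v_orig) / v_orig

  list(proximal_fragment = s1$front,
       wedge = s2$front,
       distal_fragment = s2$back,
       proximal_face = s1$face,
       distal_face = s2$face,
       volumes = c(original = v_orig, proximal = v_prox,
                   wedge = v_wedge, distal = v_dist,
                   conservation_error = cons))
}

#' Medial gap volume of a hybrid osteotomy
#'
#' For hinge positions inside the bone (hybrid techniques) closing the
#' lateral wedge opens a small medial gap. It is measured as the mirror
#' construction of the lateral wedge: the bone region between the proximal
#' cutting plane and the proximal plane rotated by `-theta` (opening
#' medially) about the hinge axis. Defined this way, gap and wedge scale
#' identically with their hinge arms, so on a joint-line-parallel cut
#' through a prism the gap/wedge ratio is exactly `(f/(1-f))^2` with `f`
#' the hinge fraction (1/9 for the 3:1 hinge).
#'
#' @param mesh the intact [tibial_mesh()].
#' @param plan an [plan_osteotomy()] result.
#' @param rest optional pre-computed fragment distal to the proximal plane
#'   (avoids re-slicing when [execute_plan()] already ran).
#' @return gap volume in mm^3 (0 for a medial-cortex hinge).
#' @export
medial_gap_volume <- function(mesh, plan, rest = NULL) {
  if (plan$hinge_fraction <= 0) return(0)
  if (is.null(rest)) {
    rest <- slice_mesh(mesh, plan$proximal_plane, validate = FALSE)$back
  }
  n_m <- drop(rotation_about_axis(plan$hinge_axis, -deg2rad(plan$theta)) %*%
                plan$proximal_plane$normal)
  pl_m <- plane3(plan$hinge_point, n_m)
  s <- slice_mesh(rest, pl_m, validate = FALSE)
  mesh_volume_signed(s$front)
}

#' Non-overlap metrics after osteotomy closure
#'
#' Transforms the distal cut face through the closure rotation into the
#' proximal plane and compares the two faces in the shared 2D chart
#' (hinge at the origin, +u lateral). Reports:
#'
#' * `overlap_area`: polygon boolean intersection of the faces.
#' * `nonoverlap_total_difference`: proximal face area minus the overlap
#'   (the full uncovered proximal surface, including anterior/posterior rim
#'   slivers).
#' * `nonoverlap_lateral`: scanline lateral overhang - at each AP station
#'   the mismatch between the lateral-most boundaries of the two faces,
#'   integrated over AP, for whichever fragment protrudes (see
#'   `overhang_fragment`); stations where either face is absent (rim
#'   slivers) are excluded.
#' * `nonoverlap_medial`: the uncovered proximal surface on the medial
#'   side - the extent by which the proximal face reaches medial of the
#'   distal face's medial-most boundary, integrated over AP. This is the
#'   medial gap area of the hybrid hinges and ~0 for medial-cortex
#'   hinges.
#' * `nonoverlap_signed`: `+nonoverlap_lateral` for medial-cortex hinges
#'   (conventional, oblique), `-nonoverlap_medial` for hybrid hinges
#'   (medial opening reported as negative).
#' * `overhang_fragment`: which fragment protrudes laterally.
#'
#' @param proximal_face,distal_face [cut_face()] objects from
#'   [execute_plan()].
#' @param plan the [plan_osteotomy()] result the faces came from.
#' @param step AP scanline step in mm (default 0.25).
#' @return named list of metrics.
#' @export
compute_nonoverlap <- function(proximal_face, distal_face, plan, step = 0.25) {
  if (length(proximal_face$rings) == 0L || length(distal_face$rings) == 0L)
    stop("geometry error: empty cut face", call. = FALSE)
  if (step <= 0) stop("parameter error: step must be > 0", call. = FALSE)
  closure <- closure_transform(plan)
  prings <- proximal_face$rings
  drings <- lapply(distal_face$rings, function(r) {
    p3 <- chart_unproject(distal_face$chart, cbind(r$x, r$y))
    p3 <- apply_transform(closure, p3)
    uv <- chart_project(proximal_face$chart, p3)
    list(x = uv[, 1], y = uv[, 2])
  })

  p_area <- polygon_area(prings)
  overlap <- polygon_intersection_area(prings, drings)
  total_diff <- p_area - overlap

  ys <- unlist(lapply(c(prings, drings), `[[`, "y"))
  vmin <- min(ys); vmax <- max(ys)
  m <- max(1L, ceiling((vmax - vmin) / step))
  h <- (vmax - vmin) / m
  stations <- vmin + (seq_len(m) - 0.5) * h
  lat_p <- lat_d <- med_p <- 0
  for (y0 in stations) {
    ip <- polygon_line_intervals(prings, y0)
    id <- polygon_line_intervals(drings, y0)
    if (nrow(ip) == 0L || nrow(id) == 0L) next
    xmax_p <- max(ip[, 2]); xmin_p <- min(ip[, 1])
    xmax_d <- max(id[, 2]); xmin_d <- min(id[, 1])
    lat_p <- lat_p + max(0, xmax_p - xmax_d)
    lat_d <- lat_d + max(0, xmax_d - xmax_p)
    med_p <- med_p + max(0, xmin_d - xmin_p)
  }
  lat_p <- lat_p * h; lat_d <- lat_d * h
  nl <- lat_p + lat_d
  nm <- med_p * h   # uncovered proximal surface medial of the distal face
  hybrid <- plan$hinge_fraction > 0
  list(overlap_area = overlap,
       nonoverlap_total_difference = total_diff,
       nonoverlap_lateral = nl,
       nonoverlap_medial = nm,
       nonoverlap_signed = if (hybrid) -nm else nl,
       overhang_fragment = if (lat_d > lat_p) "distal" else "proximal")
}

#' Simulate one knee under one technique and correction angle
#'
#' Full per-knee pipeline: frame construction, plane planning, cutting,
#' closure and non-overlap measurement, plus the medial gap volume for
#' hybrid hinges.
#'
#' @param mesh a [tibial_mesh()].
#' @param landmarks a [landmark_set()].
#' @param technique one of [cwhto_techniques()].
#' @param theta correction angle in degrees.
#' @param knee_id identifier carried into the result row.
#' @param scan_step AP scanline step (mm) for the non-overlap metrics.
#' @param offsets,ap_halfwidth,kerf passed to [plan_osteotomy()].
#' @param with_nonoverlap compute closure/non-overlap metrics (default
#'   `TRUE`); volumes-only runs are faster for large sweeps.
#' @return one-row tibble (a `SimulationResult` record).
#' @export
simulate_knee <- function(mesh, landmarks, technique, theta,
                          knee_id = NA_character_, scan_step = 0.25,
                          offsets = c(conventional = 10, medial = 15, lateral = 35),
                          ap_halfwidth = Inf, kerf = 0,
                          with_nonoverlap = TRUE) {
  frame <- build_frame(landmarks)
  plan <- plan_osteotomy(mesh, frame, technique, theta,
                         offsets = offsets, ap_halfwidth = ap_halfwidth,
                         kerf = kerf)
  ex <- execute_plan(mesh, plan, validate = TRUE)
  gap <- medial_gap_volume(mesh, plan)
  no <- if (with_nonoverlap) {
    compute_nonoverlap(ex$proximal_face, ex$distal_face, plan, step = scan_step)
  } else {
    list(overlap_area = NA_real_, nonoverlap_total_difference = NA_real_,
         nonoverlap_lateral = NA_real_, nonoverlap_medial = NA_real_,
         nonoverlap_signed = NA_real_, overhang_fragment = NA_character_)
  }
  tibble::tibble(
    knee_id = knee_id, technique = technique, theta = theta,
    proximal_area = ex$proximal_face$area,
    distal_area = ex$distal_face$area,
    wedge_volume = ex$volumes[["wedge"]],
    medial_gap_volume = gap,
    overlap_area = no$overlap_area,
    nonoverlap_lateral = no$nonoverlap_lateral,
    nonoverlap_medial = no$nonoverlap_medial,
    nonoverlap_signed = no$nonoverlap_signed,
    nonoverlap_total_difference = no$nonoverlap_total_difference,
    overhang_fragment = no$overhang_fragment,
    conservation_error = ex$volumes[["conservation_error"]])
}
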