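# Anatomical frame construction and osteotomy plane planning.

#' Build the anatomical frame from landmarks
#'
#' Produces a right-handed orthonormal frame: `si_axis` is the joint-plane
#' normal (superior), `ap_axis` the orthogonalized anterior direction and
#' `ml_axis` the medial-to-lateral direction along the plateau edge chord.
#' Orthonormalization order is SI then AP then ML, so the joint line itself
#' is the reference every "distal to the joint line" offset is measured
#' against (perpendicular to the joint plane).
#'
#' @param landmarks a [landmark_set()].
#' @return object of class `tibial_frame` with fields `origin`, `ml_axis`,
#'   `ap_axis`, `si_axis` and `joint_plane` ([plane3()]).
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ml_raw <- landmarks$lateral_plateau_edge - landmarks$medial_plateau_edge
  if (vnorm(ml_raw) < 1e-9)
    stop("frame error: plateau edge landmarks are coincident", call. = FALSE)
  si <- cross3(unitize(ml_raw), landmarks$anterior_direction)
  if (vnorm(si) < 1e-6)
    stop("frame error: degenerate landmarks (ML parallel to AP)", call. = FALSE)
  si <- unitize(si)
  ap <- unitize(landmarks$anterior_direction - sum(landmarks$anterior_direction * si) * si)
  ml <- cross3(ap, si)
  mid <- (landmarks$medial_plateau_edge + landmarks$lateral_plateau_edge) / 2
  structure(list(origin = landmarks$joint_center,
                 ml_axis = ml, ap_axis = ap, si_axis = si,
                 joint_plane = plane3(mid, si)),
            class = "tibial_frame")
}

#' @export
print.tibial_frame <- function(x, ...) {
  cat("<tibial_frame>\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  si_axis: (%.3f, %.3f, %.3f)\n",
              x$si_axis[1], x$si_axis[2], x$si_axis[3]))
  invisible(x)
}

#' Locate a cortex silhouette point at a distal offset
#'
#' Intersects the mesh with the plane parallel to the joint plane at the
#' given perpendicular distal offset and returns the extreme medial or
#' lateral point of the cross-section (restricted to a coronal mid-slab if
#' `ap_halfwidth` is finite), projected onto the coronal mid-plane (AP
#' coordinate zero).
#'
#' @param mesh a [tibial_mesh()].
#' @param frame a [build_frame()] result.
#' @param side `"medial"` or `"lateral"`.
#' @param si_offset distance below the joint line (mm), > 0.
#' @param ap_halfwidth half-width of the coronal slab used for the
#'   silhouette (mm); default `Inf` = full section.
#' @return 3D point (mm) on the section plane with AP coordinate 0.
#' @export
locate_cortex_point <- function(mesh, frame, side = c("medial", "lateral"),
                                si_offset, ap_halfwidth = Inf) {
  side <- match.arg(side)
  if (si_offset <= 0)
    stop("geometry error: si_offset must be positive", call. = FALSE)
  n <- frame$joint_plane$normal
  pl <- plane3(frame$joint_plane$point - si_offset * n, n)
  loops <- mesh_plane_section(mesh, pl)
  pts <- do.call(rbind, loops)
  c0 <- frame$origin - (sum(frame$origin * n) - pl$offset) * n
  rel <- sweep(pts, 2L, c0)
  u <- drop(rel %*% frame$ml_axis)
  v <- drop(rel %*% frame$ap_axis)
  keep <- abs(v) <= ap_halfwidth
  if (!any(keep))
    stop("geometry error: empty cross-section inside the coronal slab", call. = FALSE)
  u_ext <- if (side == "medial") min(u[keep]) else max(u[keep])
  c0 + u_ext * frame$ml_axis
}

#' Available CWHTO techniques
#' @return character vector of the four technique identifiers.
#' @export
cwhto_techniques <- function() {
  c("conventional", "oblique", "hybrid_3_1", "hybrid_2_1")
}

# Hinge position along the proximal cut chord, as a fraction from the
# medial end. "3:1 from the medial cortex" reads lateral:medial = 3:1,
# i.e. the hinge sits 1/4 of the chord from the medial end; this is the
# reading under which the 2:1 hinge removes less bone than the 3:1 hinge
# and the medial gap is ~1/9 of the lateral wedge for 3:1 on uniform
# sections.
hinge_fraction_for <- function(technique) {
  switch(technique,
         conventional = 0,
         oblique = 0,
         hybrid_3_1 = 1 / 4,
         hybrid_2_1 = 1 / 3,
         stop("unknown technique: ", technique, call. = FALSE))
}

#' Construct an osteotomy plan
#'
#' Builds the two cutting planes, hinge point and hinge axis for one
#' technique at one correction angle:
#'
#' * conventional: proximal cut parallel to the joint line, offset
#'   `offsets["conventional"]` (10 mm) distally; hinge at the medial end of
#'   the proximal cut chord (medial cortex).
#' * oblique: proximal cut through the medial cortex point
#'   `offsets["medial"]` (15 mm) and the lateral cortex point
#'   `offsets["lateral"]` (35 mm) below the joint line; hinge at the medial
#'   cortex point.
#' * hybrid_3_1 / hybrid_2_1: same proximal cut as oblique; hinge at 1/4
#'   resp. 1/3 of the chord from its medial end.
#'
#' Both planes contain the AP axis (pure coronal correction). The distal
#' plane is the proximal plane rotated about the AP-directed hinge axis so
#' that it dives distally on the lateral side; the dihedral angle between
#' the planes equals `theta` exactly.
#'
#' @param mesh a [tibial_mesh()].
#' @param frame a [build_frame()] result.
#' @param technique one of [cwhto_techniques()].
#' @param theta correction angle in degrees, 0 < theta < 45.
#' @param offsets named numeric vector of cut offsets below the joint line
#'   (mm): `conventional`, `medial`, `lateral`. The defaults define the
#'   four techniques; equal medial/lateral offsets yield a joint-line
#'   parallel oblique-family cut, useful for analytic validation.
#' @param ap_halfwidth coronal slab half-width for cortex localization.
#' @param kerf saw-blade thickness (mm); 0 in the reference simulation.
#' @return object of class `osteotomy_plan`.
#' @export
plan_osteotomy <- function(mesh, frame, technique, theta,
                           offsets = c(conventional = 10, medial = 15, lateral = 35),
                           ap_halfwidth = Inf, kerf = 0) {
  technique <- match.arg(technique, cwhto_techniques())
  if (!is.finite(theta) || theta <= 0 || theta >= 45)
    stop("parameter error: theta must lie in (0, 45) degrees", call. = FALSE)
  if (kerf < 0) stop("parameter error: kerf must be >= 0", call. = FALSE)
  ap <- frame$ap_axis
  si <- frame$si_axis

  if (technique == "conventional") {
    prox <- plane3(frame$joint_plane$point - offsets[["conventional"]] * si, si)
    p_med <- locate_cortex_point(mesh, frame, "medial",
                                 offsets[["conventional"]], ap_halfwidth)
    p_lat <- locate_cortex_point(mesh, frame, "lateral",
                                 offsets[["conventional"]], ap_halfwidth)
  } else {
    p_med <- locate_cortex_point(mesh, frame, "medial",
                                 offsets[["medial"]], ap_halfwidth)
    p_lat <- locate_cortex_point(mesh, frame, "lateral",
                                 offsets[["lateral"]], ap_halfwidth)
    nrm <- cross3(ap, p_lat - p_med)
    if (sum(nrm * si) < 0) nrm <- -nrm
    prox <- plane3(p_med, nrm)
  }
  chord <- p_lat - p_med
  f <- hinge_fraction_for(technique)
  hinge <- p_med + f * chord
  Rd <- rotation_about_axis(ap, deg2rad(theta))
  distal <- plane3(hinge, drop(Rd %*% prox$normal))
  structure(list(
    technique = technique, theta = theta,
    proximal_plane = prox, distal_plane = distal,
    hinge_point = hinge, hinge_axis = ap, hinge_fraction = f,
    chord_dir = unitize(chord), chord_length = vnorm(chord),
    kerf = kerf, frame = frame,
    landmarks_used = list(medial_cortex = p_med, lateral_cortex = p_lat)
  ), class = "osteotomy_plan")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  cat(sprintf("<osteotomy_plan> %s, theta = %g deg, hinge fraction %.3f\n",
              x$technique, x$theta, x$hinge_fraction))
  cat(sprintf("  hinge at (%.2f, %.2f, %.2f) mm, chord %.1f mm\n",
              x$hinge_point[1], x$hinge_point[2], x$hinge_point[3],
              x$chord_length))
  invisible(x)
}

#' Closure transform of an osteotomy plan
#'
#' The rigid rotation (by `-theta` about the AP hinge axis through the
#' hinge point) that closes the osteotomy gap: it maps the distal cutting
#' plane exactly onto the proximal cutting plane and is an isometry.
#'
#' @param plan an [plan_osteotomy()] result.
#' @return a [rigid_transform()].
#' @export
closure_transform <- function(plan) {
  rigid_transform(rotation_about_axis(plan$hinge_axis, -deg2rad(plan$theta)),
                  plan$hinge_point)
}

#' Serialize / restore an osteotomy plan (JSON)
#'
#' Writes plane point/normal pairs, hinge point/axis, technique and angle
#' for inspection and replay.
#'
#' @param plan an `osteotomy_plan`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    technique = plan$technique, theta = plan$theta,
    proximal_plane = list(point = plan$proximal_plane$point,
                          normal = plan$proximal_plane$normal),
    distal_plane = list(point = plan$distal_plane$point,
                        normal = plan$distal_plane$normal),
    hinge_point = plan$hinge_point, hinge_axis = plan$hinge_axis,
    hinge_fraction = plan$hinge_fraction,
    chord_dir = plan$chord_dir, chord_length = plan$chord_length,
    kerf = plan$kerf)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
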