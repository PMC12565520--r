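# Slicing, volumes, wedge extraction, closure and non-overlap metrics.

test_that("slicing a cube bisects it with an exact cap", {
  ph <- prism_fixture(1, 1, 1)
  s <- slice_mesh(ph$mesh, plane3(c(0, 0, -0.5), c(0, 0, 1)))
  expect_equal(mesh_volume(s$front), 0.5)
  expect_equal(mesh_volume(s$back), 0.5)
  expect_equal(s$face$area, 1)
  expect_silent(validate_mesh(s$front))
  expect_silent(validate_mesh(s$back))
})

test_that("an oblique slice through the prism has the tilted-rectangle area", {
  ph <- prism_fixture(60, 45, 100)
  z1 <- -15; z2 <- -35
  n <- c(-(z2 - z1), 0, 60)  # plane through (-30, z1) and (30, z2), along y
  s <- slice_mesh(ph$mesh, plane3(c(-30, 0, z1), n))
  expect_equal(s$face$area, 45 * sqrt(60^2 + (z2 - z1)^2), tolerance = 1e-9)
  # volume conservation through an oblique cut
  expect_equal(mesh_volume(s$front) + mesh_volume(s$back), 270000,
               tolerance = 1e-9)
  expect_error(slice_mesh(ph$mesh, plane3(c(0, 0, 50), c(0, 0, 1))),
               "intersect")
})

test_that("mesh volume requires a closed, outward-oriented mesh", {
  ph <- prism_fixture()
  expect_equal(mesh_volume(ph$mesh), 270000)
  open_mesh <- ph$mesh
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_error(mesh_volume(open_mesh), "watertight")
  flipped <- ph$mesh
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_error(mesh_volume(flipped), "orientation")
})

test_that("prism wedge volumes match the closed forms for every technique and angle", {
  ph <- prism_fixture(60, 45, 100)
  fr <- build_frame(ph$landmarks)
  alpha <- atan(20 / 60)  # inclination of the 15/35 mm oblique cut
  for (th in c(12, 15, 18)) {
    thr <- th * pi / 180
    conv <- execute_plan(ph$mesh, plan_osteotomy(ph$mesh, fr, "conventional", th))
    expect_equal(conv$volumes[["wedge"]],
                 prism_wedge_closed_form(60, 45, thr, 0),
                 tolerance = 1e-9)
    for (tech in c("oblique", "hybrid_3_1", "hybrid_2_1")) {
      pl <- plan_osteotomy(ph$mesh, fr, tech, th)
      ex <- execute_plan(ph$mesh, pl)
      w_lat <- (1 - pl$hinge_fraction) * 60
      expect_equal(ex$volumes[["wedge"]],
                   prism_wedge_closed_form(w_lat, 45, thr, alpha),
                   tolerance = 1e-9)
      gap <- medial_gap_volume(ph$mesh, pl)
      expect_equal(gap,
                   prism_gap_closed_form(pl$hinge_fraction * 60, 45, thr, alpha),
                   tolerance = 1e-9)
      expect_lt(ex$volumes[["conservation_error"]], 1e-12)
    }
  }
})

test_that("fragment volumes are conserved and wedges nest with theta on a flared knee", {
  tb <- tibia_fixture()
  fr <- build_frame(tb$landmarks)
  for (tech in cwhto_techniques()) {
    wedges <- vapply(c(6, 12, 15, 18), function(th) {
      ex <- execute_plan(tb$mesh, plan_osteotomy(tb$mesh, fr, tech, th))
      expect_lt(ex$volumes[["conservation_error"]], 1e-6)
      expect_silent(validate_mesh(ex$proximal_fragment))
      expect_silent(validate_mesh(ex$wedge))
      expect_silent(validate_mesh(ex$distal_fragment))
      ex$volumes[["wedge"]]
    }, numeric(1))
    expect_true(all(diff(wedges) > 0))
  }
})

test_that("closure transform is an isometry mapping the distal onto the proximal plane", {
  tb <- tibia_fixture()
  fr <- build_frame(tb$landmarks)
  pl <- plan_osteotomy(tb$mesh, fr, "hybrid_3_1", 15)
  cl <- closure_transform(pl)
  # distal plane normal maps onto the proximal plane normal
  expect_equal(apply_transform(cl, pl$distal_plane$normal, vector = TRUE),
               pl$proximal_plane$normal, tolerance = 1e-12)
  # forward then inverse is the identity
  pts <- matrix(rnorm(30, sd = 30), ncol = 3)
  back <- apply_transform(invert_transform(cl), apply_transform(cl, pts))
  expect_equal(back, pts, tolerance = 1e-12)
  # isometry: pairwise distances preserved
  d0 <- dist(pts); d1 <- dist(apply_transform(cl, pts))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
  # every transformed distal-face vertex lands on the proximal plane
  ex <- execute_plan(tb$mesh, pl)
  for (r in ex$distal_face$rings) {
    p3 <- chart_unproject_test(ex$distal_face$chart, cbind(r$x, r$y))
    p3 <- apply_transform(cl, p3)
    dev <- abs(p3 %*% pl$proximal_plane$normal - pl$proximal_plane$offset)
    expect_lt(max(dev), 1e-6)
  }
  # transformed distal face keeps its area (isometry on the face)
  uv <- chart_project_test(ex$proximal_face$chart,
                           apply_transform(cl, chart_unproject_test(
                             ex$distal_face$chart,
                             cbind(ex$distal_face$rings[[1]]$x,
                                   ex$distal_face$rings[[1]]$y))))
  shoelace <- function(x, y) {
    n <- length(x); j <- c(n, seq_len(n - 1))
    abs(sum(x[j] * y - x * y[j])) / 2
  }
  expect_equal(shoelace(uv[, 1], uv[, 2]), ex$distal_face$area, tolerance = 1e-9)
})

test_that("identical faces give full overlap and zero non-overlap", {
  ph <- prism_fixture()
  s <- slice_mesh(ph$mesh, plane3(c(0, 0, -20), c(0, 0, 1)))
  fake_plan <- structure(list(theta = 1e-12, hinge_axis = c(0, 1, 0),
                              hinge_point = c(0, 0, -20), hinge_fraction = 0),
                         class = "osteotomy_plan")
  no <- compute_nonoverlap(s$face, s$face, fake_plan)
  expect_equal(no$overlap_area, s$face$area, tolerance = 1e-6)
  expect_equal(no$nonoverlap_total_difference, 0, tolerance = 1e-6)
  expect_equal(no$nonoverlap_lateral, 0, tolerance = 1e-9)
  expect_equal(no$nonoverlap_medial, 0, tolerance = 1e-9)
})

test_that("a medially shifted rectangle yields the exact scanline strip", {
  plane <- plane3(c(0, 0, 0), c(0, 0, 1))
  chart <- list(origin = c(0, 0, 0), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                normal = c(0, 0, 1))
  rect <- function(x0, x1, y0, y1) list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  fp <- cut_face(plane, chart, list(rect(0, 60, -22.5, 22.5)))
  fd <- cut_face(plane, chart, list(rect(-5, 55, -22.5, 22.5)))
  fake_plan <- structure(list(theta = 0, hinge_axis = c(0, 1, 0),
                              hinge_point = c(0, 0, 0), hinge_fraction = 0),
                         class = "osteotomy_plan")
  no <- compute_nonoverlap(fp, fd, fake_plan)
  expect_equal(no$nonoverlap_lateral, 5 * 45, tolerance = 1e-9)
  # the proximal face does not extend medial of the distal face here
  expect_equal(no$nonoverlap_medial, 0, tolerance = 1e-9)
  expect_equal(no$overlap_area, 55 * 45, tolerance = 1e-9)
  expect_equal(no$overhang_fragment, "proximal")
})

test_that("conventional prism closure overhang matches the 1/cos(theta) excess", {
  ph <- prism_fixture(60, 45, 100)
  fr <- build_frame(ph$landmarks)
  for (th in c(12, 18)) {
    pl <- plan_osteotomy(ph$mesh, fr, "conventional", th)
    ex <- execute_plan(ph$mesh, pl)
    no <- compute_nonoverlap(ex$proximal_face, ex$distal_face, pl)
    expect_equal(no$nonoverlap_lateral, 60 * (1 / cos(th * pi / 180) - 1) * 45,
                 tolerance = 1e-6)
    expect_equal(no$overhang_fragment, "distal")
    expect_equal(no$nonoverlap_medial, 0, tolerance = 1e-9)
    expect_equal(no$nonoverlap_signed, no$nonoverlap_lateral)
  }
})

test_that("scanline non-overlap is stable under step refinement (Richardson check)", {
  tb <- tibia_fixture()
  fr <- build_frame(tb$landmarks)
  pl <- plan_osteotomy(tb$mesh, fr, "conventional", 15)
  ex <- execute_plan(tb$mesh, pl)
  a <- compute_nonoverlap(ex$proximal_face, ex$distal_face, pl, step = 0.25)
  b <- compute_nonoverlap(ex$proximal_face, ex$distal_face, pl, step = 0.125)
  expect_equal(a$nonoverlap_lateral, b$nonoverlap_lateral, tolerance = 0.01)
})
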