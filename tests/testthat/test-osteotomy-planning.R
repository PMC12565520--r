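# Frame construction, cortex localization and plane planning.

test_that("frame from prism landmarks is axis-aligned and equivariant", {
  ph <- prism_fixture()
  fr <- build_frame(ph$landmarks)
  expect_equal(fr$ml_axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$ap_axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$si_axis, c(0, 0, 1), tolerance = 1e-12)
  # axes orthonormal
  M <- rbind(fr$ml_axis, fr$ap_axis, fr$si_axis)
  expect_equal(M %*% t(M), diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  R <- rotation_about_axis(c(1, 2, 3), 0.7)
  ph2 <- transform_phantom(ph, R, c(5, -4, 12))
  fr2 <- build_frame(ph2$landmarks)
  expect_equal(fr2$ml_axis, drop(R %*% fr$ml_axis), tolerance = 1e-9)
  expect_equal(fr2$ap_axis, drop(R %*% fr$ap_axis), tolerance = 1e-9)
  expect_equal(fr2$si_axis, drop(R %*% fr$si_axis), tolerance = 1e-9)
})

test_that("degenerate landmarks are rejected", {
  expect_error(landmark_set(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
               "distinct")
  expect_error(landmark_set(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "parallel")
})

test_that("cortex silhouette points hit the prism walls and follow the taper", {
  ph <- prism_fixture(60, 45, 100)
  fr <- build_frame(ph$landmarks)
  lat <- locate_cortex_point(ph$mesh, fr, "lateral", 20)
  med <- locate_cortex_point(ph$mesh, fr, "medial", 20)
  expect_equal(lat, c(30, 0, -20), tolerance = 1e-9)
  expect_equal(med, c(-30, 0, -20), tolerance = 1e-9)

  tb <- tibia_fixture()
  frt <- build_frame(tb$landmarks)
  x35 <- locate_cortex_point(tb$mesh, frt, "lateral", 35)
  x10 <- locate_cortex_point(tb$mesh, frt, "lateral", 10)
  expect_lt(abs(x35[1]), abs(x10[1]))

  expect_error(locate_cortex_point(ph$mesh, fr, "lateral", 500), "intersect")
  expect_error(locate_cortex_point(ph$mesh, fr, "lateral", -3), "positive")
})

test_that("plans satisfy the dihedral, hinge and shared-plane contracts", {
  for (ph in list(prism_fixture(), tibia_fixture())) {
    fr <- build_frame(ph$landmarks)
    planes <- list()
    for (tech in cwhto_techniques()) {
      pl <- plan_osteotomy(ph$mesh, fr, tech, 15)
      # dihedral angle between the planes equals theta
      ang <- atan2(sqrt(sum(cross3_test(pl$proximal_plane$normal,
                                        pl$distal_plane$normal)^2)),
                   sum(pl$proximal_plane$normal * pl$distal_plane$normal))
      expect_equal(ang, 15 * pi / 180, tolerance = 1e-9)
      # hinge on the proximal plane; hinge axis along AP
      d <- sum(pl$proximal_plane$normal * pl$hinge_point) - pl$proximal_plane$offset
      expect_lt(abs(d), 1e-6)
      expect_equal(abs(sum(pl$hinge_axis * fr$ap_axis)), 1, tolerance = 1e-9)
      planes[[tech]] <- pl
    }
    # hinge fractions: exact rationals
    expect_identical(planes$conventional$hinge_fraction, 0)
    expect_identical(planes$oblique$hinge_fraction, 0)
    expect_identical(planes$hybrid_3_1$hinge_fraction, 1 / 4)
    expect_identical(planes$hybrid_2_1$hinge_fraction, 1 / 3)
    # oblique and hybrids share one proximal plane
    for (tech in c("hybrid_3_1", "hybrid_2_1")) {
      expect_equal(planes[[tech]]$proximal_plane$normal,
                   planes$oblique$proximal_plane$normal, tolerance = 1e-9)
      expect_equal(planes[[tech]]$proximal_plane$offset,
                   planes$oblique$proximal_plane$offset, tolerance = 1e-9)
    }
    # distal plane below proximal laterally, above medially for hybrids
    lat_probe <- planes$hybrid_2_1$hinge_point + 10 * fr$ml_axis
    med_probe <- planes$hybrid_2_1$hinge_point - 10 * fr$ml_axis
    z_of <- function(plane, p) sum(plane$normal * p) - plane$offset
    expect_gt(z_of(planes$hybrid_2_1$distal_plane, lat_probe), 0)   # proximal side
    expect_lt(z_of(planes$hybrid_2_1$distal_plane, med_probe), 0)
  }
})

test_that("conventional and hybrid hinge geometry on the prism is exact", {
  ph <- prism_fixture(60, 45, 100)
  fr <- build_frame(ph$landmarks)
  conv <- plan_osteotomy(ph$mesh, fr, "conventional", 12)
  # proximal plane 10 mm distal to the joint surface, hinge at medial cortex
  expect_equal(conv$proximal_plane$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(conv$proximal_plane$offset, -10, tolerance = 1e-9)
  expect_equal(conv$hinge_point, c(-30, 0, -10), tolerance = 1e-9)

  h2 <- plan_osteotomy(ph$mesh, fr, "hybrid_2_1", 12)
  # hinge at 1/3 of the chord from the medial end: x = -30 + 60/3 = -10
  expect_equal(h2$hinge_point[1], -10, tolerance = 1e-9)

  expect_error(plan_osteotomy(ph$mesh, fr, "conventional", 0), "theta")
  expect_error(plan_osteotomy(ph$mesh, fr, "conventional", 45), "theta")
  expect_error(plan_osteotomy(ph$mesh, fr, "nope", 12), "'arg'")
})

test_that("plans are equivariant under rigid transformation", {
  ph <- tibia_fixture()
  R <- rotation_about_axis(c(2, -1, 1), 1.1)
  shift <- c(-7, 3, 20)
  ph2 <- transform_phantom(ph, R, shift)
  for (tech in c("conventional", "hybrid_3_1")) {
    r1 <- simulate_knee(ph$mesh, ph$landmarks, tech, 15, with_nonoverlap = TRUE)
    r2 <- simulate_knee(ph2$mesh, ph2$landmarks, tech, 15, with_nonoverlap = TRUE)
    for (col in c("proximal_area", "distal_area", "wedge_volume",
                  "medial_gap_volume", "nonoverlap_signed", "overlap_area")) {
      expect_equal(r2[[col]], r1[[col]], tolerance = 1e-6)
    }
  }
})

test_that("plan serialization round-trips through JSON", {
  ph <- prism_fixture()
  fr <- build_frame(ph$landmarks)
  pl <- plan_osteotomy(ph$mesh, fr, "hybrid_3_1", 15)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_plan(pl, tmp)
  obj <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(obj$technique, "hybrid_3_1")
  expect_equal(obj$hinge_fraction, 0.25)
  expect_equal(unlist(obj$hinge_point), pl$hinge_point, ignore_attr = TRUE)
})
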