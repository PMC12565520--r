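# Shared fixtures and independent oracles for the test suite.

# Analytic prism fixture (60 x 45 x 100 mm box with plateau at z = 0).
prism_fixture <- function(width = 60, depth = 45, height = 100) {
  generate_prism_phantom(width, depth, height)
}

# Small flared phantom for fast full-pipeline tests.
tibia_fixture <- function(mpta = 82.1, plateau_width = 70.8, seed = 7) {
  p <- phantom_params(plateau_width = plateau_width, mpta = mpta)
  generate_parametric_tibia(p, seed = seed, n_segments = 32, ring_spacing = 3.5)
}

# Coarse cohort used by batch tests (resolution chosen for speed; the
# geometry invariants are resolution-independent).
cohort_fixture <- function(n = 11, seed = 1) {
  generate_cohort(n, seed = seed, n_segments = 32, ring_spacing = 3.5)
}

# Apply one rigid transform to a phantom (mesh + landmarks) for
# equivariance tests.
transform_phantom <- function(ph, R, shift) {
  v2 <- sweep(ph$mesh$vertices %*% t(R), 2, shift, `+`)
  mesh2 <- tibial_mesh(v2, ph$mesh$faces, validate = FALSE)
  lm2 <- landmark_set(
    drop(R %*% ph$landmarks$medial_plateau_edge) + shift,
    drop(R %*% ph$landmarks$lateral_plateau_edge) + shift,
    drop(R %*% ph$landmarks$joint_center) + shift,
    drop(R %*% ph$landmarks$anterior_direction))
  list(mesh = mesh2, landmarks = lm2)
}

# --- independent statistics oracles (enumeration, no stats:: shortcuts) ---

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments;
# two-sided rule min(1, 2 * min(P(U <= u), P(U >= u))).
mwu_brute_force <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(r), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exact two-sided Fisher p by hypergeometric enumeration: sum the
# probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed table's.
fisher_brute_force <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form prism wedge volume for a cut of coronal inclination alpha
# (radians), horizontal lateral arm w_lat (mm), depth d (mm), correction
# theta (radians): the dihedral region between the cut plane and its
# rotation, bounded by the vertical lateral cortex.
prism_wedge_closed_form <- function(w_lat, d, theta, alpha = 0) {
  0.5 * w_lat^2 * (tan(alpha + theta) - tan(alpha)) * d
}

# Mirror form for the medial gap (opening rotation).
prism_gap_closed_form <- function(w_med, d, theta, alpha = 0) {
  0.5 * w_med^2 * (tan(alpha) - tan(alpha - theta)) * d
}

# 3D cross product and chart mapping helpers used by several test files.
cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
chart_unproject_test <- function(chart, uv) {
  sweep(outer(uv[, 1], chart$e1) + outer(uv[, 2], chart$e2), 2, chart$origin, `+`)
}
chart_project_test <- function(chart, pts) {
  rel <- sweep(pts, 2, chart$origin)
  cbind(rel %*% chart$e1, rel %*% chart$e2)
}
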