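# Parametric proximal-tibia phantoms and synthetic cohorts.
#
# The phantom is a two-segment tapered solid: a flared metaphysis whose
# medial-lateral width shrinks from the plateau width to the shaft width
# over the flare length (smoothstep taper), above a constant-width shaft.
# Varus alignment is modeled as a tilt of the joint-line plane relative to
# the shaft axis (the medial proximal tibial angle, MPTA); only the
# joint-line orientation enters the osteotomy constructions, so no curved
# shaft is modeled. Coordinate convention: right-handed, +x medial->lateral,
# +y anterior, +z superior, origin at the joint center, mm everywhere.

#' Phantom shape parameters
#'
#' @param plateau_width medial-to-lateral extent at the joint line (mm).
#' @param plateau_depth anterior-to-posterior extent at the joint line (mm).
#' @param shaft_width ML width of the shaft below the flare (mm).
#' @param flare_length superior-inferior distance over which the width
#'   tapers from `plateau_width` to `shaft_width` (mm).
#' @param model_height total model height (mm); must exceed `flare_length`.
#' @param mpta medial proximal tibial angle (degrees): coronal tilt of the
#'   joint-line plane against the shaft axis; 90 = square, < 90 = varus
#'   (medial plateau edge more distal).
#' @param cross_section `"ellipse"` (anatomic default) or `"rectangle"`.
#' @return validated parameter list of class `phantom_params`.
#' @export
phantom_params <- function(plateau_width = 70.8,
                           plateau_depth = 0.72 * plateau_width,
                           shaft_width = 0.6 * plateau_width,
                           flare_length = 40,
                           model_height = 110,
                           mpta = 82.1,
                           cross_section = c("ellipse", "rectangle")) {
  cross_section <- match.arg(cross_section)
  p <- list(plateau_width = plateau_width, plateau_depth = plateau_depth,
            shaft_width = shaft_width, flare_length = flare_length,
            model_height = model_height, mpta = mpta,
            cross_section = cross_section)
  with(p, {
    if (!(plateau_width >= shaft_width && shaft_width > 0))
      stop("parameter error: need plateau_width >= shaft_width > 0", call. = FALSE)
    if (plateau_depth <= 0) stop("parameter error: plateau_depth <= 0", call. = FALSE)
    if (flare_length <= 0) stop("parameter error: flare_length <= 0", call. = FALSE)
    if (model_height <= flare_length)
      stop("parameter error: model_height must exceed flare_length", call. = FALSE)
    if (mpta < 70 || mpta > 95)
      stop("parameter error: mpta outside [70, 95] degrees", call. = FALSE)
  })
  structure(p, class = "phantom_params")
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Rectangular prism phantom (analytic fixture)
#'
#' An axis-aligned box of width W (ML), depth D (AP) and height H with the
#' joint surface at z = 0. Its cut metrics have closed forms, making it the
#' oracle fixture for the geometry engine: a conventional closing wedge at
#' angle theta has volume W^2 D tan(theta) / 2.
#'
#' @param width,depth,height box dimensions in mm (all > 0).
#' @return list with `mesh` ([tibial_mesh()]) and `landmarks`
#'   ([landmark_set()]); landmarks sit at the top-face medial/lateral
#'   mid-edge points.
#' @export
generate_prism_phantom <- function(width = 60, depth = 45, height = 100) {
  if (width <= 0 || depth <= 0 || height <= 0)
    stop("parameter error: prism dimensions must be positive", call. = FALSE)
  a <- width / 2; b <- depth / 2
  v <- rbind(
    c(-a, -b, -height), c(a, -b, -height), c(a, b, -height), c(-a, b, -height),
    c(-a, -b, 0), c(a, -b, 0), c(a, b, 0), c(-a, b, 0))
  f <- rbind(
    c(1, 2, 3), c(1, 3, 4),          # bottom (z = -H), outward -z
    c(5, 7, 6), c(5, 8, 7),          # top (z = 0), outward +z
    c(1, 6, 2), c(1, 5, 6),          # y = -b
    c(2, 7, 3), c(2, 6, 7),          # x = +a
    c(3, 8, 4), c(3, 7, 8),          # y = +b
    c(4, 5, 1), c(4, 8, 5))          # x = -a
  # ensure outward orientation
  mesh <- tibial_mesh(v, f, validate = FALSE)
  if (mesh_volume_signed(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  validate_mesh(mesh)
  lm <- landmark_set(medial_plateau_edge = c(-a, 0, 0),
                     lateral_plateau_edge = c(a, 0, 0),
                     joint_center = c(0, 0, 0),
                     anterior_direction = c(0, 1, 0))
  list(mesh = mesh, landmarks = lm)
}

#' Parametric flared proximal-tibia phantom
#'
#' Stacked elliptical (or rectangular) cross-sections whose ML width
#' interpolates monotonically from the plateau width to the shaft width
#' over the flare length; the AP depth scales proportionally. The joint
#' line is tilted in the coronal plane to realize the requested MPTA, with
#' the tilt blended out over the flare so the shaft stays axis-aligned.
#' Deterministic given `(params, seed)`.
#'
#' @param params a [phantom_params()].
#' @param seed integer seed for the optional surface irregularity.
#' @param n_segments vertices per cross-section ring (multiple of 4).
#' @param ring_spacing SI distance between rings (mm).
#' @param noise_sd SD (mm) of smooth radial surface irregularity; 0
#'   (default) gives the ideal analytic surface.
#' @return list with `mesh`, `landmarks` and `params`.
#' @export
generate_parametric_tibia <- function(params, seed = 0L, n_segments = 48L,
                                      ring_spacing = 2.5, noise_sd = 0) {
  stopifnot(inherits(params, "phantom_params"))
  if (n_segments %% 4L != 0L || n_segments < 8L)
    stop("n_segments must be a multiple of 4, >= 8", call. = FALSE)
  W <- params$plateau_width; D <- params$plateau_depth
  H <- params$model_height; FL <- params$flare_length
  beta <- deg2rad(90 - params$mpta)
  nr <- max(ceiling(H / ring_spacing), 8L) + 1L
  depth_t <- seq(0, H, length.out = nr)          # distance below joint line
  half_w <- (W - smoothstep(depth_t / FL) * (W - params$shaft_width)) / 2
  half_d <- D / W * 2 * half_w / 2               # depth scales with width
  blend <- 1 - smoothstep(depth_t / FL)          # joint-line tilt decays over flare

  ang <- 2 * pi * (seq_len(n_segments) - 1L) / n_segments
  cx <- cos(ang); sy <- sin(ang)
  if (params$cross_section == "rectangle") {
    # map the circle parameterization onto the unit square boundary
    m <- pmax(abs(cx), abs(sy))
    cx <- cx / m; sy <- sy / m
  }
  noise <- matrix(0, nrow = nr, ncol = n_segments)
  if (noise_sd > 0) {
    noise <- with_seed(seed, {
      amp <- stats::rnorm(3L, 0, noise_sd)
      ph <- stats::runif(3L, 0, 2 * pi)
      n0 <- outer(rep(1, nr), amp[1] * cos(2 * ang + ph[1])) +
        outer(sin(2 * pi * depth_t / H + ph[2]), amp[2] * cos(3 * ang)) +
        outer(cos(2 * pi * depth_t / H + ph[3]), amp[3] * sin(ang))
      n0
    })
  }

  verts <- matrix(0, nrow = nr * n_segments + 2L, ncol = 3L)
  for (i in seq_len(nr)) {
    r_ml <- half_w[i] + noise[i, ]
    r_ap <- half_d[i] + noise[i, ]
    x <- r_ml * cx
    y <- r_ap * sy
    z <- -depth_t[i] + blend[i] * x * tan(beta)
    verts[(i - 1L) * n_segments + seq_len(n_segments), ] <- cbind(x, y, z)
  }
  top_c <- nr * n_segments + 1L
  bot_c <- nr * n_segments + 2L
  verts[top_c, ] <- c(0, 0, 0)
  verts[bot_c, ] <- c(0, 0, -H)

  faces <- vector("list", nr + 1L)
  for (i in seq_len(nr - 1L)) {
    a <- (i - 1L) * n_segments + seq_len(n_segments)
    b <- c(a[-1L], a[1L])
    c_ <- a + n_segments
    d_ <- b + n_segments
    faces[[i]] <- rbind(cbind(a, b, d_), cbind(a, d_, c_))
  }
  top <- seq_len(n_segments); topn <- c(top[-1L], top[1L])
  faces[[nr]] <- cbind(topn, top, top_c)
  bot <- (nr - 1L) * n_segments + seq_len(n_segments)
  botn <- c(bot[-1L], bot[1L])
  faces[[nr + 1L]] <- cbind(bot, botn, bot_c)
  mesh <- tibial_mesh(verts, do.call(rbind, faces), validate = FALSE)
  if (mesh_volume_signed(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  validate_mesh(mesh)

  i_lat <- 1L                                 # angle 0 -> +x (lateral)
  i_med <- n_segments / 2L + 1L               # angle pi -> -x (medial)
  lm <- landmark_set(medial_plateau_edge = verts[i_med, ],
                     lateral_plateau_edge = verts[i_lat, ],
                     joint_center = c(0, 0, 0),
                     anterior_direction = c(0, 1, 0))
  list(mesh = mesh, landmarks = lm, params = params)
}

# Evaluate code with a temporarily-seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- cohort generation -------------------------------------------------

#' Cohort sampling configuration
#'
#' Truncated-normal distributions for the per-knee anatomical metadata.
#' Defaults emulate a published CT cohort of 11 varus knees: proximal
#' tibia width 70.8 +/- 6.2 mm (60.4-80.7), MPTA mean 82.1 deg
#' (75.9-87.7), JLCA mean 4.4 deg (0.1-10.1), HKA mean 10.5 deg
#' (5.1-16.5), age 58 years (51-66), 5 male / 6 female knees. Standard
#' deviations not published alongside a mean (range) are back-computed
#' from the printed range (range approximately 3.2 sigma at n = 11).
#'
#' @param width,mpta,jlca,hka,age each `c(mean, sd, lower, upper)`.
#' @param p_male probability a knee is from a male patient.
#' @param shaft_ratio shaft width as a fraction of plateau width.
#' @param depth_ratio plateau AP depth as a fraction of ML width.
#' @param flare_length,model_height phantom dimensions (mm).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(width = c(70.8, 6.2, 60.4, 80.7),
                          mpta = c(82.1, 3.3, 75.9, 87.7),
                          jlca = c(4.4, 2.9, 0.1, 10.1),
                          hka = c(10.5, 3.4, 5.1, 16.5),
                          age = c(58, 4.7, 51, 66),
                          p_male = 5 / 11,
                          shaft_ratio = 0.6,
                          depth_ratio = 0.72,
                          flare_length = 40,
                          model_height = 110) {
  cfg <- list(width = width, mpta = mpta, jlca = jlca, hka = hka, age = age,
              p_male = p_male, shaft_ratio = shaft_ratio,
              depth_ratio = depth_ratio, flare_length = flare_length,
              model_height = model_height)
  for (nm in c("width", "mpta", "jlca", "hka", "age")) {
    v <- cfg[[nm]]
    if (length(v) != 4L || v[2] <= 0 || v[3] >= v[4])
      stop("parameter error: ", nm, " must be c(mean, sd > 0, lower < upper)",
           call. = FALSE)
  }
  if (p_male < 0 || p_male > 1)
    stop("parameter error: p_male must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Inverse-CDF truncated normal draws (exact, loop-free).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Generate a synthetic knee cohort
#'
#' Draws per-knee anatomical records from the configured truncated-normal
#' distributions and builds one flared phantom per knee from its width and
#' MPTA. Bit-reproducible for a fixed seed.
#'
#' @param n number of knees (default 11).
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @param n_segments,ring_spacing mesh resolution, see
#'   [generate_parametric_tibia()].
#' @return list of knees, each `list(record, mesh, landmarks)`; `record`
#'   is a one-row tibble (knee_id, sex, age, hka, mpta, jlca, tibia_width).
#' @export
generate_cohort <- function(n = 11L, config = cohort_config(), seed = 1L,
                            n_segments = 48L, ring_spacing = 2.5) {
  if (n < 1L) stop("parameter error: n must be >= 1", call. = FALSE)
  stopifnot(inherits(config, "cohort_config"))
  recs <- with_seed(seed, {
    tibble::tibble(
      knee_id = sprintf("K%02d", seq_len(n)),
      sex = ifelse(stats::runif(n) < config$p_male, "male", "female"),
      age = round(do.call(rtruncnorm, c(list(n), as.list(config$age)))),
      hka = do.call(rtruncnorm, c(list(n), as.list(config$hka))),
      mpta = do.call(rtruncnorm, c(list(n), as.list(config$mpta))),
      jlca = do.call(rtruncnorm, c(list(n), as.list(config$jlca))),
      tibia_width = do.call(rtruncnorm, c(list(n), as.list(config$width)))
    )
  })
  lapply(seq_len(n), function(i) {
    p <- phantom_params(
      plateau_width = recs$tibia_width[i],
      plateau_depth = config$depth_ratio * recs$tibia_width[i],
      shaft_width = config$shaft_ratio * recs$tibia_width[i],
      flare_length = config$flare_length,
      model_height = config$model_height,
      mpta = recs$mpta[i])
    ph <- generate_parametric_tibia(p, seed = seed + i, n_segments = n_segments,
                                    ring_spacing = ring_spacing)
    list(record = recs[i, ], mesh = ph$mesh, landmarks = ph$landmarks)
  })
}

#' Cohort metadata as a single table
#' @param cohort output of [generate_cohort()].
#' @return tibble with one row per knee.
#' @export
cohort_records <- function(cohort) {
  dplyr::bind_rows(lapply(cohort, `[[`, "record"))
}
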