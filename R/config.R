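# Run configuration and pipeline entry points.

#' Pipeline run configuration
#'
#' Validated configuration for the end-to-end pipeline. Defaults encode
#' the reference simulation protocol: all four techniques, correction
#' angles 12, 15 and 18 degrees, zero saw kerf, a synthetic cohort of 11
#' knees.
#'
#' @param n_knees synthetic cohort size (ignored when `cohort_dir` given).
#' @param seed integer RNG seed for cohort generation.
#' @param techniques subset of [cwhto_techniques()].
#' @param thetas correction angles (degrees), each in (0, 45).
#' @param kerf saw-blade thickness in mm, >= 0.
#' @param scan_step AP scanline step in mm, > 0.
#' @param offsets named cut offsets (mm): `conventional`, `medial`,
#'   `lateral`.
#' @param cohort a [cohort_config()].
#' @param cohort_dir optional directory of `<id>.stl` + `<id>_landmarks.json`
#'   pairs to load instead of generating phantoms.
#' @param stat_test test used for subgroup comparisons
#'   (see [compare_groups()]).
#' @param mpta_threshold,jlca_threshold subgroup thresholds (degrees).
#' @param output_dir directory for reports and records.
#' @return validated list of class `cwhto_config`.
#' @export
cwhto_config <- function(n_knees = 11L, seed = 1L,
                         techniques = cwhto_techniques(),
                         thetas = c(12, 15, 18), kerf = 0,
                         scan_step = 0.25,
                         offsets = c(conventional = 10, medial = 15, lateral = 35),
                         cohort = cohort_config(), cohort_dir = NULL,
                         stat_test = "mann_whitney",
                         mpta_threshold = 83, jlca_threshold = 7,
                         output_dir = "cwhto_output") {
  if (any(!is.finite(thetas)) || any(thetas <= 0) || any(thetas >= 45))
    stop("config error: thetas must lie in (0, 45) degrees [thetas]", call. = FALSE)
  if (kerf < 0) stop("config error: kerf must be >= 0 [kerf]", call. = FALSE)
  if (scan_step <= 0) stop("config error: scan_step must be > 0 [scan_step]", call. = FALSE)
  if (n_knees < 1L) stop("config error: n_knees must be >= 1 [n_knees]", call. = FALSE)
  if (!all(c("conventional", "medial", "lateral") %in% names(offsets)))
    stop("config error: offsets needs conventional/medial/lateral [offsets]",
         call. = FALSE)
  techniques <- match.arg(techniques, cwhto_techniques(), several.ok = TRUE)
  structure(list(n_knees = as.integer(n_knees), seed = as.integer(seed),
                 techniques = techniques, thetas = thetas, kerf = kerf,
                 scan_step = scan_step, offsets = offsets, cohort = cohort,
                 cohort_dir = cohort_dir, stat_test = stat_test,
                 mpta_threshold = mpta_threshold,
                 jlca_threshold = jlca_threshold,
                 output_dir = output_dir),
            class = "cwhto_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys raise a schema error naming the offending field.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a [cwhto_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(cwhto_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config schema error: unknown field(s) [",
         paste(bad, collapse = ", "), "]", call. = FALSE)
  if (!is.null(raw$offsets)) raw$offsets <- unlist(raw$offsets)
  if (!is.null(raw$cohort)) raw$cohort <- do.call(cohort_config, as.list(raw$cohort))
  do.call(cwhto_config, raw)
}

#' Generate (or load) the cohort for a configuration
#'
#' With a `cohort_dir`, loads STL meshes and landmark JSON pairs;
#' otherwise generates the synthetic cohort. With `write = TRUE` the
#' cohort is written under `output_dir/cohort` as STL + JSON.
#'
#' @param config a [cwhto_config()].
#' @param write write mesh/landmark/record files (default `FALSE`).
#' @return cohort list (see [generate_cohort()]).
#' @export
cwhto_generate <- function(config = cwhto_config(), write = FALSE) {
  stopifnot(inherits(config, "cwhto_config"))
  cohort <- if (!is.null(config$cohort_dir)) {
    load_cohort_dir(config$cohort_dir)
  } else {
    generate_cohort(config$n_knees, config$cohort, seed = config$seed)
  }
  if (write) {
    dir <- file.path(config$output_dir, "cohort")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (knee in cohort) {
      id <- knee$record$knee_id
      write_mesh(knee$mesh, file.path(dir, paste0(id, ".stl")))
      write_landmarks(knee$landmarks,
                      file.path(dir, paste0(id, "_landmarks.json")))
    }
    utils::write.csv(as.data.frame(cohort_records(cohort)),
                     file.path(dir, "records.csv"), row.names = FALSE)
  }
  cohort
}

load_cohort_dir <- function(dir) {
  stls <- list.files(dir, pattern = "\\.stl$", full.names = TRUE)
  if (length(stls) == 0L) stop("no STL files in ", dir, call. = FALSE)
  recs <- NULL
  rc <- file.path(dir, "records.csv")
  if (file.exists(rc)) recs <- utils::read.csv(rc)
  lapply(stls, function(p) {
    id <- sub("\\.stl$", "", basename(p))
    lmp <- file.path(dir, paste0(id, "_landmarks.json"))
    if (!file.exists(lmp))
      stop("missing landmark file for ", id, ": ", lmp, call. = FALSE)
    record <- if (!is.null(recs) && id %in% recs$knee_id) {
      tibble::as_tibble(recs[recs$knee_id == id, , drop = FALSE])
    } else {
      tibble::tibble(knee_id = id)
    }
    list(record = record, mesh = read_mesh(p), landmarks = read_landmarks(lmp))
  })
}

#' Simulate a configured cohort
#'
#' @param config a [cwhto_config()].
#' @param cohort optional pre-generated cohort (default: generated from
#'   the config).
#' @param write write per-simulation JSON records under
#'   `output_dir/records.json` (default `FALSE`).
#' @return results tibble, see [run_cohort()].
#' @export
cwhto_simulate <- function(config = cwhto_config(), cohort = NULL,
                           write = FALSE) {
  stopifnot(inherits(config, "cwhto_config"))
  if (is.null(cohort)) cohort <- cwhto_generate(config)
  results <- run_cohort(cohort, techniques = config$techniques,
                        thetas = config$thetas, scan_step = config$scan_step,
                        offsets = config$offsets, kerf = config$kerf)
  if (write) {
    if (!dir.exists(config$output_dir))
      dir.create(config$output_dir, recursive = TRUE)
    jsonlite::write_json(as.data.frame(results),
                         file.path(config$output_dir, "records.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  results
}

#' Analyze simulation results
#'
#' Summary table plus subgroup comparisons (sex, proximal tibia vara,
#' high JLCA) when the cohort records carry those covariates.
#'
#' @param config a [cwhto_config()].
#' @param results results tibble from [cwhto_simulate()].
#' @param records knee records ([cohort_records()]); `NULL` skips the
#'   subgroup comparisons.
#' @param write write `summary.csv` / `report.json` under `output_dir`.
#' @return list with `summary` and `comparisons`.
#' @export
cwhto_analyze <- function(config, results, records = NULL, write = FALSE) {
  stopifnot(inherits(config, "cwhto_config"))
  summary <- summarize_results(results)
  comparisons <- tibble::tibble()
  if (!is.null(records) && all(c("sex", "mpta", "jlca") %in% names(records))) {
    comparisons <- dplyr::bind_rows(lapply(
      c("sex", "mpta_vara", "high_jlca"),
      function(cr) suppressWarnings(
        compare_subgroups(results, records, cr, test = config$stat_test,
                          mpta_threshold = config$mpta_threshold,
                          jlca_threshold = config$jlca_threshold))))
  }
  if (write) write_report(summary, comparisons, config$output_dir)
  list(summary = summary, comparisons = comparisons)
}

#' Run the full pipeline
#'
#' Generate, simulate, analyze; deterministic for a fixed configuration
#' and seed.
#'
#' @param config a [cwhto_config()].
#' @param write write cohort files, records and reports (default `TRUE`).
#' @return list with `cohort`, `records`, `results`, `summary`,
#'   `comparisons`.
#' @export
cwhto_run_all <- function(config = cwhto_config(), write = TRUE) {
  cohort <- cwhto_generate(config, write = write)
  records <- cohort_records(cohort)
  results <- cwhto_simulate(config, cohort = cohort, write = write)
  an <- cwhto_analyze(config, results,
                      records = if (all(c("sex", "mpta", "jlca") %in%
                                        names(records))) records else NULL,
                      write = write)
  list(cohort = cohort, records = records, results = results,
       summary = an$summary, comparisons = an$comparisons)
}

#' Published reference summary table
#'
#' Mean +/- SD osteotomy metrics of the clinical CT cohort (11 varus
#' knees) that the synthetic cohort defaults emulate, as printed by the
#' source study: proximal and distal osteotomy areas (mm^2), non-overlap
#' areas (mm^2; medial side for the hybrid hinges) and resected wedge
#' volumes (mm^3) per technique and correction angle. These printed means
#' are the inputs for validating the summary table's percent-ratio
#' semantics; the absolute values depend on the patients' CT anatomy and
#' are not reproduction targets for the phantoms.
#'
#' @return tibble: technique, theta, metric, mean, sd, side.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "reference_summary.csv", package = "cwhto")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
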