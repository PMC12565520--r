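# Batch simulation over a cohort and Table-style summaries / comparisons.

#' Run all simulations for a cohort
#'
#' Simulates every knee under every technique x correction angle cell.
#' Per-cell failures are recorded in the `status` column without aborting
#' the batch; rows are ordered knee, then technique, then angle.
#'
#' @param cohort list of knees from [generate_cohort()] (each element
#'   `list(record, mesh, landmarks)`).
#' @param techniques character vector, subset of [cwhto_techniques()].
#' @param thetas correction angles in degrees (default `c(12, 15, 18)`).
#' @param scan_step,offsets,kerf passed to [simulate_knee()].
#' @param with_nonoverlap compute closure/non-overlap metrics (default
#'   `TRUE`); `FALSE` runs volumes only, roughly twice as fast.
#' @return tibble of simulation results, one row per knee x technique x
#'   angle, with a `status` column (`"ok"` or the error message).
#' @export
run_cohort <- function(cohort, techniques = cwhto_techniques(),
                       thetas = c(12, 15, 18), scan_step = 0.25,
                       offsets = c(conventional = 10, medial = 15, lateral = 35),
                       kerf = 0, with_nonoverlap = TRUE) {
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  techniques <- match.arg(techniques, cwhto_techniques(), several.ok = TRUE)
  rows <- list()
  for (knee in cohort) {
    kid <- if (!is.null(knee$record)) knee$record$knee_id else NA_character_
    for (tech in techniques) {
      for (th in thetas) {
        row <- tryCatch({
          r <- simulate_knee(knee$mesh, knee$landmarks, tech, th,
                             knee_id = kid, scan_step = scan_step,
                             offsets = offsets, kerf = kerf,
                             with_nonoverlap = with_nonoverlap)
          r$status <- "ok"
          r
        }, error = function(e) {
          tibble::tibble(knee_id = kid, technique = tech, theta = th,
                         proximal_area = NA_real_, distal_area = NA_real_,
                         wedge_volume = NA_real_, medial_gap_volume = NA_real_,
                         overlap_area = NA_real_,
                         nonoverlap_lateral = NA_real_,
                         nonoverlap_medial = NA_real_,
                         nonoverlap_signed = NA_real_,
                         nonoverlap_total_difference = NA_real_,
                         overhang_fragment = NA_character_,
                         conservation_error = NA_real_,
                         status = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (all(out$status != "ok"))
    stop("batch error: every simulation cell failed", call. = FALSE)
  out
}

#' Summarize simulation results into a technique x angle table
#'
#' Cohort means and sample standard deviations (n-1 denominator) per
#' technique and correction angle for each metric, plus the two percent
#' ratios the field reports:
#'
#' * `percent_of_conventional`: ratio of the cell mean to the conventional
#'   technique's mean at the same angle, x 100 (ratio of means, not mean
#'   of ratios), rounded to 1 decimal.
#' * `percent_of_proximal` (non-overlap metric only): ratio of the mean
#'   non-overlap area to that technique's mean proximal osteotomy area
#'   (pooled over angles, since the proximal cut does not depend on the
#'   angle), x 100, rounded to 1 decimal.
#'
#' The non-overlap metric summarized is the magnitude of
#' `nonoverlap_signed` (lateral overhang for medial-cortex hinges, medial
#' gap area for hybrid hinges).
#'
#' @param results tibble from [run_cohort()] (failed cells are dropped).
#' @param metrics metric columns to summarize.
#' @return long-format tibble: technique, theta, metric, n, mean, sd,
#'   percent_of_conventional, percent_of_proximal.
#' @export
summarize_results <- function(results,
                              metrics = c("proximal_area", "distal_area",
                                          "wedge_volume", "medial_gap_volume",
                                          "nonoverlap")) {
  res <- results
  if ("status" %in% names(res)) res <- res[res$status == "ok", , drop = FALSE]
  if (nrow(res) == 0L) stop("no successful simulation rows", call. = FALSE)
  if ("nonoverlap" %in% metrics && !"nonoverlap" %in% names(res))
    res$nonoverlap <- abs(res$nonoverlap_signed)
  metrics <- intersect(metrics, names(res))

  long <- tidyr_pivot(res, metrics)
  smry <- dplyr::summarise(
    dplyr::group_by(long, .data$technique, .data$theta, .data$metric),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value[is.finite(.data$value)]),
    sd = if (sum(is.finite(.data$value)) > 1L)
      stats::sd(.data$value[is.finite(.data$value)]) else NA_real_,
    .groups = "drop")

  conv <- smry[smry$technique == "conventional",
               c("theta", "metric", "mean")]
  names(conv)[names(conv) == "mean"] <- "conv_mean"
  smry <- dplyr::left_join(smry, conv, by = c("theta", "metric"))
  smry$percent_of_conventional <-
    ifelse(is.finite(smry$conv_mean) & smry$conv_mean > 0,
           round(100 * smry$mean / smry$conv_mean, 1), NA_real_)
  smry$conv_mean <- NULL

  # proximal-area reference per technique, pooled over angles
  prox <- smry[smry$metric == "proximal_area", , drop = FALSE]
  prox_ref <- tapply(prox$mean, prox$technique, mean)
  smry$percent_of_proximal <- NA_real_
  is_no <- smry$metric == "nonoverlap"
  if (any(is_no)) {
    ref <- prox_ref[as.character(smry$technique[is_no])]
    smry$percent_of_proximal[is_no] <- round(100 * smry$mean[is_no] / ref, 1)
  }
  tech_order <- intersect(cwhto_techniques(), unique(smry$technique))
  smry$technique <- factor(smry$technique, levels = tech_order)
  dplyr::arrange(smry, .data$metric, .data$theta, .data$technique)
}

# Minimal long-format pivot (avoids a tidyr dependency for one reshape).
tidyr_pivot <- function(res, metrics) {
  parts <- lapply(metrics, function(mname) {
    tibble::tibble(technique = res$technique, theta = res$theta,
                   metric = mname, value = res[[mname]])
  })
  dplyr::bind_rows(parts)
}

#' Two-sample group comparison
#'
#' Thin wrapper over the standard two-sample tests with a uniform result
#' record. For the Mann-Whitney U test the exact distribution is used when
#' both samples are small (min n <= 8) and tie-free, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param sample_a,sample_b numeric vectors (>= 2 values each) for
#'   `student_t` / `welch_t` / `mann_whitney`; for `chi_square` /
#'   `fisher_exact` pass a 2x2 count matrix as `sample_a`.
#' @param test one of `"mann_whitney"`, `"student_t"`, `"welch_t"`,
#'   `"chi_square"`, `"fisher_exact"`.
#' @param group_a,group_b labels carried into the result.
#' @param alpha significance level (default 0.05, strict inequality).
#' @return one-row tibble: group_a, group_b, test, statistic, p_value,
#'   significant.
#' @export
compare_groups <- function(sample_a, sample_b = NULL,
                           test = c("mann_whitney", "student_t", "welch_t",
                                    "chi_square", "fisher_exact"),
                           group_a = "A", group_b = "B", alpha = 0.05) {
  test <- match.arg(test)
  if (test %in% c("chi_square", "fisher_exact")) {
    tab <- as.matrix(sample_a)
    if (!all(dim(tab) == c(2L, 2L)))
      stop("stat error: ", test, " requires a 2x2 count matrix", call. = FALSE)
    ht <- if (test == "chi_square") {
      stats::chisq.test(tab, correct = FALSE)
    } else {
      stats::fisher.test(tab)
    }
    stat <- if (test == "chi_square") unname(ht$statistic) else NA_real_
  } else {
    a <- sample_a[is.finite(sample_a)]
    b <- sample_b[is.finite(sample_b)]
    if (length(a) < 2L || length(b) < 2L)
      stop("stat error: need at least 2 finite values per group", call. = FALSE)
    ht <- switch(test,
      student_t = stats::t.test(a, b, var.equal = TRUE),
      welch_t = stats::t.test(a, b, var.equal = FALSE),
      mann_whitney = {
        ties <- anyDuplicated(c(a, b)) > 0L
        use_exact <- !ties && min(length(a), length(b)) <= 8L
        suppressWarnings(
          stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
      })
    stat <- unname(ht$statistic)
  }
  tibble::tibble(group_a = group_a, group_b = group_b, test = test,
                 statistic = stat, p_value = unname(ht$p.value),
                 significant = ht$p.value < alpha)
}

#' Split a cohort into two subgroups
#'
#' Partition criteria and boundary handling follow the reference cohort's
#' definitions: proximal tibia vara is MPTA <= 83 degrees (boundary value
#' in the vara group); high JLCA is JLCA >= 7 degrees (boundary value in
#' the high group); `sex` splits male vs female.
#'
#' @param records tibble of knee records (see [cohort_records()]).
#' @param criterion `"sex"`, `"mpta_vara"` or `"high_jlca"`.
#' @param mpta_threshold,jlca_threshold configurable thresholds (degrees).
#' @return list with `labels` (the two group names, in order), `group`
#'   (factor over records) and `groups` (named list of record subsets).
#'   An empty subgroup triggers a warning.
#' @export
subgroup_split <- function(records,
                           criterion = c("sex", "mpta_vara", "high_jlca"),
                           mpta_threshold = 83, jlca_threshold = 7) {
  criterion <- match.arg(criterion)
  g <- switch(criterion,
    sex = factor(ifelse(records$sex == "male", "male", "female"),
                 levels = c("male", "female")),
    mpta_vara = factor(ifelse(records$mpta <= mpta_threshold, "vara", "non_vara"),
                       levels = c("vara", "non_vara")),
    high_jlca = factor(ifelse(records$jlca >= jlca_threshold,
                              "high_jlca", "low_jlca"),
                       levels = c("high_jlca", "low_jlca")))
  if (any(table(g) == 0L))
    warning("empty subgroup for criterion '", criterion,
            "'; comparisons will be skipped", call. = FALSE)
  split_recs <- split(records, g)
  list(labels = levels(g), group = g, groups = split_recs)
}

#' Compare simulation metrics between cohort subgroups
#'
#' For each technique and metric, compares the per-knee values (averaged
#' over correction angles) between the two subgroups.
#'
#' @param results tibble from [run_cohort()].
#' @param records knee-record tibble ([cohort_records()]).
#' @param criterion passed to [subgroup_split()].
#' @param metrics metric columns to compare.
#' @param test statistical test, see [compare_groups()].
#' @param ... further arguments to [subgroup_split()].
#' @return tibble of comparison rows (technique, metric + the
#'   [compare_groups()] fields); empty when a subgroup is empty.
#' @export
compare_subgroups <- function(results, records, criterion,
                              metrics = c("proximal_area", "distal_area",
                                          "wedge_volume"),
                              test = "mann_whitney", ...) {
  sg <- subgroup_split(records, criterion, ...)
  if (any(table(sg$group) < 2L)) return(tibble::tibble())
  res <- results[results$status == "ok", , drop = FALSE]
  key <- stats::setNames(as.character(sg$group), records$knee_id)
  res$group <- key[res$knee_id]
  out <- list()
  for (tech in unique(res$technique)) {
    for (mname in intersect(metrics, names(res))) {
      sub <- res[res$technique == tech, c("knee_id", "group", mname)]
      agg <- stats::aggregate(sub[[mname]],
                              by = list(knee_id = sub$knee_id, group = sub$group),
                              FUN = mean)
      a <- agg$x[agg$group == sg$labels[1]]
      b <- agg$x[agg$group == sg$labels[2]]
      if (length(a) < 2L || length(b) < 2L) next
      cmp <- compare_groups(a, b, test = test,
                            group_a = sg$labels[1], group_b = sg$labels[2])
      cmp$technique <- tech
      cmp$metric <- mname
      cmp$criterion <- criterion
      out[[length(out) + 1L]] <- cmp
    }
  }
  dplyr::bind_rows(out)
}

#' Write summary and comparison reports
#'
#' Writes the summary table as CSV (one row per technique x angle x
#' metric) and a JSON report bundling the summary and the group
#' comparisons with their significance flags (p < 0.05, strict).
#'
#' @param summary tibble from [summarize_results()].
#' @param comparisons tibble of comparison rows (may be empty).
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(summary, comparisons, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "summary.csv")
  js <- file.path(dir, "report.json")
  utils::write.csv(as.data.frame(summary), csv, row.names = FALSE)
  jsonlite::write_json(
    list(summary = as.data.frame(summary),
         comparisons = as.data.frame(comparisons)),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(summary_csv = csv, report_json = js))
}
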