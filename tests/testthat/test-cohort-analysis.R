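# Batch simulation, summaries, statistics and subgrouping.

test_that("run_cohort covers every cell, is deterministic, and isolates faults", {
  coh <- cohort_fixture(3, seed = 5)
  res <- run_cohort(coh, thetas = c(12, 15), with_nonoverlap = FALSE)
  expect_equal(nrow(res), 3 * 4 * 2)
  expect_true(all(res$status == "ok"))

  res2 <- run_cohort(cohort_fixture(3, seed = 5), thetas = c(12, 15),
                     with_nonoverlap = FALSE)
  expect_identical(res$wedge_volume, res2$wedge_volume)

  # break one knee's mesh: its cells flag, others still compute
  broken <- coh
  broken[[2]]$mesh$faces <- broken[[2]]$mesh$faces[-1, ]
  res3 <- run_cohort(broken, thetas = 12, with_nonoverlap = FALSE)
  bad <- res3$knee_id == broken[[2]]$record$knee_id
  expect_true(all(res3$status[bad] != "ok"))
  expect_true(all(res3$status[!bad] == "ok"))
})

test_that("summary table reproduces percent ratios from its own means", {
  coh <- cohort_fixture(4, seed = 2)
  res <- run_cohort(coh, thetas = c(12, 15))
  sm <- summarize_results(res)
  expect_true(all(sm$sd >= 0, na.rm = TRUE))
  conv <- sm[sm$technique == "conventional", ]
  # exactly 100 wherever the conventional mean is nonzero (the hybrid-only
  # medial gap metric has a zero conventional reference and reports NA)
  expect_true(all(conv$percent_of_conventional[conv$mean > 0] == 100))
  expect_true(all(is.na(conv$percent_of_conventional[conv$mean == 0])))
  # internal consistency: percents recomputed from the table's own means
  for (i in which(sm$metric == "wedge_volume")) {
    ref <- sm$mean[sm$technique == "conventional" & sm$theta == sm$theta[i] &
                     sm$metric == "wedge_volume"]
    expect_equal(sm$percent_of_conventional[i],
                 round(100 * sm$mean[i] / ref, 1))
  }
  # summary invariant to row order
  sm2 <- summarize_results(res[sample(nrow(res)), ])
  expect_equal(sm, sm2)
})

test_that("single-knee cells report missing SD", {
  coh <- cohort_fixture(1, seed = 3)
  res <- run_cohort(coh, thetas = 12, with_nonoverlap = FALSE)
  sm <- summarize_results(res, metrics = "wedge_volume")
  expect_true(all(is.na(sm$sd)))
  expect_true(all(is.finite(sm$mean)))
})

test_that("exact Mann-Whitney p-values match brute-force enumeration", {
  set.seed(11)
  designs <- list(c(2, 2), c(2, 5), c(3, 3), c(4, 4), c(5, 3), c(6, 6),
                  c(8, 4), c(8, 8))
  for (d in designs) {
    a <- round(stats::rnorm(d[1]), 6)
    b <- round(stats::rnorm(d[2], mean = 0.8), 6)
    got <- compare_groups(a, b, test = "mann_whitney")
    expect_equal(got$p_value, mwu_brute_force(a, b), tolerance = 1e-12,
                 info = paste(d, collapse = "x"))
  }
  # well-separated samples: shift detected at the exact tail
  sep <- compare_groups(c(1, 2, 3, 4), c(10, 11, 12, 13), test = "mann_whitney")
  expect_equal(sep$p_value, mwu_brute_force(1:4, 10:13), tolerance = 1e-12)
  expect_equal(sep$p_value, 2 / 70, tolerance = 1e-12)
  # identical samples: no shift
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "mann_whitney")
  expect_equal(same$p_value, 1, tolerance = 1e-9)
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  tabs <- list(matrix(c(5, 0, 0, 6), 2), matrix(c(3, 1, 2, 4), 2),
               matrix(c(2, 6, 5, 1), 2), matrix(c(4, 4, 4, 4), 2))
  for (tb in tabs) {
    got <- compare_groups(tb, test = "fisher_exact")
    expect_equal(got$p_value, fisher_brute_force(tb), tolerance = 1e-9)
  }
  expect_equal(compare_groups(matrix(c(5, 0, 0, 6), 2),
                              test = "fisher_exact")$p_value,
               1 / 462, tolerance = 1e-12)
})

test_that("t tests and chi-square run and enforce sample-size preconditions", {
  a <- c(1.2, 2.3, 3.1, 4.8); b <- c(2.2, 3.1, 4.4, 5.9)
  st <- compare_groups(a, b, test = "student_t")
  expect_equal(st$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value)
  wt <- compare_groups(a, b, test = "welch_t")
  expect_equal(wt$p_value, stats::t.test(a, b)$p.value)
  cs <- compare_groups(matrix(c(20, 10, 12, 22), 2), test = "chi_square")
  expect_equal(cs$p_value,
               stats::chisq.test(matrix(c(20, 10, 12, 22), 2),
                                 correct = FALSE)$p.value)
  expect_error(compare_groups(1, c(1, 2), test = "mann_whitney"), "at least 2")
  expect_error(compare_groups(matrix(1:6, 2), test = "fisher_exact"), "2x2")
})

test_that("subgroup boundaries follow the inclusive threshold definitions", {
  recs <- tibble::tibble(
    knee_id = sprintf("K%02d", 1:6),
    sex = c("male", "male", "female", "female", "female", "male"),
    mpta = c(83.0, 80.0, 85.0, 83.001, 79.0, 84.0),
    jlca = c(7.0, 3.0, 9.0, 6.999, 7.0, 1.0))
  sg <- subgroup_split(recs, "mpta_vara")
  expect_equal(as.character(sg$group),
               c("vara", "vara", "non_vara", "non_vara", "vara", "non_vara"))
  sg2 <- subgroup_split(recs, "high_jlca")
  expect_equal(as.character(sg2$group),
               c("high_jlca", "low_jlca", "high_jlca", "low_jlca",
                 "high_jlca", "low_jlca"))
  sg3 <- subgroup_split(recs, "sex")
  expect_equal(sum(sg3$group == "male"), 3)

  allmale <- recs; allmale$sex <- "male"
  expect_warning(subgroup_split(allmale, "sex"), "empty subgroup")
})

test_that("reports round-trip and flag significance strictly below 0.05", {
  coh <- cohort_fixture(4, seed = 6)
  res <- run_cohort(coh, thetas = 12, with_nonoverlap = FALSE)
  sm <- summarize_results(res, metrics = c("proximal_area", "wedge_volume"))
  cmp <- dplyr::bind_rows(
    compare_groups(c(1, 2, 3, 4), c(10, 11, 12, 13), test = "mann_whitney",
                   group_a = "low", group_b = "high"),
    compare_groups(c(1, 2, 3), c(1, 2, 3), test = "mann_whitney"))
  dir <- withr::local_tempdir()
  files <- write_report(sm, cmp, dir)
  back <- utils::read.csv(files[["summary_csv"]])
  expect_equal(back$mean, sm$mean)
  expect_equal(back$percent_of_conventional, sm$percent_of_conventional)
  rep <- jsonlite::read_json(files[["report_json"]], simplifyVector = TRUE)
  expect_equal(rep$comparisons$significant,
               rep$comparisons$p_value < 0.05)
})

test_that("subgroup comparisons run per technique and metric", {
  coh <- cohort_fixture(6, seed = 9)
  res <- run_cohort(coh, thetas = c(12, 15), with_nonoverlap = FALSE)
  recs <- cohort_records(coh)
  cmp <- compare_subgroups(res, recs, "mpta_vara", metrics = "wedge_volume")
  if (nrow(cmp) > 0) {
    expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
    expect_true(all(cmp$criterion == "mpta_vara"))
  }
  expect_true(nrow(cmp) <= 4)
})
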