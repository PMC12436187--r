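cohort_predictions <- function() {
  profiles <- subset(load_assay_fixture(), variant_id != "WT")
  list(preds = stratify_profiles(profiles), cohort = load_cohort_fixture())
}

test_that("stage-wise sensitivities on the packaged cohort are 6/11, 8/11, 10/11", {
  x <- cohort_predictions()
  s1 <- stagewise_sensitivity(x$preds, x$cohort, "expression")
  expect_identical(c(s1$numerator, s1$denominator), c(6L, 11L))
  expect_equal(s1$percent, 54.5)
  s2 <- stagewise_sensitivity(x$preds, x$cohort, "repression")
  expect_identical(c(s2$numerator, s2$denominator), c(8L, 11L))
  expect_equal(s2$percent, 72.7)
  s3 <- stagewise_sensitivity(x$preds, x$cohort, "migration")
  expect_identical(c(s3$numerator, s3$denominator), c(10L, 11L))
  expect_equal(s3$percent, 90.9)
})

test_that("overall metrics on the packaged cohort match the published cascade", {
  x <- cohort_predictions()
  rep <- overall_metrics(x$preds, x$cohort)
  expect_identical(c(rep$mild_sensitivity$numerator,
                     rep$mild_sensitivity$denominator), c(2L, 2L))
  expect_identical(c(rep$overall_sensitivity$numerator,
                     rep$overall_sensitivity$denominator), c(12L, 13L))
  expect_equal(rep$overall_sensitivity$percent, 92.3)
  expect_identical(c(rep$false_negative_rate$numerator,
                     rep$false_negative_rate$denominator), c(1L, 13L))
  expect_equal(rep$false_negative_rate$percent, 7.69)
  # the single normal-MRI case is called normal and excluded from the
  # overall denominator
  expect_identical(c(rep$normal_correct$numerator,
                     rep$normal_correct$denominator), c(1L, 1L))
  expect_equal(sum(rep$confusion_matrix), 14)
})

test_that("degenerate prediction sets evaluate as expected", {
  x <- cohort_predictions()
  perfect <- data.frame(
    variant_id = x$cohort$variant_id,
    band = ifelse(x$cohort$mri_severity %in% c("moderate", "severe"),
                  "moderate_to_severe", x$cohort$mri_severity),
    stage_fired = "expression", stringsAsFactors = FALSE)
  rep <- overall_metrics(perfect, x$cohort)
  expect_equal(rep$overall_sensitivity$fraction, 1)
  expect_equal(rep$false_negative_rate$fraction, 0)

  all_normal <- data.frame(variant_id = x$cohort$variant_id,
                           band = "normal", stage_fired = "migration",
                           stringsAsFactors = FALSE)
  rep <- overall_metrics(all_normal, x$cohort)
  expect_equal(rep$overall_sensitivity$fraction, 0)
  expect_equal(rep$false_negative_rate$fraction, 1)

  no_positives <- data.frame(variant_id = "P182Q", mri_severity = "normal")
  expect_error(stagewise_sensitivity(all_normal[1, ], no_positives,
                                     "expression"),
               "alignment|empty denominator")
  expect_error(
    stagewise_sensitivity(
      data.frame(variant_id = "P182Q", band = "normal",
                 stage_fired = "migration"),
      no_positives, "expression"),
    "empty denominator")
})

test_that("prediction/truth key mismatches are an alignment error", {
  x <- cohort_predictions()
  expect_error(overall_metrics(x$preds[-1, ], x$cohort), "alignment")
})

test_that("cumulative sensitivity never decreases with deeper stages", {
  set.seed(99)
  stages <- c("expression", "repression", "migration")
  for (i in 1:25) {
    n <- sample(5:20, 1)
    truths <- data.frame(
      variant_id = sprintf("V%02d", 1:n),
      mri_severity = sample(c("normal", "mild", "moderate", "severe"), n,
                            replace = TRUE, prob = c(1, 2, 4, 4)))
    preds <- data.frame(
      variant_id = truths$variant_id,
      band = sample(c("normal", "mild", "moderate", "moderate_to_severe"),
                    n, replace = TRUE),
      stage_fired = sample(stages, n, replace = TRUE))
    if (!any(truths$mri_severity %in% c("moderate", "severe"))) next
    sens <- vapply(stages, function(s) {
      stagewise_sensitivity(preds, truths, s)$fraction
    }, numeric(1))
    expect_true(all(diff(sens) >= 0))
  }
})

test_that("cohort descriptives tally the fixture's columns exactly", {
  cohort <- load_cohort_fixture()
  d <- cohort_descriptives(cohort)
  expect_identical(d$n_cases, 14L)
  expect_identical(as.integer(d$microcephaly[c("yes", "none")]), c(13L, 1L))
  expect_identical(unname(d$coding_effect["missense"]), 8L)
  expect_identical(unname(d$coding_effect["frameshift"]), 3L)
  expect_identical(unname(d$coding_effect["nonsense"]), 3L)
  expect_identical(as.integer(d$mri_severity[c("normal", "mild", "moderate",
                                               "severe")]),
                   c(1L, 2L, 6L, 5L))
  empty <- cohort_descriptives(cohort[0, ])
  expect_identical(empty$n_cases, 0L)
})

test_that("R-squared of a simple linear fit matches the hand OLS oracle", {
  expect_equal(assay_severity_correlation(1:5, 1:5), 1)
  # zero-covariance construction
  expect_equal(assay_severity_correlation(c(-1, 0, 1), c(1, 0, 1)), 0)
  # hand oracle for (1,2),(2,4),(3,5): Sxy = 3, Sxx = 2, Syy = 14/3;
  # R^2 = Sxy^2 / (Sxx * Syy) = 27/28 = 0.9643
  x <- c(1, 2, 3); y <- c(2, 4, 5)
  expect_equal(assay_severity_correlation(x, y), 27 / 28)
  expect_equal(assay_severity_correlation(x, y), 0.964, tolerance = 1e-3)
  expect_error(assay_severity_correlation(c(1, 1, 1), 1:3), "zero variance")
  expect_error(assay_severity_correlation(1:2, 1:2), "at least 3")
})

test_that("the packaged end-to-end analysis reproduces the full cascade", {
  res <- reproduce_cohort_analysis()
  rep <- res$report
  expect_equal(rep$stage1_sensitivity$percent, 54.5)
  expect_equal(rep$stage2_cumulative_sensitivity$percent, 72.7)
  expect_equal(rep$stage3_cumulative_sensitivity$percent, 90.9)
  expect_equal(rep$mild_sensitivity$percent, 100)
  expect_equal(rep$overall_sensitivity$percent, 92.3)
  expect_equal(rep$false_negative_rate$percent, 7.69)
  expect_output(print(rep), "false-negative rate")
})
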