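test_that("relative expression is the mean of batch-matched ratios", {
  w <- make_western(c(1, 1, 1))
  res <- summarize_expression(w$variant, w$wt)
  expect_equal(res$relative_expression, 1)
  expect_equal(res$log2_ratio, 0)
  expect_identical(res$category, "normal")

  # hand oracle: ratios (0.30, 0.25, 0.35) -> mean 0.30, log2 = -1.7370
  w <- make_western(c(0.30, 0.25, 0.35))
  res <- summarize_expression(w$variant, w$wt)
  expect_equal(res$relative_expression, 0.30)
  expect_equal(res$log2_ratio, log2(0.30))
  expect_equal(res$log2_ratio, -1.737, tolerance = 1e-3)
  expect_identical(res$category, "very_low")
})

test_that("expression normalization is invariant to batch-wide rescaling", {
  w <- make_western(c(0.6, 0.7, 0.8))
  base <- summarize_expression(w$variant, w$wt)
  # multiply every raw intensity of batch B2 by a constant
  for (tbl in c("variant", "wt")) {
    sel <- w[[tbl]]$batch_id == "B2"
    w[[tbl]]$band_intensity[sel] <- w[[tbl]]$band_intensity[sel] * 37
    w[[tbl]]$loading_control_intensity[sel] <-
      w[[tbl]]$loading_control_intensity[sel] * 37
  }
  rescaled <- summarize_expression(w$variant, w$wt)
  expect_equal(rescaled$relative_expression, base$relative_expression)
})

test_that("expression replicates without a batch-matched WT are rejected", {
  w <- make_western(c(1, 1, 1))
  w$variant$batch_id[3] <- "B9"
  expect_error(summarize_expression(w$variant, w$wt), "batch-matched")
  w <- make_western(c(1, 1, -1))
  expect_error(summarize_expression(w$variant, w$wt), "strictly positive")
  w <- make_western(c(1, 1))
  expect_error(summarize_expression(w$variant, w$wt), "3 replicates")
})

test_that("expression categories change only at the documented thresholds", {
  grid <- seq(0, 2, by = 0.001)
  cats <- vapply(grid, categorize_expression, character(1))
  expect_identical(rle(cats)$values, c("very_low", "low", "normal", "high"))
  expect_identical(categorize_expression(0.499), "very_low")
  expect_identical(categorize_expression(0.5), "low")
  expect_identical(categorize_expression(0.85), "normal")
  expect_identical(categorize_expression(1.20), "normal")
  expect_identical(categorize_expression(1.2001), "high")
  expect_identical(categorize_expression(1.50), "high")
  expect_error(categorize_expression(-0.1), "non-negative")
})

test_that("repression normalization makes WT exactly 1 and scales variants", {
  wells <- make_wells(list(V1 = c(2, 2, 2)))
  res <- summarize_repression(wells)
  expect_equal(res$rlu_norm[res$effector == "WT"], 1)
  expect_equal(res$rlu_norm[res$effector == "V1"], 2)

  # rescaling all luminescences of one batch leaves rlu_norm unchanged
  scaled <- wells
  sel <- scaled$batch_id == "B2"
  scaled$firefly[sel] <- scaled$firefly[sel] * 11
  scaled$renilla[sel] <- scaled$renilla[sel] * 11
  res2 <- summarize_repression(scaled)
  expect_equal(res2$rlu_norm, res$rlu_norm)
})

test_that("PBS1 inclusion lowers reporter activity under WT FOXG1", {
  wells <- make_wells(list(V1 = c(1, 1, 1)), promoter_only_level = 0.9)
  expect_true(verify_pbs1_repression(wells))
})

test_that("repression status separates LOF, partial LOF and intact", {
  # identical to WT -> intact
  wells <- make_wells(list(V1 = c(1, 1, 1)))
  res <- summarize_repression(wells)
  expect_identical(res$status[res$effector == "V1"], "intact")

  # large separation, small variance -> significant de-repression (LOF)
  wells <- make_wells(list(V1 = c(1.95, 2.0, 2.05),
                           WT = c(0.95, 1.0, 1.05)))
  res <- summarize_repression(wells)
  expect_identical(res$status[res$effector == "V1"], "LOF")
  expect_lt(res$p_vs_wt[res$effector == "V1"], 0.05)

  # 1.3x WT with overlapping replicates: above the partial margin but not
  # significant (one-sided pooled-t check: t = 0.3 / 0.238 on 4 df)
  wells <- make_wells(list(V1 = c(0.9, 1.3, 1.7),
                           WT = c(0.9, 1.0, 1.1)))
  res <- summarize_repression(wells)
  expect_identical(res$status[res$effector == "V1"], "partial_LOF")
  expect_gt(res$p_vs_wt[res$effector == "V1"], 0.05)
})

test_that("missing reference conditions are a configuration error", {
  wells <- make_wells(list(V1 = c(1, 1, 1)))
  expect_error(summarize_repression(wells[wells$construct != "empty_vector", ]),
               "empty_vector")
  no_wt <- wells[!(wells$construct == "promoter_plus_PBS1" &
                     wells$effector == "WT"), ]
  expect_error(summarize_repression(no_wt), "WT reference")
})

test_that("migration fractions average over embryos and band the CP fraction", {
  res <- summarize_migration(make_migration(40, 40, 20))
  expect_equal(res$cp_fraction, 0.20)
  expect_identical(res$category, "cp_mid")
  expect_equal(sum(res$zone_fractions), 1, tolerance = 1e-9)

  expect_identical(summarize_migration(make_migration(60, 35, 5))$category,
                   "cp_low")
  expect_identical(summarize_migration(make_migration(40, 30, 30))$category,
                   "cp_high")
  # band edges: 10% and 25% inclusive in the middle band
  expect_identical(summarize_migration(make_migration(45, 45, 10))$category,
                   "cp_mid")
  expect_identical(summarize_migration(make_migration(40, 35, 25))$category,
                   "cp_mid")
})

test_that("zero-total embryos are excluded with a warning, never counted", {
  counts <- rbind(make_migration(40, 40, 20, 3),
                  data.frame(embryo_id = 4, vz = 0, iz = 0, cp = 0))
  expect_warning(res <- summarize_migration(counts), "zero total")
  expect_identical(res$n_embryos, 3L)
  too_few <- rbind(make_migration(40, 40, 20, 2),
                   data.frame(embryo_id = 3, vz = 0, iz = 0, cp = 0))
  expect_warning(expect_error(summarize_migration(too_few),
                              "insufficient"), "zero total")
})

test_that("cell-fate fractions are per-brain means by default", {
  counts <- data.frame(brain_id = 1:3, marker_positive = c(10, 20, 30),
                       gfp_total = c(100, 100, 100))
  expect_equal(summarize_cellfate(counts), 0.20)
  one <- data.frame(brain_id = 1, marker_positive = 30, gfp_total = 120)
  expect_equal(summarize_cellfate(one), 0.25)
  zero <- data.frame(brain_id = 1, marker_positive = 0, gfp_total = 100)
  expect_equal(summarize_cellfate(zero), 0)
  bad <- data.frame(brain_id = 1, marker_positive = 101, gfp_total = 100)
  expect_error(summarize_cellfate(bad), "gfp_total")
})
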