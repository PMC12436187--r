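test_that("the cascade resolves archetypal profiles at the documented stages", {
  # very low expression fires stage 1 regardless of later assays
  res <- stratify(list(expression_category = "very_low",
                       repression_status = "LOF",
                       migration_category = "cp_high"))
  expect_identical(res$band, "moderate_to_severe")
  expect_identical(res$stage_fired, "expression")

  # lost repression with preserved expression fires stage 2
  res <- stratify(list(expression_category = "normal",
                       repression_status = "LOF",
                       migration_category = "cp_low"))
  expect_identical(res$band, "moderate")
  expect_identical(res$stage_fired, "repression")

  # intact profiles resolve on migration
  res <- stratify(list(expression_category = "normal",
                       repression_status = "intact",
                       migration_category = "cp_low"))
  expect_identical(res$band, "normal")
  expect_identical(res$stage_fired, "migration")

  res <- stratify(list(expression_category = "high",
                       repression_status = "intact",
                       migration_category = "cp_mid"))
  expect_identical(res$band, "mild")

  # the Y307X-like discordant profile is predicted normal
  res <- stratify(list(variant_id = "Y307X", expression_category = "high",
                       repression_status = "intact",
                       migration_category = "cp_low"))
  expect_identical(res$band, "normal")
})

test_that("partial LOF routes past stage 2 to the migration assay", {
  res <- stratify(list(expression_category = "low",
                       repression_status = "partial_LOF",
                       migration_category = "cp_mid"))
  expect_identical(res$band, "mild")
  expect_identical(res$stage_fired, "migration")
})

test_that("every category combination maps to exactly one band", {
  combos <- all_category_combinations()
  bands <- character(nrow(combos))
  stages <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    res <- stratify(combos[i, ])
    expect_true(res$band %in% c("normal", "mild", "moderate",
                                "moderate_to_severe"))
    bands[i] <- res$band
    stages[i] <- res$stage_fired
  }
  expect_identical(length(bands), 36L)
  # stage-3 outcomes are monotone in the CP category
  stage3 <- combos$expression_category != "very_low" &
    combos$repression_status != "LOF"
  rank <- c(cp_low = 1, cp_mid = 2, cp_high = 3)
  band_rank <- c(normal = 1, mild = 2, moderate_to_severe = 3)
  s3 <- data.frame(cp = rank[combos$migration_category[stage3]],
                   band = band_rank[bands[stage3]])
  expect_true(all(s3$band == s3$cp))
})

test_that("incomplete or invalid profiles are rejected", {
  expect_error(stratify(list(expression_category = "normal",
                             repression_status = "LOF")),
               "incomplete profile")
  expect_error(stratify(list(expression_category = "normal",
                             repression_status = "LOF",
                             migration_category = NA)),
               "incomplete profile")
  expect_error(stratify(list(expression_category = "tiny",
                             repression_status = "LOF",
                             migration_category = "cp_low")),
               "invalid expression_category")
})

test_that("the packaged cohort walks the cascade exactly as published", {
  profiles <- subset(load_assay_fixture(), variant_id != "WT")
  preds <- stratify_profiles(profiles)
  stage1 <- preds$variant_id[preds$stage_fired == "expression"]
  expect_setequal(stage1, c("Q86Dfs*34", "Q86Rfs*106", "E136X", "R230H",
                            "G252V", "W255Lfs*156"))
  stage2 <- preds$variant_id[preds$stage_fired == "repression"]
  expect_setequal(stage2, c("N187K", "I194S"))
  expect_identical(sum(preds$stage_fired == "migration"), 6L)

  band_of <- function(v) preds$band[preds$variant_id == v]
  expect_identical(band_of("P182Q"), "normal")
  expect_identical(band_of("F215L"), "mild")
  expect_identical(band_of("G252D"), "mild")
  expect_identical(band_of("L235H"), "moderate_to_severe")
  expect_identical(band_of("Y416X"), "moderate_to_severe")
  expect_identical(band_of("Y307X"), "normal")

  # Y307X is the only mismatch against MRI truth
  cohort <- load_cohort_fixture()
  merged <- merge(preds, cohort[, c("variant_id", "mri_severity")])
  mismatch <- merged$variant_id[!band_matches(merged$mri_severity,
                                              merged$band)]
  expect_identical(mismatch, "Y307X")
})

test_that("PCA of standardized features preserves variance and separates clusters", {
  set.seed(7)
  # two well-separated clusters in the three-assay feature space
  n <- 10
  cluster <- rep(c(0, 1), each = n)
  feats <- data.frame(
    variant_id = sprintf("V%02d", seq_len(2 * n)),
    log2_expression = rnorm(2 * n, ifelse(cluster == 1, -2, 0), 0.2),
    rlu_norm = rnorm(2 * n, ifelse(cluster == 1, 3, 1), 0.2),
    cp_fraction = rnorm(2 * n, ifelse(cluster == 1, 0.4, 0.05), 0.02)
  )
  fit <- pca_profiles(feats)
  ev <- fit$explained_variance
  expect_equal(sum(ev), 1, tolerance = 1e-12)
  expect_true(all(diff(ev) <= 1e-12))
  # trace preservation: eigenvalues sum to the number of features
  expect_equal(sum(fit$sdev^2), 3, tolerance = 1e-12)
  # loadings are orthonormal
  expect_equal(crossprod(fit$loadings), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # brute-force silhouette of PC1 scores against the cluster labels
  pc1 <- fit$scores[, 1]
  sil <- vapply(seq_along(pc1), function(i) {
    d <- abs(pc1 - pc1[i])
    a <- mean(d[cluster == cluster[i] & seq_along(pc1) != i])
    b <- mean(d[cluster != cluster[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)

  # scores reproduce the standardized data under the inverse transform
  std <- scale(as.matrix(feats[, -1]))
  recon <- fit$scores %*% t(fit$loadings)
  expect_equal(unname(recon), unname(std[, ]), tolerance = 1e-10)
})

test_that("PCA input is validated and duplicated rows score identically", {
  feats <- data.frame(variant_id = c("a", "b", "c"),
                      f1 = c(1, 2, 3), f2 = c(1, 1, 1))
  expect_error(pca_profiles(feats), "constant feature 'f2'")
  feats <- data.frame(variant_id = c("a", "b", "c", "a2"),
                      f1 = c(1, 2, 3, 1), f2 = c(4, 2, 1, 4))
  fit <- pca_profiles(feats)
  expect_equal(fit$scores["a", ], fit$scores["a2", ])
})

test_that("categorical profiles yield ordinal codes only with a warning", {
  profiles <- load_assay_fixture()
  expect_warning(codes <- ordinal_profile_features(profiles), "ordinal")
  expect_identical(nrow(codes), 15L)
  expect_true(all(codes$expression_code %in% 0:3))
  fit <- pca_profiles(codes)
  expect_equal(sum(fit$explained_variance), 1)
})
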