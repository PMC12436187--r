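# The three-stage decision cascade mapping a variant's assay profile to a
# predicted band of brain-MRI severity:
#
#   Stage 1 (expression):  very-low expression (<50% of WT) predicts
#                          moderate-to-severe brain anomalies; stop.
#   Stage 2 (repression):  lost COUP-TFI repression (LOF; partial LOF does
#                          NOT fire) predicts moderate anomalies; stop.
#   Stage 3 (migration):   <10% of cells reaching the CP predicts normal
#                          MRI, 10-25% mild, >25% moderate-to-severe.
#
# The cascade is strictly sequential with early exit: a variant resolved at
# an earlier stage is never revisited. Exactly one band is emitted for every
# element of the 4 x 3 x 3 category product.

BAND_LEVELS <- c("normal", "mild", "moderate", "moderate_to_severe")
STAGE_LEVELS <- c("expression", "repression", "migration")

#' Stratify one assay profile into a predicted severity band
#'
#' @param profile A list or one-row data.frame with `expression_category`,
#'   `repression_status`, `migration_category` and optionally `variant_id`.
#' @return An object of class `stratification`: `variant_id`, `band`
#'   (one of `normal`, `mild`, `moderate`, `moderate_to_severe`),
#'   `stage_fired` and `rationale` — a data.frame tracing each stage
#'   consulted, the observed category and the rule applied.
#' @examples
#' stratify(list(variant_id = "N187K", expression_category = "normal",
#'               repression_status = "LOF", migration_category = "cp_low"))
#' @export
stratify <- function(profile) {
  profile <- as.list(profile)
  need <- c("expression_category", "repression_status", "migration_category")
  for (nm in need) {
    v <- profile[[nm]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      stop("incomplete profile: missing ", nm, call. = FALSE)
    }
  }
  expr <- profile$expression_category
  repr <- profile$repression_status
  migr <- profile$migration_category
  if (!expr %in% EXPRESSION_LEVELS) {
    stop("invalid expression_category '", expr, "'", call. = FALSE)
  }
  if (!repr %in% REPRESSION_LEVELS) {
    stop("invalid repression_status '", repr, "'", call. = FALSE)
  }
  if (!migr %in% MIGRATION_LEVELS) {
    stop("invalid migration_category '", migr, "'", call. = FALSE)
  }
  variant_id <- if (is.null(profile$variant_id)) NA_character_
  else profile$variant_id

  rationale <- list()
  if (expr == "very_low") {
    rationale[[1]] <- data.frame(
      stage = "expression", observed = expr,
      rule = "expression < 50% of WT -> moderate_to_severe",
      stringsAsFactors = FALSE)
    band <- "moderate_to_severe"; stage <- "expression"
  } else {
    rationale[[1]] <- data.frame(
      stage = "expression", observed = expr,
      rule = "expression >= 50% of WT -> continue", stringsAsFactors = FALSE)
    if (repr == "LOF") {
      rationale[[2]] <- data.frame(
        stage = "repression", observed = repr,
        rule = "COUP-TFI repression lost -> moderate", stringsAsFactors = FALSE)
      band <- "moderate"; stage <- "repression"
    } else {
      rationale[[2]] <- data.frame(
        stage = "repression", observed = repr,
        rule = "repression intact or partial -> continue",
        stringsAsFactors = FALSE)
      band <- switch(migr, cp_low = "normal", cp_mid = "mild",
                     cp_high = "moderate_to_severe")
      rule <- switch(migr,
                     cp_low = "CP fraction < 10% -> normal",
                     cp_mid = "CP fraction 10-25% -> mild",
                     cp_high = "CP fraction > 25% -> moderate_to_severe")
      rationale[[3]] <- data.frame(stage = "migration", observed = migr,
                                   rule = rule, stringsAsFactors = FALSE)
      stage <- "migration"
    }
  }
  structure(list(variant_id = variant_id, band = band, stage_fired = stage,
                 rationale = do.call(rbind, rationale)),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("<stratification>", if (!is.na(x$variant_id)) x$variant_id else "",
      "-> band:", x$band, "(stage:", x$stage_fired, ")\n")
  print(x$rationale, row.names = FALSE)
  invisible(x)
}

#' Stratify a table of assay profiles
#'
#' @param profiles Data frame as validated by [validate_profiles()]; a `WT`
#'   row, if present, is carried through like any other profile.
#' @return A data.frame with `variant_id`, `band`, `stage_fired` and a
#'   collapsed `rationale` string per variant.
#' @examples
#' stratify_profiles(load_assay_fixture())
#' @export
stratify_profiles <- function(profiles) {
  validate_profiles(profiles)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    res <- stratify(profiles[i, ])
    data.frame(variant_id = res$variant_id, band = res$band,
               stage_fired = res$stage_fired,
               rationale = paste(res$rationale$rule, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PCA of the three-assay numeric feature space
#'
#' Standardizes the per-variant features (log2 relative expression,
#' normalized RLU, CP fraction) to zero mean and unit variance and performs
#' a principal component analysis. On the packaged cohort only categorical
#' calls are available; use [ordinal_profile_features()] to obtain ordinal
#' stand-in codes (with a loud warning) for a qualitative view.
#'
#' @param features Data frame with a `variant_id` column plus at least two
#'   numeric feature columns; at least 3 rows.
#' @return An object of class `pca_profiles`: `scores` (per-variant PC
#'   scores), `loadings` (orthonormal rotation), `explained_variance`
#'   (fractions, non-increasing, summing to 1), `sdev`, `center`, `scale`.
#' @export
pca_profiles <- function(features) {
  if (!is.data.frame(features) || !"variant_id" %in% names(features)) {
    stop("features must be a data.frame with a variant_id column",
         call. = FALSE)
  }
  num_cols <- setdiff(names(features), "variant_id")
  mat <- as.matrix(features[, num_cols, drop = FALSE])
  if (!is.numeric(mat) || ncol(mat) < 2) {
    stop("need at least two numeric feature columns", call. = FALSE)
  }
  if (nrow(mat) < 3) {
    stop("need at least 3 variants with complete numeric features",
         call. = FALSE)
  }
  if (anyNA(mat)) stop("features must be complete (no NA)", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("cannot standardize constant feature '",
         num_cols[which(sds == 0)[1]], "'", call. = FALSE)
  }
  fit <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  scores <- fit$x
  rownames(scores) <- features$variant_id
  structure(list(scores = scores, loadings = fit$rotation,
                 explained_variance = ev / sum(ev), sdev = fit$sdev,
                 center = fit$center, scale = fit$scale),
            class = "pca_profiles")
}

#' Ordinal stand-in feature codes for categorical profiles
#'
#' Maps the categorical assay calls to ordinal integer codes (expression
#' very_low..high -> 0..3; repression intact..LOF -> 0..2; migration
#' cp_low..cp_high -> 0..2) so that a qualitative PCA can be run when no
#' numeric assay layer exists. A warning marks the output as ordinal
#' surrogate data, suitable for qualitative cluster inspection only.
#'
#' @param profiles Profile table as from [load_assay_fixture()].
#' @return Data frame with `variant_id` and ordinal columns
#'   `expression_code`, `repression_code`, `migration_code`.
#' @export
ordinal_profile_features <- function(profiles) {
  validate_profiles(profiles)
  warning("numeric assay layer absent: using ordinal category codes; ",
          "PCA on these is qualitative only", call. = FALSE)
  data.frame(
    variant_id = profiles$variant_id,
    expression_code = match(profiles$expression_category,
                            EXPRESSION_LEVELS) - 1L,
    repression_code = match(profiles$repression_status,
                            REPRESSION_LEVELS) - 1L,
    migration_code = match(profiles$migration_category,
                           MIGRATION_LEVELS) - 1L,
    stringsAsFactors = FALSE
  )
}
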