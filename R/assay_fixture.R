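# Packaged categorical assay outcomes for wild type and the 14 cohort
# variants: expression category (western blot), COUP-TFI repression status
# (dual-luciferase) and cortical-plate migration category (IUE). These are
# the published categorical calls; the underlying per-variant numeric assay
# values were never published, so the numeric layer of this fixture is
# deliberately absent.

#' Load the packaged assay-category profiles
#'
#' Returns one row per construct (wild type plus the 14 cohort variants)
#' with the three categorical assay outcomes used by the stratification
#' cascade.
#'
#' @param path Optional path to an alternative profile TSV.
#' @return A data.frame with columns `variant_id`, `expression_category`,
#'   `repression_status`, `migration_category` (15 rows).
#' @examples
#' profiles <- load_assay_fixture()
#' subset(profiles, variant_id == "N187K")
#' @export
load_assay_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "foxg1_assay_categories.tsv",
                        package = "foxg1strat", mustWork = TRUE)
  }
  profiles <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_profiles(profiles, require_wt = TRUE)
  profiles
}

#' Validate an assay-profile table
#'
#' @param profiles Data frame with columns `variant_id`,
#'   `expression_category`, `repression_status`, `migration_category`.
#' @param require_wt Require a `WT` row.
#' @return The profiles, invisibly; errors on any integrity failure.
#' @export
validate_profiles <- function(profiles, require_wt = FALSE) {
  need <- c("variant_id", "expression_category", "repression_status",
            "migration_category")
  if (!is.data.frame(profiles) || !all(need %in% names(profiles))) {
    stop("profiles must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(profiles$variant_id)) {
    stop("profile integrity failure: duplicated variant_id", call. = FALSE)
  }
  checks <- list(
    expression_category = profiles$expression_category %in% EXPRESSION_LEVELS,
    repression_status = profiles$repression_status %in% REPRESSION_LEVELS,
    migration_category = profiles$migration_category %in% MIGRATION_LEVELS
  )
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]] | is.na(profiles[[nm]]))
    if (length(bad) > 0) {
      stop("profile integrity failure: invalid ", nm, " for variant '",
           profiles$variant_id[bad[1]], "'", call. = FALSE)
    }
  }
  if (require_wt && !"WT" %in% profiles$variant_id) {
    stop("profile integrity failure: WT row missing", call. = FALSE)
  }
  invisible(profiles)
}
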