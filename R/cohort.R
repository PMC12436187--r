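# Packaged cohort: 14 individuals with FOXG1 syndrome, each carrying one
# intragenic heterozygous variant, with demographics, clinical severity
# score (CSS) and brain-MRI severity score (MRI SS) plus their printed band
# labels. Loaded from a versioned TSV with a JSON provenance sidecar.

COHORT_COLUMNS <- c("case_id", "variant_id", "cdna_change", "protein_change",
                    "coding_effect", "protein_position", "domain", "sex",
                    "age_months", "microcephaly", "clinical_severity", "css",
                    "age_at_mri_months", "mri_severity", "mri_ss", "source")

CODING_EFFECTS <- c("missense", "nonsense", "frameshift")
MICROCEPHALY_LEVELS <- c("yes", "none", "unknown")

#' Validate a cohort table
#'
#' Checks column presence, enum membership, score ranges, and internal
#' consistency: every printed severity label must equal the band implied by
#' its score ([classify_css()], [classify_mri()]), and every variant's
#' coding effect and domain must be reproducible from its HGVS protein
#' change and the domain map.
#'
#' @param cohort A cohort data.frame.
#' @param domain_map Domain map used to check the `domain` column.
#' @return The cohort, invisibly, or an error describing the first
#'   inconsistency (never silently repaired).
#' @export
validate_cohort <- function(cohort, domain_map = foxg1_domain_map()) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cohort$case_id) || anyDuplicated(cohort$variant_id)) {
    stop("cohort case_id and variant_id must be unique", call. = FALSE)
  }
  checks <- list(
    coding_effect = cohort$coding_effect %in% CODING_EFFECTS,
    domain = cohort$domain %in% DOMAIN_LEVELS,
    sex = cohort$sex %in% c("M", "F"),
    microcephaly = cohort$microcephaly %in% MICROCEPHALY_LEVELS,
    clinical_severity = cohort$clinical_severity %in% CSS_LEVELS,
    mri_severity = cohort$mri_severity %in% MRI_LEVELS,
    css = cohort$css >= 0 & cohort$css <= 2,
    mri_ss = cohort$mri_ss %in% 0:6
  )
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]])
    if (length(bad) > 0) {
      stop("cohort integrity failure: invalid ", nm, " for case_id ",
           cohort$case_id[bad[1]], call. = FALSE)
    }
  }
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    if (classify_css(row$css) != row$clinical_severity) {
      stop("cohort integrity failure: case ", row$case_id,
           " clinical label '", row$clinical_severity,
           "' does not match classify_css(", row$css, ")", call. = FALSE)
    }
    if (classify_mri(row$mri_ss) != row$mri_severity) {
      stop("cohort integrity failure: case ", row$case_id,
           " MRI label '", row$mri_severity,
           "' does not match classify_mri(", row$mri_ss, ")", call. = FALSE)
    }
    change <- parse_hgvs_protein(row$protein_change)
    if (change$canonical != row$variant_id) {
      stop("cohort integrity failure: case ", row$case_id,
           " protein_change parses to '", change$canonical,
           "', not variant_id '", row$variant_id, "'", call. = FALSE)
    }
    if (classify_coding_effect(change) != row$coding_effect) {
      stop("cohort integrity failure: case ", row$case_id,
           " coding_effect mismatch", call. = FALSE)
    }
    if (change$position != row$protein_position) {
      stop("cohort integrity failure: case ", row$case_id,
           " protein_position mismatch", call. = FALSE)
    }
    if (assign_domain(row$protein_position, domain_map) != row$domain) {
      stop("cohort integrity failure: case ", row$case_id,
           " domain mismatch at position ", row$protein_position,
           call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Load the packaged 14-case cohort
#'
#' Returns the packaged table of 14 individuals with FOXG1 syndrome: HGVS
#' variant, coding effect, protein domain, demographics, microcephaly flag,
#' CSS and MRI SS with their severity bands. The fixture is validated on
#' load; any inconsistency is an error, never silently repaired. Provenance
#' notes (including the R230H/R203H naming discrepancy in the source text)
#' travel in a JSON sidecar exposed as the `"provenance"` attribute.
#'
#' @param path Optional path to an alternative cohort TSV.
#' @return A validated cohort data.frame of 14 rows.
#' @examples
#' cohort <- load_cohort_fixture()
#' table(cohort$mri_severity)
#' @export
load_cohort_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "foxg1_cohort.tsv", package = "foxg1strat",
                        mustWork = TRUE)
  }
  cohort <- read_cohort_tsv(path)
  if (nrow(cohort) != 14) {
    stop("cohort fixture integrity failure: expected 14 records, got ",
         nrow(cohort), call. = FALSE)
  }
  sidecar <- file.path(dirname(path), "foxg1_cohort.json")
  if (file.exists(sidecar)) {
    attr(cohort, "provenance") <- jsonlite::read_json(sidecar)
  }
  cohort
}

#' Read a cohort table from TSV
#'
#' @param path TSV file with the documented cohort columns.
#' @return A validated cohort data.frame.
#' @export
read_cohort_tsv <- function(path) {
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  validate_cohort(cohort)
  cohort
}

#' Write a cohort table to TSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.table(cohort[, COHORT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
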