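# Clinical severity score (CSS) and brain-MRI severity score (MRI SS).
#
# The CSS averages 17 phenotypic items rated 0-2 across four categories:
# somatic growth (4), motor/speech development (4, each may be inapplicable,
# e.g. too young to assess), behavior (3) and neurological features (6).
# The MRI SS sums five imaging items (simplified gyral pattern, basal-ganglia
# hypoplasia, inner-CSF-space enlargement, corpus-callosum anomaly, frontal
# lobe hypoplasia) to a total of 0-6.

CSS_LEVELS <- c("mild", "moderate", "severe")
MRI_LEVELS <- c("normal", "mild", "moderate", "severe")

CSS_ITEM_NAMES <- c(
  paste0("somatic_growth_", 1:4),
  paste0("motor_speech_", 1:4),
  paste0("behavior_", 1:3),
  paste0("neurological_", 1:6)
)

MRI_ITEM_NAMES <- c("simplified_gyral_pattern", "basal_ganglia_hypoplasia",
                    "inner_csf_enlargement", "corpus_callosum_anomaly",
                    "frontal_lobe_hypoplasia")

# per-item maxima; corpus callosum anomalies are graded 0-3, the rest 0-1
MRI_DEFAULT_MAXIMA <- c(simplified_gyral_pattern = 1L,
                        basal_ganglia_hypoplasia = 1L,
                        inner_csf_enlargement = 1L,
                        corpus_callosum_anomaly = 3L,
                        frontal_lobe_hypoplasia = 1L)

#' Build a clinical score sheet
#'
#' @param somatic_growth Integer vector of 4 items in `{0,1,2}`.
#' @param motor_speech Integer vector of 4 items in `{0,1,2}`; individual
#'   items may be `NA` when not applicable (e.g. not yet assessable).
#' @param behavior Integer vector of 3 items in `{0,1,2}`.
#' @param neurological Integer vector of 6 items in `{0,1,2}`.
#' @return A `clinical_score_sheet`: a named integer vector of 17 item slots.
#' @examples
#' s <- clinical_score_sheet(c(2, 1, 1, 2), c(2, 2, NA, NA),
#'                           c(1, 0, 1), c(2, 1, 1, 0, 1, 2))
#' compute_css(s)
#' @export
clinical_score_sheet <- function(somatic_growth, motor_speech, behavior,
                                 neurological) {
  lens <- c(somatic_growth = 4L, motor_speech = 4L, behavior = 3L,
            neurological = 6L)
  parts <- list(somatic_growth = somatic_growth, motor_speech = motor_speech,
                behavior = behavior, neurological = neurological)
  for (nm in names(parts)) {
    if (length(parts[[nm]]) != lens[[nm]]) {
      stop(nm, " must have ", lens[[nm]], " items", call. = FALSE)
    }
    if (nm != "motor_speech" && anyNA(parts[[nm]])) {
      stop("only motor/speech items may be marked not-applicable (NA)",
           call. = FALSE)
    }
  }
  items <- as.numeric(unlist(parts, use.names = FALSE))
  bad <- !is.na(items) & !(items %in% c(0, 1, 2))
  if (any(bad)) {
    stop("score items must be 0, 1 or 2 (offending value: ",
         items[bad][1], ")", call. = FALSE)
  }
  if (all(is.na(items))) {
    stop("at least one item must be applicable", call. = FALSE)
  }
  items <- as.integer(items)
  names(items) <- CSS_ITEM_NAMES
  class(items) <- "clinical_score_sheet"
  items
}

#' Compute the clinical severity score (CSS)
#'
#' The CSS is the mean of the applicable items; not-applicable motor/speech
#' items are excluded from both numerator and denominator. The score is
#' rounded to 2 decimal places (the resolution at which cohort tables print
#' it) before band classification.
#'
#' @param sheet A [clinical_score_sheet()].
#' @return A list with `css` (2-dp value in `[0,2]`), `category`
#'   (`mild`/`moderate`/`severe`) and `n_applicable`.
#' @export
compute_css <- function(sheet) {
  stopifnot(inherits(sheet, "clinical_score_sheet"))
  applicable <- !is.na(sheet)
  if (!any(applicable)) stop("undefined CSS: no applicable items", call. = FALSE)
  css <- round(sum(sheet[applicable]) / sum(applicable), 2)
  list(css = css, category = classify_css(css),
       n_applicable = sum(applicable))
}

#' Classify a CSS value into a severity band
#'
#' Bands: mild 0–0.67, moderate 0.68–1.33, severe 1.34–2, closed at 2-dp
#' resolution; the value is rounded to 2 decimal places before lookup, so
#' the three bands tile the observable score grid.
#'
#' @param css Numeric CSS value in `[0, 2]`.
#' @return `"mild"`, `"moderate"` or `"severe"`.
#' @examples
#' classify_css(1.44)
#' classify_css(0.56)
#' @export
classify_css <- function(css) {
  if (!is.numeric(css) || length(css) != 1 || is.na(css) ||
      css < 0 || css > 2) {
    stop("css must be a single value in [0, 2]", call. = FALSE)
  }
  x <- round(css, 2)
  if (x <= 0.67) "mild" else if (x <= 1.33) "moderate" else "severe"
}

#' Build an MRI score sheet
#'
#' @param simplified_gyral_pattern,basal_ganglia_hypoplasia,inner_csf_enlargement,corpus_callosum_anomaly,frontal_lobe_hypoplasia
#'   Non-negative integer item scores, each within its configured maximum.
#' @param maxima Named integer vector of per-item maxima (each 1 or 3);
#'   default grades corpus-callosum anomalies 0–3 and the other items 0–1.
#' @return An `mri_score_sheet`: named integer vector of the five items.
#' @examples
#' compute_mri_total(mri_score_sheet(1, 0, 1, 0, 1))
#' @export
mri_score_sheet <- function(simplified_gyral_pattern,
                            basal_ganglia_hypoplasia,
                            inner_csf_enlargement,
                            corpus_callosum_anomaly,
                            frontal_lobe_hypoplasia,
                            maxima = MRI_DEFAULT_MAXIMA) {
  items <- c(simplified_gyral_pattern = simplified_gyral_pattern,
             basal_ganglia_hypoplasia = basal_ganglia_hypoplasia,
             inner_csf_enlargement = inner_csf_enlargement,
             corpus_callosum_anomaly = corpus_callosum_anomaly,
             frontal_lobe_hypoplasia = frontal_lobe_hypoplasia)
  if (!all(names(items) %in% names(maxima))) {
    stop("maxima must name all five MRI items", call. = FALSE)
  }
  if (!all(maxima[MRI_ITEM_NAMES] %in% c(1L, 3L))) {
    stop("each per-item maximum must be 1 or 3", call. = FALSE)
  }
  if (anyNA(items) || any(items != as.integer(items)) || any(items < 0)) {
    stop("MRI items must be non-negative integers", call. = FALSE)
  }
  over <- items > maxima[names(items)]
  if (any(over)) {
    stop("MRI item '", names(items)[over][1], "' exceeds its maximum of ",
         maxima[names(items)][over][1], call. = FALSE)
  }
  if (sum(items) > 6) {
    stop("MRI SS total cannot exceed 6 (got ", sum(items), ")", call. = FALSE)
  }
  items <- as.integer(items)
  names(items) <- MRI_ITEM_NAMES
  class(items) <- "mri_score_sheet"
  items
}

#' Compute the MRI severity score total
#'
#' @param sheet An [mri_score_sheet()].
#' @return Integer total in `[0, 6]`.
#' @export
compute_mri_total <- function(sheet) {
  stopifnot(inherits(sheet, "mri_score_sheet"))
  sum(unclass(sheet))
}

#' Classify an MRI SS total into a severity band
#'
#' Bands: normal (0), mild (1–2), moderate (3–4), severe (5–6).
#'
#' @param total Integer MRI SS total in `[0, 6]`.
#' @return `"normal"`, `"mild"`, `"moderate"` or `"severe"`.
#' @examples
#' classify_mri(4)
#' @export
classify_mri <- function(total) {
  if (!is.numeric(total) || length(total) != 1 || is.na(total) ||
      total != as.integer(total) || total < 0 || total > 6) {
    stop("total must be a single integer in [0, 6]", call. = FALSE)
  }
  if (total == 0) "normal"
  else if (total <= 2) "mild"
  else if (total <= 4) "moderate"
  else "severe"
}

#' Read clinical score sheets from CSV and score them
#'
#' Expects one row per case with a `case_id` column and the 17 item columns
#' named as in `clinical_score_sheet()` output
#' (`somatic_growth_1..4`, `motor_speech_1..4`, `behavior_1..3`,
#' `neurological_1..6`); not-applicable motor/speech items are the string
#' `"NA"` or empty.
#'
#' @param path CSV file path.
#' @return A data.frame with `case_id`, `css`, `category`, `n_applicable`.
#' @export
score_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("case_id", CSS_ITEM_NAMES), names(df))
  if (length(missing_cols) > 0) {
    stop("clinical score CSV lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    sheet <- clinical_score_sheet(
      as.numeric(row[paste0("somatic_growth_", 1:4)]),
      as.numeric(row[paste0("motor_speech_", 1:4)]),
      as.numeric(row[paste0("behavior_", 1:3)]),
      as.numeric(row[paste0("neurological_", 1:6)])
    )
    res <- compute_css(sheet)
    data.frame(case_id = row$case_id, css = res$css, category = res$category,
               n_applicable = res$n_applicable, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read MRI score sheets from CSV and score them
#'
#' Expects one row per case with `case_id` plus the five item columns named
#' as in `mri_score_sheet()`.
#'
#' @param path CSV file path.
#' @param maxima Per-item maxima passed to [mri_score_sheet()].
#' @return A data.frame with `case_id`, `total`, `category`.
#' @export
score_mri_csv <- function(path, maxima = MRI_DEFAULT_MAXIMA) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("case_id", MRI_ITEM_NAMES), names(df))
  if (length(missing_cols) > 0) {
    stop("MRI score CSV lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    sheet <- mri_score_sheet(row$simplified_gyral_pattern,
                             row$basal_ganglia_hypoplasia,
                             row$inner_csf_enlargement,
                             row$corpus_callosum_anomaly,
                             row$frontal_lobe_hypoplasia,
                             maxima = maxima)
    total <- compute_mri_total(sheet)
    data.frame(case_id = row$case_id, total = total,
               category = classify_mri(total), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
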