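# Normalization and categorization of the three functional-assay readouts:
#
# * Western-blot protein expression: band intensity / GAPDH loading control,
#   each variant replicate divided by the batch-matched wild-type replicate;
#   categories very_low (<50% of WT, fixed), low, normal, high.
# * Dual-luciferase COUP-TFI repression: per-well RLU = firefly / Renilla,
#   normalized by the empty-vector (pGL4.1) mean, then by wild type.
#   De-repression (elevated normalized RLU) called by one-way ANOVA with
#   one-sided Fisher-LSD vs WT.
# * Migration after in utero electroporation: per-embryo VZ/IZ/CP cell
#   counts -> zone fractions; the cortical-plate (CP) fraction is banded at
#   10% and 25%.
# * Cell-fate marker counts (BRN2+/RORb+ among GFP+) are summarized
#   descriptively; they carry no weight in stratification.

EXPRESSION_LEVELS <- c("very_low", "low", "normal", "high")
REPRESSION_LEVELS <- c("intact", "partial_LOF", "LOF")
MIGRATION_LEVELS <- c("cp_low", "cp_mid", "cp_high")

#' Default expression-category thresholds
#'
#' The very-low boundary (0.5, i.e. <50% of wild type) is fixed by the
#' stratification rule; the low/normal and normal/high boundaries are
#' conventions.
#'
#' @return Named numeric vector `c(very_low, low, high)`.
#' @export
expression_thresholds <- function() c(very_low = 0.5, low = 0.85, high = 1.20)

#' Categorize a relative-expression value
#'
#' @param relative_expression Mean variant/WT expression ratio, `>= 0`.
#' @param thresholds As [expression_thresholds()]: `very_low` (strict upper
#'   bound), `low` (strict upper bound of the low band) and `high` (values
#'   strictly above are `high`).
#' @return One of `"very_low"`, `"low"`, `"normal"`, `"high"`.
#' @examples
#' categorize_expression(0.30)
#' categorize_expression(1.50)
#' @export
categorize_expression <- function(relative_expression,
                                  thresholds = expression_thresholds()) {
  x <- relative_expression
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop("relative_expression must be a single non-negative number",
         call. = FALSE)
  }
  if (x < thresholds[["very_low"]]) "very_low"
  else if (x < thresholds[["low"]]) "low"
  else if (x <= thresholds[["high"]]) "normal"
  else "high"
}

#' Summarize western-blot replicates into a relative-expression call
#'
#' Each replicate's band intensity is divided by its GAPDH loading-control
#' intensity; the variant's loading-normalized value is then divided by the
#' batch-matched wild-type value, and the per-batch ratios are averaged.
#' Replicates without a batch-matched wild-type measurement are an error
#' (never pooled).
#'
#' @param variant_reps,wt_reps Data frames with columns `batch_id`,
#'   `band_intensity`, `loading_control_intensity` (strictly positive), at
#'   least 3 replicates each.
#' @param thresholds Category thresholds, see [categorize_expression()].
#' @return A list of class `expression_summary`: `relative_expression`,
#'   `log2_ratio`, `n_replicates`, `category`, `per_batch_ratios`.
#' @export
summarize_expression <- function(variant_reps, wt_reps,
                                 thresholds = expression_thresholds()) {
  for (nm in c("variant_reps", "wt_reps")) {
    df <- get(nm)
    need <- c("batch_id", "band_intensity", "loading_control_intensity")
    if (!is.data.frame(df) || !all(need %in% names(df))) {
      stop(nm, " must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(df$band_intensity <= 0) || any(df$loading_control_intensity <= 0)) {
      stop("intensities must be strictly positive", call. = FALSE)
    }
    if (nrow(df) < 3) {
      stop(nm, ": at least 3 replicates required", call. = FALSE)
    }
  }
  if (anyDuplicated(variant_reps$batch_id) || anyDuplicated(wt_reps$batch_id)) {
    stop("one replicate per batch expected for each construct", call. = FALSE)
  }
  unmatched <- setdiff(variant_reps$batch_id, wt_reps$batch_id)
  if (length(unmatched) > 0) {
    stop("no batch-matched WT replicate for batch ", unmatched[1],
         call. = FALSE)
  }
  wt_norm <- wt_reps$band_intensity / wt_reps$loading_control_intensity
  names(wt_norm) <- wt_reps$batch_id
  v_norm <- variant_reps$band_intensity /
    variant_reps$loading_control_intensity
  ratios <- v_norm / wt_norm[as.character(variant_reps$batch_id)]
  rel <- mean(ratios)
  structure(list(relative_expression = rel,
                 log2_ratio = log2(rel),
                 n_replicates = length(ratios),
                 category = categorize_expression(rel, thresholds),
                 per_batch_ratios = unname(ratios)),
            class = "expression_summary")
}

#' Call the COUP-TFI repression status of a variant
#'
#' A variant is `LOF` (lost repression) when its mean normalized RLU exceeds
#' wild type and the one-sided (variant > WT) uncorrected Fisher-LSD
#' comparison — using the pooled error of the full one-way ANOVA over all
#' effector groups — is significant at `alpha`. A variant whose mean exceeds
#' `partial_margin` times the WT mean without reaching significance is
#' `partial_LOF`; everything else is `intact`.
#'
#' @param groups Named list of per-effector normalized-RLU replicate vectors;
#'   must contain the entry named by `wt`.
#' @param variant Name of the variant group to call.
#' @param wt Name of the wild-type group (default `"WT"`).
#' @param alpha Significance level for the LSD comparison (default 0.05).
#' @param partial_margin Fold-over-WT margin defining `partial_LOF`
#'   (default 1.25).
#' @param fit Optional prefit [one_way_anova_lsd()] context over `groups`
#'   (avoids refitting when calling many variants against the same context).
#' @return A list: `status`, `p_vs_wt` (one-sided), `rlu_norm` (variant mean
#'   / WT mean), and the underlying `anova` fit.
#' @export
call_repression_status <- function(groups, variant, wt = "WT", alpha = 0.05,
                                   partial_margin = 1.25, fit = NULL) {
  if (!wt %in% names(groups)) {
    stop("configuration error: wild-type group '", wt, "' missing",
         call. = FALSE)
  }
  if (!variant %in% names(groups)) {
    stop("variant group '", variant, "' missing", call. = FALSE)
  }
  if (is.null(fit)) fit <- one_way_anova_lsd(groups)
  m_v <- fit$means[[variant]]
  m_wt <- fit$means[[wt]]
  p_one <- lsd_p(fit, variant, wt, direction = "greater")
  status <- if (m_v > m_wt && p_one < alpha) "LOF"
  else if (m_v > partial_margin * m_wt) "partial_LOF"
  else "intact"
  list(status = status, p_vs_wt = p_one, rlu_norm = m_v / m_wt, anova = fit)
}

#' Summarize dual-luciferase wells into repression calls
#'
#' Per well, RLU = firefly / Renilla. Within each batch the RLU of every
#' condition is divided by that batch's empty-vector (pGL4.1) mean; the
#' resulting per-batch values are the replicates. Each effector's mean is
#' finally normalized by the wild-type mean, so wild type itself is exactly
#' 1. Repression status per variant comes from [call_repression_status()]
#' over the full ANOVA context of all effector groups.
#'
#' @param wells Data frame of wells with columns `construct`
#'   (`empty_vector`, `promoter_only` or `promoter_plus_PBS1`), `effector`
#'   (`none`, `WT`, or a variant id), `firefly`, `renilla` (strictly
#'   positive counts) and `batch_id`. The `empty_vector` construct and a
#'   `promoter_plus_PBS1` + `WT` condition must be present, each with at
#'   least 3 replicate batches.
#' @param alpha,partial_margin Passed to [call_repression_status()].
#' @return A data.frame of class `repression_summary` with one row per
#'   effector (wild type included): `effector`, `rlu_norm`, `p_vs_wt`
#'   (one-sided, `NA` for WT), `status`, `n_replicates`.
#' @export
summarize_repression <- function(wells, alpha = 0.05, partial_margin = 1.25) {
  need <- c("construct", "effector", "firefly", "renilla", "batch_id")
  if (!is.data.frame(wells) || !all(need %in% names(wells))) {
    stop("wells must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(wells$firefly <= 0) || any(wells$renilla <= 0)) {
    stop("luminescence counts must be strictly positive", call. = FALSE)
  }
  wells$rlu <- wells$firefly / wells$renilla

  ev <- wells[wells$construct == "empty_vector", ]
  if (nrow(ev) == 0) {
    stop("configuration error: empty_vector reference wells missing",
         call. = FALSE)
  }
  ev_mean <- tapply(ev$rlu, ev$batch_id, mean)

  assay <- wells[wells$construct == "promoter_plus_PBS1" &
                   wells$effector != "none", ]
  if (!"WT" %in% assay$effector) {
    stop("configuration error: WT reference condition missing", call. = FALSE)
  }
  missing_ev <- setdiff(assay$batch_id, names(ev_mean))
  if (length(missing_ev) > 0) {
    stop("no empty-vector wells for batch ", missing_ev[1], call. = FALSE)
  }
  assay$rlu_ev <- assay$rlu / as.numeric(ev_mean[as.character(assay$batch_id)])

  groups <- split(assay$rlu_ev, assay$effector)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 3)) {
    stop("at least 3 replicate wells required per condition (",
         names(ns)[ns < 3][1], ")", call. = FALSE)
  }
  wt_mean <- mean(groups[["WT"]])
  context_fit <- if (length(groups) >= 2) one_way_anova_lsd(groups) else NULL
  effectors <- names(groups)
  rows <- lapply(effectors, function(e) {
    if (e == "WT") {
      return(data.frame(effector = e, rlu_norm = 1, p_vs_wt = NA_real_,
                        status = "intact", n_replicates = ns[[e]],
                        stringsAsFactors = FALSE))
    }
    call <- call_repression_status(groups, e, wt = "WT", alpha = alpha,
                                   partial_margin = partial_margin,
                                   fit = context_fit)
    data.frame(effector = e, rlu_norm = mean(groups[[e]]) / wt_mean,
               p_vs_wt = call$p_vs_wt, status = call$status,
               n_replicates = ns[[e]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("repression_summary", "data.frame")
  out
}

#' Check that PBS1 confers FOXG1-mediated repression
#'
#' The reporter design predicts lower luciferase activity when the
#' FOXG1-binding region PBS1 is included in the promoter construct
#' alongside wild-type FOXG1.
#'
#' @param wells Well table as in [summarize_repression()], containing
#'   `promoter_only` + `WT` and `promoter_plus_PBS1` + `WT` wells.
#' @return `TRUE` if the mean RLU with PBS1 is lower than without.
#' @export
verify_pbs1_repression <- function(wells) {
  wells$rlu <- wells$firefly / wells$renilla
  with_pbs1 <- wells$rlu[wells$construct == "promoter_plus_PBS1" &
                           wells$effector == "WT"]
  without <- wells$rlu[wells$construct == "promoter_only" &
                         wells$effector == "WT"]
  if (length(with_pbs1) == 0 || length(without) == 0) {
    stop("need promoter_only and promoter_plus_PBS1 wells with WT effector",
         call. = FALSE)
  }
  mean(with_pbs1) < mean(without)
}

#' Summarize per-embryo migration zone counts
#'
#' Computes per-embryo VZ/IZ/CP fractions, averages them across embryos
#' (the embryo is the replicate unit), and bands the cortical-plate
#' fraction: `cp_low` below the first edge, `cp_mid` between the edges
#' (inclusive), `cp_high` above the second.
#'
#' @param counts Data frame with columns `embryo_id`, `vz`, `iz`, `cp`
#'   (non-negative integer cell counts). Embryos with zero total cells are
#'   excluded with a warning.
#' @param band_edges Numeric length-2 vector of CP-fraction band edges
#'   (default `c(0.10, 0.25)`).
#' @return A list of class `migration_summary`: `zone_fractions` (named
#'   mean fractions summing to 1), `cp_fraction`, `n_embryos`, `category`.
#' @examples
#' counts <- data.frame(embryo_id = 1:3, vz = 40, iz = 40, cp = 20)
#' summarize_migration(counts)
#' @export
summarize_migration <- function(counts, band_edges = c(0.10, 0.25)) {
  need <- c("embryo_id", "vz", "iz", "cp")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  zones <- as.matrix(counts[, c("vz", "iz", "cp")])
  if (anyNA(zones) || any(zones < 0) || any(zones != round(zones))) {
    stop("zone counts must be non-negative integers", call. = FALSE)
  }
  totals <- rowSums(zones)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " embryo(s) with zero total cells excluded")
    zones <- zones[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (nrow(zones) < 3) {
    stop("insufficient data: at least 3 embryos with cells required",
         call. = FALSE)
  }
  fracs <- zones / totals
  zone_fractions <- colMeans(fracs)
  cp <- zone_fractions[["cp"]]
  category <- if (cp < band_edges[1]) "cp_low"
  else if (cp <= band_edges[2]) "cp_mid"
  else "cp_high"
  structure(list(zone_fractions = zone_fractions, cp_fraction = cp,
                 n_embryos = nrow(zones), category = category),
            class = "migration_summary")
}

#' Summarize layer-marker cell-fate counts
#'
#' Fraction of marker-positive (BRN2+ or RORb+) cells among GFP+
#' electroporated cells, averaged over brains by default. Descriptive only:
#' cell-fate fractions carry no weight in stratification.
#'
#' @param counts Data frame with columns `brain_id`, `marker_positive`,
#'   `gfp_total` (with `marker_positive <= gfp_total`, `gfp_total > 0`).
#' @param method `"per_brain_mean"` (default) or `"pooled"`.
#' @return Fraction in `[0, 1]`.
#' @export
summarize_cellfate <- function(counts,
                               method = c("per_brain_mean", "pooled")) {
  method <- match.arg(method)
  need <- c("brain_id", "marker_positive", "gfp_total")
  if (!is.data.frame(counts) || !all(need %in% names(counts)) ||
      nrow(counts) < 1) {
    stop("counts must have at least one row with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(counts$gfp_total <= 0)) {
    stop("gfp_total must be positive", call. = FALSE)
  }
  if (any(counts$marker_positive > counts$gfp_total) ||
      any(counts$marker_positive < 0)) {
    stop("marker_positive must be in [0, gfp_total]", call. = FALSE)
  }
  if (method == "pooled") {
    sum(counts$marker_positive) / sum(counts$gfp_total)
  } else {
    mean(counts$marker_positive / counts$gfp_total)
  }
}
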