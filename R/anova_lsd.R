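# One-way ANOVA with uncorrected Fisher's LSD post-hoc comparisons, the
# statistical procedure used for the reporter and expression assays
# (triplicate designs, comparisons of each variant against wild type).

#' One-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Fits a classical one-way ANOVA over `k >= 2` groups (via [stats::aov()])
#' and computes uncorrected Fisher-LSD pairwise comparisons using the pooled
#' mean squared error with `N - k` degrees of freedom. With zero residual
#' variance the decomposition is degenerate: the result is flagged and
#' pairwise p-values are taken in the limit (0 for any nonzero mean
#' difference, 1 for equal means).
#'
#' @param groups A named list of numeric vectors, one per group, each with
#'   at least 2 values.
#' @return An object of class `anova_lsd`: `f_statistic`, `p_value`,
#'   `df_between`, `df_within`, `mse`, `means`, `ns`, `degenerate`, and
#'   `pairs` — a data.frame of all pairwise comparisons with columns
#'   `group1`, `group2`, `diff` (mean1 - mean2), `t`, `p` (two-sided) and
#'   `p_greater` (one-sided, group1 > group2).
#' @examples
#' one_way_anova_lsd(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
one_way_anova_lsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) {
    stop("insufficient data: every group needs at least 2 values",
         call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (!is.numeric(values) || anyNA(values)) {
    stop("group values must be numeric and non-missing", call. = FALSE)
  }
  fac <- factor(rep(names(groups), ns), levels = names(groups))
  k <- length(groups)
  n_total <- length(values)

  fit <- stats::aov(values ~ fac)
  # anova() warns on a zero-residual fit; that case is handled explicitly
  # below via the degenerate flag
  tab <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ss_between <- tab[["Sum Sq"]][1]
  ss_within <- tab[["Sum Sq"]][2]
  df_between <- tab[["Df"]][1]
  df_within <- tab[["Df"]][2]
  mse <- ss_within / df_within
  means <- vapply(groups, mean, numeric(1))

  degenerate <- isTRUE(all.equal(ss_within, 0)) || mse < .Machine$double.eps
  if (degenerate) {
    f_stat <- if (ss_between > .Machine$double.eps) Inf else NaN
    p_value <- if (is.infinite(f_stat)) 0 else NA_real_
  } else {
    f_stat <- tab[["F value"]][1]
    p_value <- tab[["Pr(>F)"]][1]
  }

  combos <- utils::combn(names(groups), 2)
  g1 <- combos[1, ]; g2 <- combos[2, ]
  d <- unname(means[g1] - means[g2])
  if (degenerate) {
    equal <- abs(d) < sqrt(.Machine$double.eps)
    t_val <- ifelse(equal, 0, sign(d) * Inf)
    p_two <- ifelse(equal, 1, 0)
    p_gt <- ifelse(equal, 1, ifelse(d > 0, 0, 1))
  } else {
    se <- sqrt(mse * (1 / ns[g1] + 1 / ns[g2]))
    t_val <- unname(d / se)
    p_two <- 2 * stats::pt(-abs(t_val), df_within)
    p_gt <- stats::pt(t_val, df_within, lower.tail = FALSE)
  }
  pairs <- data.frame(group1 = g1, group2 = g2, diff = d, t = t_val,
                      p = p_two, p_greater = p_gt, stringsAsFactors = FALSE)

  structure(list(f_statistic = f_stat, p_value = p_value,
                 df_between = df_between, df_within = df_within,
                 mse = mse, means = means, ns = ns,
                 degenerate = degenerate, pairs = pairs),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      format(x$f_statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 3),
      if (x$degenerate) "  [degenerate: zero within-group variance]" else "",
      "\n", sep = "")
  cat("Fisher-LSD pairwise comparisons (uncorrected):\n")
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

# Fisher-LSD comparison of two named groups within a fitted anova_lsd
# context; direction "greater" tests group1 > group2.
lsd_p <- function(fit, group1, group2, direction = c("two_sided", "greater")) {
  direction <- match.arg(direction)
  rows <- fit$pairs
  idx <- which(rows$group1 == group1 & rows$group2 == group2)
  flip <- FALSE
  if (length(idx) == 0) {
    idx <- which(rows$group1 == group2 & rows$group2 == group1)
    flip <- TRUE
  }
  if (length(idx) == 0) {
    stop("no LSD comparison for groups '", group1, "' and '", group2, "'",
         call. = FALSE)
  }
  row <- rows[idx, ]
  if (direction == "two_sided") return(row$p)
  if (!flip) row$p_greater else {
    if (fit$degenerate) {
      if (isTRUE(all.equal(row$diff, 0))) 1 else if (row$diff < 0) 0 else 1
    } else {
      stats::pt(-row$t, fit$df_within, lower.tail = FALSE)
    }
  }
}
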