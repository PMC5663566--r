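#' Mann-Whitney U test for two groups of circulating levels
#'
#' Computes the U statistic of `x` (number of (x, y) pairs with x > y, with
#' midranks for ties) and a two-sided p-value: exact by enumeration of the
#' permutation distribution when the combined sample size is at most
#' `exact_max_n` and there are no ties, otherwise the normal approximation
#' with tie and continuity correction.  The method actually used is recorded.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_max_n combined-size threshold for the exact test (default 16).
#' @return list(U, p_value, method) with method "exact" or "normal_approx".
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 16L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= exact_max_n
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Fold change between case and control levels
#'
#' Linear-scale ratio of group means of relative levels (`2^-dCt`), with its
#' log2 and direction ("over" when the case mean exceeds the control mean,
#' "under" otherwise).
#'
#' @param case,control numeric vectors of relative levels; both group means
#'   must be positive.
#' @return list(fold_change, log2_fold_change, direction).
#' @export
fold_change <- function(case, control) {
  m1 <- mean(case); m0 <- mean(control)
  if (!is.finite(m1) || !is.finite(m0) || m1 <= 0 || m0 <= 0)
    stop("group means must be positive and finite", call. = FALSE)
  fc <- m1 / m0
  list(fold_change = fc, log2_fold_change = log2(fc),
       direction = if (fc >= 1) "over" else "under")
}

#' Multiple-testing adjustment of p-values
#'
#' Step-up Benjamini-Hochberg by default (the standard choice for array
#' screening), with Bonferroni and no adjustment as configurable
#' alternatives.  Adjusted values are never below the raw p-values and are
#' returned in the input order.
#'
#' @param p p-values in \[0, 1\] (NA passed through).
#' @param method "bh", "bonferroni" or "none".
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  switch(method,
         bh = p.adjust(p, method = "BH"),
         bonferroni = p.adjust(p, method = "bonferroni"),
         none = p)
}

#' Per-target differential representation table
#'
#' Runs [mann_whitney_u()] and [fold_change()] for every target of a long
#' expression table (case vs control levels), then adjusts the p-values.
#' Targets measured in fewer than `min_per_group` samples in either group
#' get NA statistics.
#'
#' @param levels long data.frame (sample_id, target_id, level) as produced by
#'   [global_mean_normalize()].
#' @param groups named group label per sample_id (values "cancer"/"control",
#'   or any two labels with `case`/`control` naming them).
#' @param case,control group labels taken as numerator and denominator.
#' @param adjust adjustment method for [adjust_pvalues()].
#' @param min_per_group minimum measured samples per group to test a target.
#' @return data.frame: target_id, n_case, n_control, fold_change,
#'   log2_fold_change, direction, U, p_value, adjusted_p, method.
#' @export
differential_table <- function(levels, groups, case = "cancer",
                               control = "control", adjust = "bh",
                               min_per_group = 3L) {
  stopifnot(all(c("sample_id", "target_id", "level") %in% names(levels)))
  grp <- groups[levels$sample_id]
  tids <- sort(unique(levels$target_id))
  rows <- lapply(tids, function(t) {
    sel <- levels$target_id == t
    x <- levels$level[sel & grp == case]
    y <- levels$level[sel & grp == control]
    if (length(x) < min_per_group || length(y) < min_per_group)
      return(data.frame(target_id = t, n_case = length(x), n_control = length(y),
                        fold_change = NA_real_, log2_fold_change = NA_real_,
                        direction = NA_character_, U = NA_real_,
                        p_value = NA_real_, method = NA_character_,
                        stringsAsFactors = FALSE))
    fc <- fold_change(x, y)
    mw <- mann_whitney_u(x, y)
    data.frame(target_id = t, n_case = length(x), n_control = length(y),
               fold_change = fc$fold_change, log2_fold_change = fc$log2_fold_change,
               direction = fc$direction, U = mw$U, p_value = mw$p_value,
               method = mw$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- adjust_pvalues(out$p_value, adjust)
  out
}

#' Select differential candidates by fold change and significance
#'
#' A target is selected iff `max(FC, 1/FC) > fc_threshold` (strict, so the
#' rule covers under-represented targets symmetrically) and its (adjusted, if
#' requested) p-value is strictly below `alpha`.
#'
#' @param results a [differential_table()] data.frame.
#' @param fc_threshold linear fold-change threshold (default 1.5, strict).
#' @param alpha significance level (default 0.05, strict).
#' @param use_adjusted use `adjusted_p` (screening) or raw `p_value`
#'   (validation).
#' @return `results` with a logical `selected` column (NA statistics are
#'   never selected).
#' @export
select_candidates <- function(results, fc_threshold = 1.5, alpha = 0.05,
                              use_adjusted = TRUE) {
  if (fc_threshold <= 0 || alpha <= 0) stop("thresholds must be positive", call. = FALSE)
  p <- if (use_adjusted) results$adjusted_p else results$p_value
  fc <- results$fold_change
  sel <- pmax(fc, 1 / fc) > fc_threshold & p < alpha
  results$selected <- !is.na(sel) & sel
  results
}
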