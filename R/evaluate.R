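#' Confusion matrix with malignant as the positive class
#'
#' @param truth,predicted equal-length label vectors over the same two-class
#'   label set.
#' @param positive label counted as positive (default "malignant").
#' @return list(tp, fp, tn, fn, total, positive) of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, positive = "malignant") {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  labels <- unique(c(truth, predicted))
  if (length(labels) > 2L)
    stop(sprintf("unknown labels: expected two classes, got %s",
                 paste(labels, collapse = ", ")), call. = FALSE)
  if (!positive %in% labels && length(labels) == 2L)
    stop(sprintf("positive class '%s' not among labels", positive), call. = FALSE)
  is_pos_t <- truth == positive
  is_pos_p <- predicted == positive
  structure(list(tp = sum(is_pos_t & is_pos_p), fp = sum(!is_pos_t & is_pos_p),
                 tn = sum(!is_pos_t & !is_pos_p), fn = sum(is_pos_t & !is_pos_p),
                 total = length(truth), positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP).  A metric with a zero denominator is reported
#' as NA (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list(accuracy, sensitivity, specificity, lr_positive,
#'   lr_negative) — the likelihood ratios are filled from
#'   [likelihood_ratios()] where defined.
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0L) stop("empty confusion matrix", call. = FALSE)
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  sens <- if (pos > 0L) cm$tp / pos else NA_real_
  spec <- if (neg > 0L) cm$tn / neg else NA_real_
  lr <- if (!is.na(sens) && !is.na(spec)) likelihood_ratios(sens, spec)
        else list(lr_positive = NA_real_, lr_negative = NA_real_)
  list(accuracy = (cm$tp + cm$tn) / cm$total, sensitivity = sens,
       specificity = spec, lr_positive = lr$lr_positive,
       lr_negative = lr$lr_negative)
}

#' Positive and negative likelihood ratios
#'
#' LR+ = sensitivity / (1 - specificity); LR- = (1 - sensitivity) /
#' specificity.  At specificity 1 the LR+ is infinite (reported as `Inf`);
#' at specificity 0 the LR- is infinite.
#'
#' @param sensitivity,specificity fractions in \[0, 1\].
#' @return list(lr_positive, lr_negative).
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  check_fraction(sensitivity, "sensitivity")
  check_fraction(specificity, "specificity")
  lr_pos <- if (specificity == 1) {
    if (sensitivity > 0) Inf else NaN
  } else sensitivity / (1 - specificity)
  lr_neg <- if (specificity == 0) {
    if (sensitivity < 1) Inf else NaN
  } else (1 - sensitivity) / specificity
  list(lr_positive = lr_pos, lr_negative = lr_neg)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold (a sample is called positive
#' when its score reaches the threshold) and integrates by the trapezoid
#' rule.  Tied scores produce
#' diagonal segments, so the AUC equals the Mann-Whitney rank statistic
#' `U / (n1 * n0)` with midranks for ties.
#'
#' @param truth logical (or 0/1) vector, TRUE = positive class; both classes
#'   must be present.
#' @param scores finite numeric scores, higher = more positive.
#' @return list(points = data.frame(threshold, fpr, tpr), auc).
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.logical(truth)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / n0, numeric(1))
  fpr_full <- c(0, fpr, 1)
  tpr_full <- c(0, tpr, 1)
  auc <- sum(diff(fpr_full) * (head(tpr_full, -1) + tpr_full[-1]) / 2)
  list(points = data.frame(threshold = c(Inf, thr, -Inf), fpr = fpr_full,
                           tpr = tpr_full),
       auc = auc)
}

#' Pearson correlation between a covariate and circulating levels
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom (used to check the signature against age,
#' BMI and similar covariates).
#'
#' @param x,y numeric vectors, n >= 3, both with non-zero variance.
#' @return list(r, p_value, n).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
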