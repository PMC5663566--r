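#' Tukey IQR outlier fences and filtering
#'
#' `tukey_fences()` computes Q1, Q3 (linear-interpolation / type-7 quartiles)
#' and the fences `Q1 - 1.5*IQR`, `Q3 + 1.5*IQR`.  `tukey_filter()` keeps the
#' values inside the closed fence interval and flags the rest; the fences are
#' returned so they can be reapplied verbatim to new samples.
#'
#' @param x numeric vector with at least 4 finite values.
#' @return `tukey_fences()`: list(q1, q3, iqr, lower, upper).
#'   `tukey_filter()`: list(kept, keep (logical per input), params).
#' @export
tukey_fences <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("at least 4 finite values are required", call. = FALSE)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], iqr = iqr,
       lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' @rdname tukey_fences
#' @export
tukey_filter <- function(x) {
  p <- tukey_fences(x)
  keep <- is.finite(x) & x >= p$lower & x <= p$upper
  list(kept = x[keep], keep = keep, params = p)
}

#' Min-max standardization to \[-1, +1\]
#'
#' `fit_minmax()` records the post-filter minimum and maximum of a feature;
#' `apply_minmax()` maps `x` to `2 * (x - min) / (max - min) - 1`, so the
#' training minimum becomes -1, the maximum +1 and the midpoint 0.  A
#' constant feature (max == min) maps to 0.  Parameters fitted on training
#' data are reused verbatim for validation, test and new samples.
#'
#' @param x numeric values.
#' @param params list(min, max) from `fit_minmax()`.
#' @return `fit_minmax()`: list(min, max); `apply_minmax()`: scaled values.
#' @export
fit_minmax <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to fit", call. = FALSE)
  list(min = min(x), max = max(x))
}

#' @rdname fit_minmax
#' @export
apply_minmax <- function(x, params) {
  rng <- params$max - params$min
  if (rng == 0) return(ifelse(is.finite(x), 0, NA_real_))
  2 * (x - params$min) / rng - 1
}

# Fit per-feature Tukey fences + min/max scaling on training rows only.
# Training rows with any out-of-fence feature are excluded from model fitting
# (their flag is returned); min/max are computed on the surviving rows.
preprocess_fit <- function(X) {
  stopifnot(is.matrix(X))
  fences <- lapply(seq_len(ncol(X)), function(j) tukey_fences(X[, j]))
  inlier <- sapply(seq_len(ncol(X)), function(j)
    X[, j] >= fences[[j]]$lower & X[, j] <= fences[[j]]$upper)
  keep_row <- rowSums(!inlier) == 0L
  minmax <- lapply(seq_len(ncol(X)), function(j)
    fit_minmax(X[keep_row, j]))
  list(fences = fences, minmax = minmax, keep_row = keep_row,
       feature_names = colnames(X))
}

# Scale any matrix with fitted parameters; returns the scaled matrix plus a
# per-row flag for samples outside the training fences (still scored, but
# flagged downstream).
preprocess_apply <- function(X, params) {
  stopifnot(is.matrix(X), ncol(X) == length(params$minmax))
  scaled <- sapply(seq_len(ncol(X)), function(j)
    apply_minmax(X[, j], params$minmax[[j]]))
  scaled <- matrix(scaled, nrow = nrow(X),
                   dimnames = list(rownames(X), params$feature_names))
  out_of_fence <- sapply(seq_len(ncol(X)), function(j)
    X[, j] < params$fences[[j]]$lower | X[, j] > params$fences[[j]]$upper)
  out_of_fence <- matrix(out_of_fence, nrow = nrow(X))
  list(scaled = scaled, out_of_fence = rowSums(out_of_fence, na.rm = TRUE) > 0L)
}
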