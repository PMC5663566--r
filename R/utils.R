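#' @useDynLib plasmiR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif rbinom p.adjust wilcox.test cor.test
#' @importFrom utils head write.table read.delim
NULL

# Derive a child seed (< 2^31) from a master seed and a stage label, so every
# sub-stage of a run has its own reproducible RNG stream.
child_seed <- function(seed, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.double(seed) %% 2147483647) * 48271 + stage_code * 1000003 + index
  as.integer(val %% 2147483629) + 1L
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) stop_field(field, "must be a single number")
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) stop_field(field, sprintf("must lie in %s0, 1%s", if (open_left) "(" else "[", if (open_right) ")" else "]"))
  x
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_field(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_field(field, "must be a single non-negative number")
  x
}

#' Convert a linear-scale coefficient of variation to a Ct-scale SD
#'
#' Relative qPCR levels (`2^-dCt`) with log-normal noise of coefficient of
#' variation `cv` correspond to Gaussian noise on the Ct (log2) scale with
#' standard deviation `sqrt(log(1 + cv^2)) / log(2)` cycles.
#'
#' @param cv coefficient of variation on the linear scale (e.g. 0.3 for 30%).
#' @return Standard deviation in cycles.
#' @export
cv_to_ct_sd <- function(cv) {
  check_nonneg(cv, "cv")
  sqrt(log(1 + cv^2)) / log(2)
}
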