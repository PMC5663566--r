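#' Detection call for a qPCR reaction
#'
#' A target is called detected when its Ct is finite and strictly below the
#' detection limit (default 35 cycles); missing or late amplification is
#' undetected.
#'
#' @param ct numeric Ct values (NA allowed).
#' @param limit detection limit in cycles (> 0).
#' @return Logical vector.
#' @export
detection_call <- function(ct, limit = 35) {
  if (!is.numeric(limit) || length(limit) != 1L || limit <= 0)
    stop_field("limit", "must be a single positive number")
  is.finite(ct) & ct < limit
}

#' Global-mean normalization of a screening Ct table
#'
#' For each sample, dCt(target) = Ct(target) - mean(Ct over that sample's
#' detected targets), and the relative level is `2^-dCt` (one cycle = one
#' doubling).  This is the global-mean calibrator convention used for
#' genome-wide miRNA PCR arrays, where no fixed reference gene exists.
#' Undetected targets are absent from the output, not zero.  Samples with no
#' detected target are dropped with a warning.
#'
#' @param x a `ct_table` or a data.frame with columns sample_id, target_id,
#'   ct, detected.
#' @return data.frame (sample_id, target_id, dct, level) with attribute
#'   `provenance = list(method = "global_mean")`.
#' @export
global_mean_normalize <- function(x) {
  obs <- if (inherits(x, "ct_table")) x$observations else x
  stopifnot(all(c("sample_id", "target_id", "ct", "detected") %in% names(obs)))
  det <- obs[obs$detected, , drop = FALSE]
  empty <- setdiff(unique(obs$sample_id), unique(det$sample_id))
  if (length(empty) > 0L)
    warning(sprintf("dropping %d sample(s) with no detected target: %s",
                    length(empty), paste(head(empty, 5L), collapse = ", ")),
            call. = FALSE)
  sample_mean <- tapply(det$ct, det$sample_id, mean)
  dct <- det$ct - as.numeric(sample_mean[det$sample_id])
  out <- data.frame(sample_id = det$sample_id, target_id = det$target_id,
                    dct = dct, level = 2^(-dct), stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(method = "global_mean")
  out
}

#' Relative level by the 2^-dCt formula against calibrator assays
#'
#' `delta_ct_level(ct, calib)` returns `2^-(ct - mean(calib))`: the target's
#' abundance relative to the mean of the calibrator Cts.  The level is
#' strictly decreasing in `ct` and halves exactly for each additional cycle.
#'
#' @param ct_target target Ct values (vectorized).
#' @param calibrator_cts non-empty numeric vector of finite calibrator Cts
#'   for the same sample.
#' @return Relative levels (dimensionless, > 0).
#' @export
delta_ct_level <- function(ct_target, calibrator_cts) {
  if (length(calibrator_cts) == 0L)
    stop("calibrator_cts must be non-empty", call. = FALSE)
  if (any(!is.finite(calibrator_cts)))
    stop("calibrator_cts must all be finite", call. = FALSE)
  2^(-(ct_target - mean(calibrator_cts)))
}

#' Reference-gene stability scores by intra/intergroup variance decomposition
#'
#' Model-based stability ranking in the NormFinder style: sample effects are
#' removed by centering each sample on its mean Ct over the scored targets;
#' then, per target and group, the intergroup bias `d_ig` (deviation of the
#' group mean from the across-group mean) and the intragroup variance are
#' estimated.  The stability score averages `|d_ig| + sqrt(var_ig / n_g)`
#' over groups; lower is more stable.  Adding a constant to all Cts of a
#' sample leaves the scores unchanged (sample-effect removal).
#'
#' @param ct_matrix numeric matrix of Cts, targets in rows, samples in
#'   columns (log2 scale, as measured).
#' @param groups group label per column; every group needs >= 2 samples.
#' @param min_per_group targets with fewer finite values than this in any
#'   group are scored NA.
#' @return Named numeric vector of stability scores (lower = more stable).
#' @export
stability_scores <- function(ct_matrix, groups, min_per_group = 2L) {
  stopifnot(is.matrix(ct_matrix), ncol(ct_matrix) == length(groups))
  groups <- as.factor(groups)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  complete <- rowSums(!is.finite(ct_matrix)) == 0L
  scores <- rep(NA_real_, nrow(ct_matrix))
  names(scores) <- rownames(ct_matrix)
  y <- ct_matrix[complete, , drop = FALSE]
  if (nrow(y) < 2L) return(scores)
  z <- sweep(y, 2L, colMeans(y))          # remove per-sample effects
  glev <- levels(groups)
  zbar <- sapply(glev, function(g) rowMeans(z[, groups == g, drop = FALSE]))
  v <- sapply(glev, function(g) apply(z[, groups == g, drop = FALSE], 1L, var))
  n_g <- as.numeric(table(groups)[glev])
  d <- zbar - rowMeans(zbar)              # intergroup bias per target x group
  s <- rowMeans(abs(d) + sqrt(sweep(v, 2L, n_g, "/")))
  # targets too sparse in any group are left NA
  counts <- sapply(glev, function(g)
    rowSums(is.finite(ct_matrix[, groups == g, drop = FALSE])))
  ok <- complete & apply(counts >= min_per_group, 1L, all)
  scores[rownames(y)[ok[complete]]] <- s[ok[complete]]
  scores
}

#' Select calibrator targets from a stability ranking
#'
#' Returns the union of user-fixed calibrators (spike-in, designated
#' references) and the `k` most stable scored targets.  Ties at rank `k` are
#' broken lexicographically by target id.
#'
#' @param scores named stability scores ([stability_scores()]); NA scores are
#'   ignored.
#' @param k number of data-selected stable targets (>= 1).
#' @param fixed_ids always-included calibrator ids (deduplicated against the
#'   selection).
#' @return A list of class `calibrator_set`: `$ids` (all calibrators),
#'   `$selected` (the k stable ones), `$fixed`, `$scores`.
#' @export
select_calibrators <- function(scores, k, fixed_ids = character()) {
  k <- check_count(k, "k", min = 1L)
  scored <- scores[!is.na(scores)]
  if (length(scored) < k)
    stop(sprintf("only %d scored targets but k = %d", length(scored), k), call. = FALSE)
  ord <- order(scored, names(scored))   # score, then lexicographic id
  selected <- names(scored)[ord][seq_len(k)]
  structure(list(ids = union(fixed_ids, selected), selected = selected,
                 fixed = fixed_ids, scores = scores),
            class = "calibrator_set")
}

#' @export
print.calibrator_set <- function(x, ...) {
  cat("calibrator_set:", paste(x$ids, collapse = ", "), "\n")
  cat("  data-selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# Reshape a long ct_table into a targets x samples Ct matrix (NA where not
# detected / not measured).
ct_long_to_matrix <- function(obs, detected_only = TRUE) {
  if (detected_only) obs <- obs[obs$detected, , drop = FALSE]
  tids <- sort(unique(obs$target_id))
  sids <- sort(unique(obs$sample_id))
  m <- matrix(NA_real_, length(tids), length(sids), dimnames = list(tids, sids))
  m[cbind(match(obs$target_id, tids), match(obs$sample_id, sids))] <- obs$ct
  m
}
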