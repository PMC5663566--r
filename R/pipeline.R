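#' Screening phase: genome-wide differential representation
#'
#' Orchestrates QC exclusion, detection calling, global-mean normalization,
#' per-target Mann-Whitney testing and multiplicity adjustment, and selects
#' screening candidates at adjusted p < `alpha`.  Per-stage counts are
#' logged when `verbose = TRUE`.
#'
#' @param ct_table a `ct_table` (see [simulate_screening_cohort()] /
#'   [read_ct_table()]).
#' @param qc_records optional QC record data.frame; samples failing
#'   [apply_sample_qc()] are excluded from all downstream stages.
#' @param detection_limit Ct detection limit (cycles).
#' @param alpha significance level on the adjusted p-value (strict).
#' @param adjust adjustment method ("bh", "bonferroni", "none").
#' @param fc_threshold optional linear fold-change threshold applied on top
#'   of the adjusted p criterion (NULL, the default, selects on adjusted p
#'   alone, the usual array-screening rule).
#' @param min_per_group minimum detected samples per group to test a target.
#' @param verbose log stage counts to stderr.
#' @return list: `results` ([differential_table()] with `selected`),
#'   `candidates` (selected target ids), `n_samples_qc_pass`, `levels`.
#' @export
run_screening <- function(ct_table, qc_records = NULL, detection_limit = 35,
                          alpha = 0.05, adjust = "bh", fc_threshold = NULL,
                          min_per_group = 3L, verbose = FALSE) {
  stopifnot(inherits(ct_table, "ct_table"))
  obs <- ct_table$observations
  samples <- ct_table$samples
  if (!is.null(qc_records)) {
    verdicts <- apply_sample_qc(qc_records, verbose = verbose)
    keep <- verdicts$sample_id[verdicts$overall_pass]
    obs <- obs[obs$sample_id %in% keep, , drop = FALSE]
    samples <- samples[samples$sample_id %in% keep, , drop = FALSE]
  }
  if (verbose)
    message(sprintf("screening: %d samples enter normalization", nrow(samples)))
  obs$detected <- detection_call(obs$ct, detection_limit)
  levels_long <- global_mean_normalize(obs)
  groups <- stats::setNames(samples$group, samples$sample_id)
  res <- differential_table(levels_long, groups, case = "cancer",
                            control = "control", adjust = adjust,
                            min_per_group = min_per_group)
  if (is.null(fc_threshold)) {
    res$selected <- !is.na(res$adjusted_p) & res$adjusted_p < alpha
  } else {
    res <- select_candidates(res, fc_threshold = fc_threshold, alpha = alpha,
                             use_adjusted = TRUE)
  }
  if (verbose)
    message(sprintf("screening: %d/%d tested targets selected (adjusted p < %g)",
                    sum(res$selected), sum(!is.na(res$p_value)), alpha))
  list(results = res, candidates = res$target_id[res$selected],
       n_samples_qc_pass = nrow(samples), levels = levels_long)
}

#' Validation phase: reduce candidates to a minimal signature
#'
#' Ranks the calibrator pool by [stability_scores()], selects calibrators
#' (fixed references plus the `k_stable` most stable), quantifies each
#' candidate per sample by [delta_ct_level()] against the mean calibrator
#' Ct, and retains candidates with fold change strictly over `fc_threshold`
#' and raw Mann-Whitney p strictly below `alpha`.
#'
#' @param ct_table validation-phase `ct_table` (cancer vs control samples).
#' @param candidate_ids candidate target ids; each must be measured in the
#'   table.
#' @param calibrator_pool ids scored for stability (default: every measured
#'   target not in `candidate_ids`).
#' @param fixed_calibrators always-included calibrator ids (spike-in,
#'   designated references).
#' @param k_stable number of data-selected stable calibrators.
#' @param fc_threshold,alpha selection thresholds (both strict).
#' @param verbose log stage counts.
#' @return list: `signature` (selected candidate ids), `results`,
#'   `calibrators` (a `calibrator_set`), `levels` (long data.frame of
#'   candidate 2^-dCt levels).
#' @export
run_validation <- function(ct_table, candidate_ids, calibrator_pool = NULL,
                           fixed_calibrators = character(), k_stable = 2L,
                           fc_threshold = 1.5, alpha = 0.05, verbose = FALSE) {
  stopifnot(inherits(ct_table, "ct_table"))
  obs <- ct_table$observations
  measured <- unique(obs$target_id)
  missing <- setdiff(candidate_ids, measured)
  if (length(missing) > 0L)
    stop(sprintf("candidate(s) not measured in the table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (is.null(calibrator_pool)) calibrator_pool <- setdiff(measured, candidate_ids)
  if (length(calibrator_pool) == 0L && length(fixed_calibrators) == 0L)
    stop("no calibrator is measurable", call. = FALSE)
  groups <- stats::setNames(ct_table$samples$group, ct_table$samples$sample_id)
  ct_mat <- ct_long_to_matrix(obs, detected_only = TRUE)
  scores <- if (length(calibrator_pool) > 0L)
    stability_scores(ct_mat[rownames(ct_mat) %in% calibrator_pool, , drop = FALSE],
                     groups[colnames(ct_mat)])
  else stats::setNames(numeric(0), character(0))
  calset <- if (length(scores) >= k_stable && k_stable >= 1L)
    select_calibrators(scores, k = k_stable, fixed_ids = fixed_calibrators)
  else structure(list(ids = fixed_calibrators, selected = character(0),
                      fixed = fixed_calibrators, scores = scores),
                 class = "calibrator_set")
  if (length(calset$ids) == 0L) stop("no calibrator is measurable", call. = FALSE)
  if (verbose)
    message(sprintf("validation: calibrators = %s", paste(calset$ids, collapse = ", ")))

  calib_ct <- ct_mat[rownames(ct_mat) %in% calset$ids, , drop = FALSE]
  calib_mean <- colMeans(calib_ct, na.rm = TRUE)
  usable <- is.finite(calib_mean)
  rows <- list()
  for (cand in candidate_ids) {
    ct_c <- ct_mat[cand, usable]
    ok <- is.finite(ct_c)
    rows[[cand]] <- data.frame(sample_id = names(ct_c)[ok], target_id = cand,
                               level = 2^(-(ct_c[ok] - calib_mean[usable][ok])),
                               stringsAsFactors = FALSE)
  }
  levels_long <- do.call(rbind, rows)
  rownames(levels_long) <- NULL
  res <- differential_table(levels_long, groups, case = "cancer",
                            control = "control", adjust = "none")
  res <- select_candidates(res, fc_threshold = fc_threshold, alpha = alpha,
                           use_adjusted = FALSE)
  if (verbose)
    message(sprintf("validation: %d/%d candidates in the signature",
                    sum(res$selected), length(candidate_ids)))
  list(signature = res$target_id[res$selected], results = res,
       calibrators = calset, levels = levels_long)
}

#' Classification phase: train and evaluate the lesion classifier
#'
#' Drops samples with unusable (missing) levels, then runs the full
#' [ann_fit()] stochastic topology search on the signature levels and
#' reports test-split and pooled (all-data) diagnostic metrics of the
#' winning network.
#'
#' @param cohort a `birads4_cohort` (or list with `$levels`, `$labels`,
#'   `$usable`).
#' @param signature feature (miRNA) names; default all columns of
#'   `cohort$levels`.
#' @param iterations,seed,control passed to [ann_fit()].
#' @param verbose log stage counts.
#' @return list: `model` (`birads_ann`), `metrics_test`, `metrics_pooled`,
#'   `n_usable`, `n_total`.
#' @export
run_classification <- function(cohort, signature = NULL, iterations = 200L,
                               seed = 1L, control = train_control(),
                               verbose = FALSE) {
  levels_mat <- cohort$levels
  if (is.null(signature)) signature <- colnames(levels_mat)
  if (length(signature) < 1L) stop("signature needs at least one feature", call. = FALSE)
  usable <- if (!is.null(cohort$usable)) cohort$usable
            else stats::complete.cases(levels_mat[, signature, drop = FALSE])
  if (!any(usable)) stop("all samples were filtered out", call. = FALSE)
  dat <- as.data.frame(levels_mat[usable, signature, drop = FALSE])
  names(dat) <- make.names(signature)
  dat$class <- factor(cohort$labels[usable])
  if (nlevels(dat$class) < 2L) stop("cohort must contain both classes", call. = FALSE)
  if (verbose)
    message(sprintf("classification: %d/%d samples usable", sum(usable),
                    length(usable)))
  fml <- stats::as.formula(paste("class ~", paste(make.names(signature), collapse = " + ")))
  model <- ann_fit(fml, dat, iterations = iterations, seed = seed,
                   control = control)
  list(model = model, metrics_test = model$metrics_test,
       metrics_pooled = model$metrics_pooled,
       n_usable = sum(usable), n_total = length(usable))
}
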