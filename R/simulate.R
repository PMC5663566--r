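#' Configuration for a synthetic qPCR cohort
#'
#' Describes a two-group circulating-miRNA cohort measured by qPCR: group
#' sizes, panel size, per-sample detection rate, and the programmed
#' differential structure.  Ct noise is Gaussian on the Ct (log2) scale; one
#' PCR cycle corresponds to one doubling of abundance, so a target with
#' programmed `log2_fold_change` f has its cancer-group mean Ct shifted by
#' `-f` cycles.
#'
#' Defaults mirror a plasma miRNome screening phase: 72 controls versus 46
#' cancer samples over a 1,805-target panel with roughly 20% of targets
#' detected per sample.
#'
#' @param n_control,n_cancer samples per group.
#' @param n_targets panel size.
#' @param detection_rate expected fraction of the panel detected per sample,
#'   in (0, 1]. Non-detection is simulated as the Ct exceeding
#'   `ct_detection_limit` plus independent dropout at rate
#'   `1 - detection_rate`.
#' @param n_true_differential number of targets carrying a programmed group
#'   effect (the first `n_true_differential` target ids).
#' @param log2_fold_changes programmed log2 fold changes (cancer/control),
#'   recycled to `n_true_differential`.
#' @param baseline_ct_mean,baseline_ct_sd distribution of per-target baseline
#'   mean Cts across the panel (cycles).
#' @param within_group_ct_sd inter-subject Ct SD within a group (cycles).
#' @param ct_detection_limit Ct at or above which a reaction is called
#'   undetected (cycles).
#' @param seed integer seed; identical configurations give identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 72L, n_cancer = 46L, n_targets = 1805L,
                          detection_rate = 0.2, n_true_differential = 0L,
                          log2_fold_changes = numeric(0),
                          baseline_ct_mean = 28, baseline_ct_sd = 2,
                          within_group_ct_sd = 0.8, ct_detection_limit = 35,
                          seed = 1L) {
  cfg <- list(
    n_control = check_count(n_control, "n_control", min = 1L),
    n_cancer = check_count(n_cancer, "n_cancer", min = 1L),
    n_targets = check_count(n_targets, "n_targets", min = 1L),
    detection_rate = check_fraction(detection_rate, "detection_rate", open_left = TRUE),
    n_true_differential = check_count(n_true_differential, "n_true_differential"),
    log2_fold_changes = log2_fold_changes,
    baseline_ct_mean = check_nonneg(baseline_ct_mean, "baseline_ct_mean"),
    baseline_ct_sd = check_nonneg(baseline_ct_sd, "baseline_ct_sd"),
    within_group_ct_sd = check_nonneg(within_group_ct_sd, "within_group_ct_sd"),
    ct_detection_limit = check_nonneg(ct_detection_limit, "ct_detection_limit"),
    seed = check_count(seed, "seed")
  )
  if (cfg$n_true_differential > cfg$n_targets)
    stop_field("n_true_differential", "cannot exceed n_targets")
  if (cfg$n_true_differential > 0L) {
    if (length(cfg$log2_fold_changes) == 0L)
      stop_field("log2_fold_changes", "required when n_true_differential > 0")
    cfg$log2_fold_changes <- rep_len(as.numeric(cfg$log2_fold_changes),
                                     cfg$n_true_differential)
  } else {
    cfg$log2_fold_changes <- numeric(0)
  }
  class(cfg) <- "cohort_config"
  cfg
}

target_ids <- function(n) sprintf("miR-T%04d", seq_len(n))

# Core two-group Ct sampler shared by the screening and validation generators.
simulate_ct_groups <- function(cfg, ids, shifts, dropout) {
  n_t <- length(ids)
  target_mu <- rnorm(n_t, cfg$baseline_ct_mean, cfg$baseline_ct_sd)
  groups <- c(rep("control", cfg$n_control), rep("cancer", cfg$n_cancer))
  sample_id <- sprintf("S%03d", seq_along(groups))
  obs <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    mu <- target_mu - if (groups[s] == "cancer") shifts else 0
    ct <- rnorm(n_t, mu, cfg$within_group_ct_sd)
    detected <- ct < cfg$ct_detection_limit
    if (dropout) detected <- detected & (runif(n_t) < cfg$detection_rate)
    obs[[s]] <- data.frame(sample_id = sample_id[s], target_id = ids,
                           ct = ct, detected = detected,
                           stringsAsFactors = FALSE)
  }
  list(observations = do.call(rbind, obs),
       samples = data.frame(sample_id = sample_id, group = groups,
                            stringsAsFactors = FALSE))
}

new_ct_table <- function(observations, samples, truth, config) {
  structure(list(observations = observations, samples = samples,
                 truth = truth, config = config),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d samples x %d targets (%d observations, %.1f%% detected)\n",
              nrow(x$samples), length(unique(x$observations$target_id)),
              nrow(x$observations), 100 * mean(x$observations$detected)))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a screening-phase cohort of raw Cts
#'
#' Generates a long-format Ct table for a two-group miRNome screen under
#' `cohort_config()`.  The designated truth targets have their cancer-group
#' mean Ct lowered by `log2_fold_change` cycles (one cycle = one doubling of
#' abundance); every other target has no group effect.  Non-detection is
#' simulated as Ct at or above the detection limit plus independent dropout
#' so the expected per-sample detected fraction matches `detection_rate`.
#'
#' @param config a [cohort_config()].
#' @return A `ct_table`: `$observations` (sample_id, target_id, ct, detected),
#'   `$samples` (sample_id, group), `$truth` (target_id, true_differential,
#'   log2_fold_change) and `$config`.
#' @export
simulate_screening_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, "screening"))
  ids <- target_ids(config$n_targets)
  shifts <- numeric(config$n_targets)
  truth_idx <- seq_len(config$n_true_differential)
  shifts[truth_idx] <- config$log2_fold_changes
  sim <- simulate_ct_groups(config, ids, shifts, dropout = TRUE)
  truth <- data.frame(target_id = ids,
                      true_differential = seq_len(config$n_targets) %in% truth_idx,
                      log2_fold_change = shifts, stringsAsFactors = FALSE)
  new_ct_table(sim$observations, sim$samples, truth, config)
}

#' Simulate a validation-phase cohort for a targeted candidate panel
#'
#' Emulates the targeted qPCR validation of screening candidates alongside
#' calibrator assays (designated references, data-selected stable miRNAs and
#' a spike-in analogue).  Calibrators carry zero programmed group effect;
#' candidates carry `config$log2_fold_changes` in panel order.  Targeted
#' assays are sensitive, so detection is limited only by the Ct detection
#' limit (no random dropout).
#'
#' @param config a [cohort_config()] whose `n_true_differential` and
#'   `log2_fold_changes` describe the candidate effects (the first
#'   `n_true_differential` candidates are truly differential).
#' @param candidate_ids,calibrator_ids disjoint character vectors of target ids.
#' @return A `ct_table` over `c(candidate_ids, calibrator_ids)`.
#' @export
simulate_validation_cohort <- function(config, candidate_ids, calibrator_ids) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(intersect(candidate_ids, calibrator_ids)) > 0L)
    stop("candidate_ids and calibrator_ids must be disjoint", call. = FALSE)
  if (length(calibrator_ids) == 0L)
    stop_field("calibrator_ids", "at least one calibrator is required")
  if (config$n_true_differential > length(candidate_ids))
    stop_field("n_true_differential", "cannot exceed the number of candidates")
  set.seed(child_seed(config$seed, "validation"))
  ids <- c(candidate_ids, calibrator_ids)
  shifts <- numeric(length(ids))
  shifts[seq_len(config$n_true_differential)] <- config$log2_fold_changes
  sim <- simulate_ct_groups(config, ids, shifts, dropout = FALSE)
  truth <- data.frame(target_id = ids,
                      true_differential = shifts != 0,
                      log2_fold_change = shifts,
                      role = rep(c("candidate", "calibrator"),
                                 c(length(candidate_ids), length(calibrator_ids))),
                      stringsAsFactors = FALSE)
  new_ct_table(sim$observations, sim$samples, truth, config)
}

#' Simulate a BI-RADS 4 cohort of relative miRNA levels
#'
#' Generates `2^-dCt` levels for the three-miRNA signature (miR-15a, miR-101,
#' miR-144) in a biopsy-proven BI-RADS category 4 cohort.  Levels are
#' log-normal with coefficient of variation `noise_cv`; malignant samples
#' have each miRNA multiplied by its fold change in `effects`.  A fraction
#' `missing_rate` of individual measurements is marked unusable; samples with
#' any unusable level are flagged (`usable = FALSE`) and are dropped by the
#' classifier stage.
#'
#' The malignant count is `round(n * malignant_fraction)` with ties rounded
#' half up (so 62 samples at 67% give 42 malignant).
#'
#' @param n cohort size (>= 4, so a 60/20/20 split is possible).
#' @param malignant_fraction fraction of malignant lesions, in (0, 1).
#' @param effects linear fold changes (malignant/benign), recycled to the
#'   three signature miRNAs.
#' @param noise_cv coefficient of variation of the log-normal level noise.
#' @param missing_rate per-measurement probability of an unusable level.
#' @param baseline_levels benign-group median levels per miRNA.
#' @param seed integer seed.
#' @return A list of class `birads4_cohort`: `$levels` (n x 3 matrix, NA where
#'   unusable), `$labels` (factor benign/malignant), `$usable` (logical),
#'   `$truth` (effects and parameters).
#' @export
simulate_birads4_cohort <- function(n = 62L, malignant_fraction = 0.67,
                                    effects = 2.5, noise_cv = 0.2,
                                    missing_rate = 0.03,
                                    baseline_levels = c(0.05, 0.02, 0.08),
                                    seed = 1L) {
  n <- check_count(n, "n", min = 0L)
  if (n < 4L) stop_field("n", "at least 4 samples are needed for a 60/20/20 split")
  check_fraction(malignant_fraction, "malignant_fraction", open_left = TRUE, open_right = TRUE)
  check_nonneg(noise_cv, "noise_cv")
  check_fraction(missing_rate, "missing_rate")
  set.seed(child_seed(check_count(seed, "seed"), "birads4"))
  signature <- c("miR-15a", "miR-101", "miR-144")
  effects <- rep_len(as.numeric(effects), 3L)
  if (any(effects <= 0)) stop_field("effects", "fold changes must be positive")
  baseline_levels <- rep_len(as.numeric(baseline_levels), 3L)

  n_mal <- floor(n * malignant_fraction + 0.5)  # round half up
  labels <- factor(rep(c("malignant", "benign"), c(n_mal, n - n_mal)),
                   levels = c("benign", "malignant"))
  labels <- labels[sample.int(n)]
  sdlog <- sqrt(log(1 + noise_cv^2))
  levels_mat <- matrix(NA_real_, n, 3L,
                       dimnames = list(sprintf("B%03d", seq_len(n)), signature))
  for (j in 1:3) {
    meanlog <- log(baseline_levels[j]) +
      ifelse(labels == "malignant", log(effects[j]), 0)
    levels_mat[, j] <- exp(rnorm(n, meanlog, sdlog))
  }
  miss <- matrix(runif(n * 3L) < missing_rate, n, 3L)
  levels_mat[miss] <- NA_real_
  usable <- rowSums(miss) == 0L
  structure(list(levels = levels_mat, labels = labels, usable = usable,
                 truth = list(signature = signature, effects = effects,
                              noise_cv = noise_cv, missing_rate = missing_rate,
                              malignant_fraction = malignant_fraction,
                              seed = seed)),
            class = "birads4_cohort")
}

#' @export
print.birads4_cohort <- function(x, ...) {
  cat(sprintf("birads4_cohort: %d samples (%d malignant, %d benign), %d usable\n",
              length(x$labels), sum(x$labels == "malignant"),
              sum(x$labels == "benign"), sum(x$usable)))
  invisible(x)
}

#' Configuration for simulated sample quality-control measurements
#'
#' @param hemolysis_rate fraction of samples drawn from the hemolyzed
#'   absorbance distribution.
#' @param abs414_clean_mean,abs414_clean_sd absorbance at 414 nm for clean
#'   plasma.
#' @param abs414_hemolyzed_mean,abs414_hemolyzed_sd absorbance for hemolyzed
#'   plasma.
#' @param rtc_ct_mean,rtc_ct_sd reverse-transcription control Ct distribution.
#' @param ppc_ct_mean,ppc_ct_sd positive PCR control Ct distribution.
#' @param n_replicates control-assay replicates per sample.
#' @param seed integer seed.
#' @return A list of class `qc_sim_config`.
#' @export
qc_sim_config <- function(hemolysis_rate = 0, abs414_clean_mean = 0.08,
                          abs414_clean_sd = 0.03, abs414_hemolyzed_mean = 0.5,
                          abs414_hemolyzed_sd = 0.15, rtc_ct_mean = 24,
                          rtc_ct_sd = 0.5, ppc_ct_mean = 19, ppc_ct_sd = 0.5,
                          n_replicates = 3L, seed = 1L) {
  cfg <- list(
    hemolysis_rate = check_fraction(hemolysis_rate, "hemolysis_rate"),
    abs414_clean_mean = check_nonneg(abs414_clean_mean, "abs414_clean_mean"),
    abs414_clean_sd = check_nonneg(abs414_clean_sd, "abs414_clean_sd"),
    abs414_hemolyzed_mean = check_nonneg(abs414_hemolyzed_mean, "abs414_hemolyzed_mean"),
    abs414_hemolyzed_sd = check_nonneg(abs414_hemolyzed_sd, "abs414_hemolyzed_sd"),
    rtc_ct_mean = check_nonneg(rtc_ct_mean, "rtc_ct_mean"),
    rtc_ct_sd = check_nonneg(rtc_ct_sd, "rtc_ct_sd"),
    ppc_ct_mean = check_nonneg(ppc_ct_mean, "ppc_ct_mean"),
    ppc_ct_sd = check_nonneg(ppc_ct_sd, "ppc_ct_sd"),
    n_replicates = check_count(n_replicates, "n_replicates", min = 1L),
    seed = check_count(seed, "seed")
  )
  class(cfg) <- "qc_sim_config"
  cfg
}

#' Simulate per-sample quality-control records
#'
#' Draws absorbance at 414 nm (hemolysis indicator) from a clean or hemolyzed
#' distribution according to `hemolysis_rate`, plus replicate RTC and PPC
#' control Cts per sample.
#'
#' @param n number of samples (>= 1).
#' @param config a [qc_sim_config()].
#' @return A data.frame with columns sample_id, abs414, list-columns rtc_cts
#'   and ppc_cts, and the simulation truth flag `hemolyzed`.
#' @export
simulate_qc_records <- function(n, config = qc_sim_config()) {
  n <- check_count(n, "n", min = 1L)
  stopifnot(inherits(config, "qc_sim_config"))
  set.seed(child_seed(config$seed, "qc"))
  hemolyzed <- runif(n) < config$hemolysis_rate
  abs414 <- ifelse(hemolyzed,
                   rnorm(n, config$abs414_hemolyzed_mean, config$abs414_hemolyzed_sd),
                   rnorm(n, config$abs414_clean_mean, config$abs414_clean_sd))
  abs414 <- pmax(abs414, 0)
  k <- config$n_replicates
  rtc <- lapply(seq_len(n), function(i) rnorm(k, config$rtc_ct_mean, config$rtc_ct_sd))
  ppc <- lapply(seq_len(n), function(i) rnorm(k, config$ppc_ct_mean, config$ppc_ct_sd))
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), abs414 = abs414,
                    hemolyzed = hemolyzed, stringsAsFactors = FALSE)
  out$rtc_cts <- rtc
  out$ppc_cts <- ppc
  out
}

#' Write a Ct table (and its truth sidecar) as TSV
#'
#' @param x a `ct_table`.
#' @param path output TSV for the observations; the samples and truth tables
#'   are written next to it with `.samples.tsv` / `.truth.tsv` suffixes.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  write.table(x$observations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  base <- sub("\\.tsv$", "", path)
  write.table(x$samples, paste0(base, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(x$truth, paste0(base, ".truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Ct table written by [write_ct_table()]
#'
#' @param path observations TSV path.
#' @return A `ct_table` (with `config = NULL`).
#' @export
read_ct_table <- function(path) {
  obs <- read.delim(path, stringsAsFactors = FALSE)
  base <- sub("\\.tsv$", "", path)
  samples <- read.delim(paste0(base, ".samples.tsv"), stringsAsFactors = FALSE)
  truth_path <- paste0(base, ".truth.tsv")
  truth <- if (file.exists(truth_path)) read.delim(truth_path, stringsAsFactors = FALSE) else NULL
  obs$detected <- as.logical(obs$detected)
  new_ct_table(obs, samples, truth, NULL)
}
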