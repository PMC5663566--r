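#' Sample acceptance rules for plasma qPCR quality control
#'
#' Plasma samples enter the pipeline only if they pass three checks:
#' * **hemolysis** — absorbance at 414 nm strictly below 0.2 (oxyhemoglobin
#'   peak; hemolyzed plasma is contaminated by cellular miRNAs);
#' * **inhibition** — mean RTC Ct minus mean PPC Ct strictly below 7 cycles
#'   (reverse-transcription / amplification inhibition);
#' * **PPC range** — every positive-PCR-control Ct within 19 +/- 2 cycles
#'   (closed interval), indicating no contaminants or inhibition.
#'
#' @param abs414 absorbance at 414 nm (non-negative).
#' @param rtc_cts,ppc_cts numeric vectors of control-assay Cts (non-empty).
#' @return A logical flag per rule.
#' @name sample_qc
NULL

#' @rdname sample_qc
#' @export
qc_hemolysis_pass <- function(abs414) {
  if (any(!is.finite(abs414)) || any(abs414 < 0))
    stop("abs414 must be finite and non-negative", call. = FALSE)
  abs414 < 0.2
}

#' @rdname sample_qc
#' @export
qc_inhibition_pass <- function(rtc_cts, ppc_cts) {
  if (length(rtc_cts) == 0L || length(ppc_cts) == 0L)
    stop("rtc_cts and ppc_cts must be non-empty", call. = FALSE)
  mean(rtc_cts) - mean(ppc_cts) < 7
}

#' @rdname sample_qc
#' @export
qc_ppc_pass <- function(ppc_cts) {
  if (length(ppc_cts) == 0L) stop("ppc_cts must be non-empty", call. = FALSE)
  all(ppc_cts >= 17 & ppc_cts <= 21)
}

#' Apply the sample QC rules to a batch of records
#'
#' @param records data.frame with columns `sample_id`, `abs414` and
#'   list-columns `rtc_cts`, `ppc_cts` (as produced by
#'   [simulate_qc_records()]); sample ids must be unique.
#' @param checks which rules to apply; `overall_pass` is the conjunction of
#'   the requested checks.
#' @param verbose log the pass count to stderr.
#' @return data.frame with one verdict row per record: per-rule flags,
#'   `overall_pass` and a `reasons` string listing the failed rules
#'   (comma-separated, empty if none).
#' @export
apply_sample_qc <- function(records, checks = c("hemolysis", "inhibition", "ppc"),
                            verbose = FALSE) {
  checks <- match.arg(checks, several.ok = TRUE)
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in QC records", call. = FALSE)
  n <- nrow(records)
  hem <- inh <- ppc <- rep(NA, n)
  if ("hemolysis" %in% checks) hem <- qc_hemolysis_pass(records$abs414)
  if ("inhibition" %in% checks)
    inh <- vapply(seq_len(n), function(i)
      qc_inhibition_pass(records$rtc_cts[[i]], records$ppc_cts[[i]]), logical(1))
  if ("ppc" %in% checks)
    ppc <- vapply(seq_len(n), function(i)
      qc_ppc_pass(records$ppc_cts[[i]]), logical(1))
  flags <- cbind(hemolysis = hem, inhibition = inh, ppc = ppc)
  requested <- colnames(flags) %in% checks
  overall <- apply(flags[, requested, drop = FALSE], 1L, all)
  reasons <- apply(flags[, requested, drop = FALSE], 1L, function(row)
    paste(names(row)[!row], collapse = ","))
  out <- data.frame(sample_id = records$sample_id,
                    hemolysis_pass = hem, inhibition_pass = inh,
                    ppc_pass = ppc, overall_pass = overall,
                    reasons = reasons, stringsAsFactors = FALSE)
  if (verbose)
    message(sprintf("sample QC: %d/%d samples pass (%s)",
                    sum(overall), n, paste(checks, collapse = "+")))
  out
}
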