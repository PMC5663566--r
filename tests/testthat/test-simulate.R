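test_that("identical config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_control = 10, n_cancer = 8, n_targets = 40,
                       n_true_differential = 3, log2_fold_changes = 1, seed = 7)
  expect_identical(simulate_screening_cohort(cfg), simulate_screening_cohort(cfg))
  vt1 <- simulate_validation_cohort(cohort_config(n_control = 6, n_cancer = 6, seed = 7),
                                    candidate_ids = c("a", "b"), calibrator_ids = "cal")
  vt2 <- simulate_validation_cohort(cohort_config(n_control = 6, n_cancer = 6, seed = 7),
                                    candidate_ids = c("a", "b"), calibrator_ids = "cal")
  expect_identical(vt1, vt2)
  expect_identical(simulate_birads4_cohort(seed = 7), simulate_birads4_cohort(seed = 7))
  expect_identical(simulate_qc_records(20, qc_sim_config(seed = 7)),
                   simulate_qc_records(20, qc_sim_config(seed = 7)))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(detection_rate = 0), "detection_rate")
  expect_error(cohort_config(detection_rate = 1.2), "detection_rate")
  expect_error(cohort_config(within_group_ct_sd = -1), "within_group_ct_sd")
  expect_error(cohort_config(n_targets = 5, n_true_differential = 6,
                             log2_fold_changes = 1), "n_true_differential")
  expect_error(cohort_config(n_true_differential = 2), "log2_fold_changes")
  expect_error(qc_sim_config(hemolysis_rate = -0.1), "hemolysis_rate")
  expect_error(simulate_birads4_cohort(n = 3), "n")
  expect_error(simulate_birads4_cohort(malignant_fraction = 1), "malignant_fraction")
})

test_that("programmed effects shift cancer-group Ct means by -log2FC cycles", {
  cfg <- cohort_config(n_control = 500, n_cancer = 500, n_targets = 12,
                       detection_rate = 1, n_true_differential = 4,
                       log2_fold_changes = 1, ct_detection_limit = Inf, seed = 11)
  ct <- simulate_screening_cohort(cfg)
  obs <- merge(ct$observations, ct$samples, by = "sample_id")
  for (t in ct$truth$target_id[ct$truth$true_differential]) {
    sel <- obs[obs$target_id == t, ]
    diff <- mean(sel$ct[sel$group == "cancer"]) - mean(sel$ct[sel$group == "control"])
    se <- cfg$within_group_ct_sd * sqrt(1 / 500 + 1 / 500)
    expect_lt(abs(diff - (-1)), 3 * se)
  }
  # null targets have no shift
  null_t <- ct$truth$target_id[!ct$truth$true_differential][1]
  sel <- obs[obs$target_id == null_t, ]
  diff <- mean(sel$ct[sel$group == "cancer"]) - mean(sel$ct[sel$group == "control"])
  expect_lt(abs(diff), 3 * cfg$within_group_ct_sd * sqrt(2 / 500))
})

test_that("detected fraction tracks the configured detection rate", {
  cfg <- cohort_config(n_control = 30, n_cancer = 30, n_targets = 500,
                       detection_rate = 0.2, seed = 5)
  ct <- simulate_screening_cohort(cfg)
  per_sample <- tapply(ct$observations$detected, ct$observations$sample_id, mean)
  expect_lt(abs(mean(per_sample) - 0.2), 0.02)
})

test_that("validation cohort puts effects on candidates and none on calibrators", {
  cfg <- cohort_config(n_control = 200, n_cancer = 200, n_true_differential = 2,
                       log2_fold_changes = 1.5, within_group_ct_sd = 0.5, seed = 3)
  ct <- simulate_validation_cohort(cfg, candidate_ids = c("c1", "c2"),
                                   calibrator_ids = c("cel-miR-39", "hk1"))
  obs <- merge(ct$observations, ct$samples, by = "sample_id")
  gdiff <- function(t) {
    sel <- obs[obs$target_id == t, ]
    mean(sel$ct[sel$group == "cancer"]) - mean(sel$ct[sel$group == "control"])
  }
  se <- 0.5 * sqrt(2 / 200)
  expect_lt(abs(gdiff("c1") - (-1.5)), 3 * se)
  expect_lt(abs(gdiff("cel-miR-39")), 3 * se)
  expect_lt(abs(gdiff("hk1")), 3 * se)
  expect_error(simulate_validation_cohort(cfg, c("a", "b"), c("b", "cal")), "disjoint")
  # empty candidate list: calibrators only
  ct0 <- simulate_validation_cohort(cohort_config(n_control = 5, n_cancer = 5, seed = 1),
                                    character(0), c("cal1", "cal2"))
  expect_setequal(unique(ct0$observations$target_id), c("cal1", "cal2"))
})

test_that("BI-RADS 4 cohort has documented rounding, usability and noise", {
  co <- simulate_birads4_cohort(n = 62, malignant_fraction = 0.67,
                                missing_rate = 0, seed = 2)
  expect_equal(sum(co$labels == "malignant"), 42)  # round(41.54) half up
  expect_true(all(co$usable))
  expect_true(all(is.finite(co$levels)))
  expect_true(all(co$levels > 0))
  # programmed fold change on the level scale (log-normal medians)
  co2 <- simulate_birads4_cohort(n = 2000, malignant_fraction = 0.5,
                                 effects = 2.5, noise_cv = 0.2,
                                 missing_rate = 0, seed = 4)
  lfc <- mean(log(co2$levels[co2$labels == "malignant", 1])) -
    mean(log(co2$levels[co2$labels == "benign", 1]))
  expect_lt(abs(exp(lfc) - 2.5), 0.15)
  # missingness flags samples unusable
  co3 <- simulate_birads4_cohort(n = 500, missing_rate = 0.1, seed = 6)
  expect_true(any(!co3$usable))
  expect_true(all(is.na(co3$levels[which(!co3$usable)[1], ]) |
                    is.finite(co3$levels[which(!co3$usable)[1], ])))
})

test_that("QC simulation reproduces the configured hemolysis mix", {
  rec0 <- simulate_qc_records(50, qc_sim_config(hemolysis_rate = 0, seed = 1))
  expect_true(all(qc_hemolysis_pass(rec0$abs414)))
  rec1 <- simulate_qc_records(50, qc_sim_config(hemolysis_rate = 1,
                                                abs414_hemolyzed_mean = 0.5,
                                                abs414_hemolyzed_sd = 0.05, seed = 1))
  expect_false(any(qc_hemolysis_pass(rec1$abs414)))
  recm <- simulate_qc_records(1000, qc_sim_config(hemolysis_rate = 0.3, seed = 9))
  fail_frac <- mean(!qc_hemolysis_pass(recm$abs414))
  expect_lt(abs(fail_frac - 0.3), 0.05)
})

test_that("ct tables round-trip through TSV", {
  cfg <- cohort_config(n_control = 4, n_cancer = 4, n_targets = 6, seed = 3)
  ct <- simulate_screening_cohort(cfg)
  path <- file.path(tempdir(), "ct.tsv")
  write_ct_table(ct, path)
  back <- read_ct_table(path)
  expect_equal(back$observations$ct, ct$observations$ct, tolerance = 1e-9)
  expect_identical(back$observations$detected, ct$observations$detected)
  expect_identical(back$samples$group, ct$samples$group)
})
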