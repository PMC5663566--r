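---
title: "Methods: circulating miRNA signatures and BI-RADS 4 classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulating miRNA signatures and BI-RADS 4 classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmiR)
```

`plasmiR` implements a three-phase pipeline — genome-wide screening,
targeted validation, neural-network classification — for discovering a
minimal circulating-miRNA signature from plasma qPCR data and using it to
call BI-RADS category 4 breast lesions malignant or benign. This vignette
is the package's own account of the underlying models, the defaults, and
the design decisions taken where the procedure left choices open.

## Quantification model

qPCR reports a cycle threshold Ct; under ideal amplification kinetics one
cycle corresponds to one doubling of template, so abundance is exponential
in −Ct and all noise modelling is done on the Ct (log2) scale.

* **Detection.** A reaction is *detected* iff its Ct is finite and strictly
  below the detection limit (default 35 cycles, configurable; late
  amplification in plasma is dominated by primer artefacts). The boundary
  is strict: Ct = 35 is undetected.
* **Screening normalization.** Genome-wide panels have no fixed reference
  gene, so each sample is normalized against its own global mean:
  ΔCt(target) = Ct(target) − mean(Ct of that sample's detected targets),
  level = 2^−ΔCt. We implement the global mean *per sample* over detected
  targets — the convention used by array-analysis pipelines — rather than a
  grand cohort-wide mean, which could not calibrate sample-specific ΔCt at
  ~20% detection. By construction the mean ΔCt of each sample is 0 (the
  conservation property is asserted to 1e-9 in the tests). Undetected
  targets are absent from the output, not zero; a sample with no detected
  target is dropped with a warning.
* **Validation normalization.** Targeted panels carry calibrator assays: a
  spike-in (cel-miR-39 analogue, controlling extraction), designated
  references, and data-selected stable miRNAs. A candidate's level is
  2^−(Ct − mean(calibrator Cts)); the level halves exactly per +1 cycle.
* **Calibrator stability.** Reference selection re-implements the
  model-based intra/intergroup variance decomposition of the NormFinder
  method: per-sample effects are removed by centering each sample on its
  mean Ct over the scored targets; per target i and group g the intergroup
  bias d_ig (deviation of the group mean from the across-group mean) and
  the intragroup variance v_ig are estimated, and the stability score is
  mean_g(|d_ig| + sqrt(v_ig / n_g)) — lower is more stable. The score is
  invariant to per-sample offsets, penalizes group bias (a shifted target
  can never outrank an equally noisy unshifted one), and reduces to the
  intragroup SD of the group means under zero bias. Exact numeric parity
  with the proprietary NormFinder tool is not claimed. Ties at rank k are
  broken lexicographically by target id, so selection is deterministic.

## Differential calling

Group comparison uses the Mann-Whitney U test (rank-based, appropriate for
skewed 2^−ΔCt levels): exact by enumeration when the combined sample size
is ≤ 16 and tie-free, otherwise the normal approximation with tie and
continuity correction; the method used is recorded per target. Screening
p-values are adjusted by the step-up Benjamini-Hochberg procedure (the
standard choice for array screening; Bonferroni and "none" are available)
and discoveries called at adjusted p < 0.05. Validation applies the
two-part rule — fold change strictly over 1.5× and raw p strictly below
0.05 — where the fold change is the linear-scale ratio of group means and
the threshold is applied two-sidedly via max(FC, 1/FC) so under-represented
miRNAs can be selected. Targets measured in fewer than 3 samples per group
(default) are reported NA rather than tested.

## The classifier

The classification core is a from-scratch multilayer perceptron:

* **Preprocessing.** Per feature, Tukey fences Q1 − 1.5·IQR and
  Q3 + 1.5·IQR with type-7 (linear-interpolation) quartiles and a *closed*
  keep interval; training samples with any out-of-fence value are excluded
  from fitting. Remaining values are min–max standardized to [−1, +1]
  (training minimum → −1, maximum → +1); a constant feature maps to 0.
  Both fences and min/max are fitted on the training split only and reused
  verbatim on validation, test and new samples — the no-leakage property is
  asserted in the tests by refitting. New samples outside the fences are
  still scored but flagged; samples missing a feature are rejected with a
  reason, mirroring the usability filter on cohort levels.
* **Network.** Layer sizes input → hidden(s) → 1, symmetric sigmoid (tanh)
  in every layer including the output, so raw scores lie in (−1, +1).
  Classes are encoded benign = −1, malignant = +1; the decision threshold
  is 0, with the tie at exactly 0 going to benign (documented, measure-zero
  in practice). Weights initialize uniformly in [−0.5, +0.5] from the
  iteration's child seed.
* **Training.** Full-batch gradient of the mean squared error,
  backpropagated analytically (verified against central finite differences
  to relative error < 1e-6 on random topologies), with iRPROP− updates:
  per-weight steps grow ×1.2 (cap 50) while the gradient keeps its sign,
  shrink ×0.5 (floor 1e-6) on a sign flip — in which case the gradient is
  zeroed and that weight does not move that epoch — and start at Δ₀ = 0.1.
  These are the de-facto standard resilient-backpropagation constants; the
  initial-step/zero-product behaviour is pinned by a hand-stepped trace on
  f(w) = w² in the tests.
* **Early stopping.** After each epoch the validation MSE is evaluated;
  the best-so-far weights are retained and returned. Training stops at
  5,000 epochs or once validation error has not improved for 50 epochs
  (patience). Patience 0 degenerately returns the initialization; the
  returned validation error always equals the minimum of the validation
  trace.
* **Topology search.** Each iteration draws a hidden-layer count in 1–3 and
  widths in 1–10 (configurable), a fresh stratified 60/20/20 split
  (validation and test take floor(0.2·n) per class, remainder to training:
  60 → 36/12/12, 62 → 38/12/12), trains with early stopping, and is scored
  by validation error. The winner is best-by-validation; its test metrics
  are reported but never used for selection (selecting on test would be
  leakage). The published-scale search uses 10,000 draws; the package
  default is 200, which the acceptance runs show is ample at the cohort
  sizes involved. A full leaderboard (topology, seed, validation error,
  test accuracy, epochs) is retained. The master seed fully determines the
  winner; child seeds for topology, split and initialization are derived
  deterministically.

Whether pooled (all-data) metrics or held-out test metrics are the right
headline is ambiguous in practice; the package reports both, clearly
labelled. Pooled metrics include the training split and are optimistic.

## Evaluation

Confusion matrices count malignant as positive. Accuracy = (TP+TN)/total,
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP); zero-denominator
metrics are *undefined* (NA), never 0. LR+ = sens/(1−spec) and
LR− = (1−sens)/spec, with boundary infinities reported as such. The ROC is
built by sweeping all score thresholds with trapezoid integration; tied
scores give diagonal segments, making the AUC identical to the rank
formulation U/(n1·n0) with midranks (asserted to 1e-9, and cross-checked
against an independent implementation). Covariate association uses the
Pearson product-moment correlation with the t-transform p-value.

## What the synthetic cohorts emulate

The generators define the study conditions under which everything above is
tested:

* **Screening cohort** (defaults): 72 controls vs 46 cancer samples,
  1,805 targets, per-target baseline Ct ~ N(28, 2²) cycles, within-group
  SD 0.8 cycles (inter-subject variability typical of pre-amplified
  targeted plasma qPCR), detection limit 35 cycles plus independent
  dropout so ~20% of the panel is detected per sample. A truly
  differential target with log2 fold change f has its cancer-group mean
  Ct shifted by −f cycles. Ct noise is Gaussian on the Ct scale — the
  standard qPCR kinetics assumption.
* **Validation cohort**: 29 vs 29 samples over candidates plus calibrators;
  calibrators (including the spike-in analogue) carry zero programmed
  effect; targeted assays detect by the Ct limit alone. Linear-scale CV is
  mapped to Ct-scale SD by `cv_to_ct_sd()` (sqrt(log(1+cv²))/log 2).
* **BI-RADS 4 cohort**: n = 62 with 67% malignant (the malignant count is
  round-half-up, so 62 × 0.67 → 42), log-normal 2^−ΔCt levels for the
  three signature miRNAs at CV 20%, malignant levels multiplied by the
  fold change (default 2.5), and a 3% per-measurement missing rate whose
  affected samples are flagged unusable (≈97% usable), matching the
  usability filtering the classifier stage applies.

Not emulated: plate/batch and array-position effects, pre-amplification
bias, PCR efficiency differences (no Pfaffl correction anywhere — plain
2^−ΔCt), correlated co-regulation between miRNAs, and covariate structure
(age, BMI). Passing tests on these cohorts therefore demonstrate the
*procedure* — calibration, power, leak-freedom, determinism — not clinical
performance on real plasma, where effect sizes are smaller and noise is
structured.

## Problem sizes and runtime choices

The test suite and acceptance script run the screening phase at full study
scale (118 samples × 1,805 targets), null calibration at 1,000 targets ×
20 replicates, validation recovery over 50 replicates, and topology
searches of 200 iterations over 20 master seeds — sizes chosen so the whole
suite completes in minutes on a single CPU while keeping every Monte-Carlo
check at ≥ 20 replicates. The training inner loop is compiled (C++); an
independent R implementation of the forward pass, backpropagation and
iRPROP− lives in the test helpers and pins the compiled path exactly.

## Known limitations

* The screening power and false-discovery behaviour depend on the assumed
  within-group SD (0.8 cycles) and the independence of targets; real
  miRNome data are correlated, which BH tolerates but the Monte-Carlo
  calibration here does not model.
* Global-mean normalization redistributes strong signals: with many
  differential targets the null targets acquire a small compensatory
  shift. At the study's effect sizes this is negligible, but it is a known
  property of the method, not a bug.
* On zero-signal cohorts the topology-search winner does not collapse
  fully onto the majority class: early-stopped noise fitting leaves a
  fraction of effectively random predictions, so its held-out accuracy
  centers on the no-information value q·p + (1−q)·(1−p) given its marginal
  prediction rate q — slightly *below* the majority rate, not at it. The
  null calibration therefore checks (i) that the classifier never beats
  the majority rate beyond binomial noise (no spurious skill) and (ii)
  that its accuracy is consistent with predictions independent of truth.
* The stability decomposition is a faithful re-implementation of the
  published variance model but is not bit-identical to the proprietary
  NormFinder software.
* Counts reported by real studies of this design vary slightly between
  sections (e.g. 46 over- plus 9 under-represented against a stated total
  of 57); the pipeline treats all such counts as data-driven outputs, never
  as constants to reproduce.
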