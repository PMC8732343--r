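---
title: "Processing and analyzing digital spatial profiling protein panels"
author: "dspTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and analyzing digital spatial profiling protein panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspTools)
```

## The assay and the analysis problem

Digital spatial profiling (DSP) quantifies dozens of proteins at once in
formalin-fixed tissue: antibodies carry photocleavable oligonucleotide
barcodes, UV light releases the barcodes from a chosen region of interest
(ROI), and the released barcodes are digitally counted. On a tissue
microarray (TMA) of breast tumors, each core is split by a pan-cytokeratin
immunofluorescence mask into a tumor ROI and a stroma ROI, so every patient
contributes paired compartment measurements for every marker in the panel.

Raw barcode counts are not comparable across ROIs: collection efficiency,
segment area and hybridization vary. Nor are they comparable across markers:
each antibody has its own nonspecific binding background. The panel
therefore carries two classes of control alongside the experimental
antibodies: spike-in positive controls (external synthetic sequences, the
ERCC class) that track per-ROI technical yield, and isotype negative
controls (non-targeting antibodies of the relevant host IgG classes) that
measure nonspecific binding in the same ROI.

`dspTools` implements the full processing chain on top of
`SummarizedExperiment`: markers are rows, ROIs are columns, the panel
manifest lives in `rowData`, the ROI-to-patient map in `colData`, and a
stage tag in `metadata()` enforces the order of operations.

## The processing chain

**Spike-in normalization** (`normalizeSpikeIn`). Every ROI is scaled by
`reference / s(roi)`, where `s(roi)` is the geometric mean of the ROI's
spike-in counts and the reference is the across-ROI geometric mean of those
summaries. The geometric mean is the natural summary for multiplicative
technical effects, and anchoring to the cohort geometric mean leaves the
overall scale unchanged. A housekeeping-based alternative
(`normalizeHousekeeping`) is provided for comparison but is not the
default: housekeeping proteins carry biology of their own.

**Signal-to-noise** (`computeSNR`). Each normalized count is divided by the
geometric mean of the negative-control counts in the same ROI, giving a
dimensionless signal-to-noise ratio (SNR) that absorbs both segment-area
differences and nonspecific IgG binding. Whether the original analysis
pooled the three isotype controls or matched each antibody to its host
class is not recoverable from the methods text; pooling is the stable
default with only three controls, and `snr_denominator =
"isotype_matched"` switches to host-matched denominators.

**Detection filter** (`detectionFilter`). An SNR of 3 is treated as the
lower detection limit. A marker is dropped when strictly more than 50% of
its ROI-level values fall below 3 in the tumor ROIs or in the stroma ROIs,
considered separately — a marker robust in one compartment but absent in
the other is removed, because every downstream analysis uses both. The
"values" in this rule are read at ROI level, not patient level; the
boundary (exactly 50%) retains. Controls are exempt but reported. Note a
consequence: a retained marker can still have many sub-threshold values
(up to half per compartment), but a marker whose *patient-mean median*
sits at the floor in some compartment cannot pass the rule, so the
synthetic panel gives every robust analyte a clearly detectable median in
both compartments.

**Floor imputation** (`imputeFloor`). Values below 3 are replaced by the
single constant 3/√2 ≈ 2.1213 — a standard half-distance stand-in for
sub-detection signal (3 divided by √2, the convention used for values
below a limit of detection). A fully floored group therefore prints as
median 2.12 with IQR 0.00. The operation is idempotent, and the
pre-imputation detection flags are preserved for downstream tie handling.

**Batch calibration** (`calibrateBatches`). TMA slides stained in separate
batches (fresh-cut vs stored sections) show a global SNR shift. Per marker,
the package fits a linear mixed model `log2(SNR) ~ 1 + (1 | batch)` by REML
on the detected (above-floor) cells only, takes the centered conditional
modes of the batch effects as additive log2 correction factors, and
subtracts them from the detected cells, re-applying the floor afterwards.
Floored cells are never moved: the imputation constant must stay
batch-invariant, otherwise the floor would encode batch membership. The
order floor-then-calibrate (with floored cells excluded from the fit) was
chosen for exactly this reason; calibrating first would move sub-threshold
values across the detection boundary and make the filter batch-dependent.
Applying the calibration twice is a no-op: after subtraction the residual
between-batch variance collapses to the boundary estimate of zero. A
marker with fewer than two detected values in a batch gets a zero
correction for that batch, with a warning.

**Patient aggregation** (`aggregatePatients`). Most patients contribute
several cores; their calibrated SNR values are averaged per (patient,
marker, compartment) on the linear scale — the log transform is reserved
for test statistics and plots, so reported medians stay on the scale of
the published tables. Patients without a stromal compartment (five in the
emulated design) simply lack stroma columns; they are excluded pairwise by
the paired analyses rather than imputed.

**Replicate concordance** (`replicateConcordance`). Repeat runs on adjacent
TMA sections are compared by per-marker Spearman correlation over shared
patients, summarized per compartment as median and range.

## The statistical layer

All tests run on log2 scores; all reported medians and IQRs are on the
linear SNR scale. Each Benjamini–Hochberg family is recorded in the result
rows (`family`, `family_size`) and is never mixed across comparisons: the
paired tumor-vs-stroma comparison forms a single family across markers,
while every group comparison (ER status, HER2 status, race) forms one
family per compartment, mirroring the separate q-value columns of the
published table layouts.

- `compareCompartments`: paired t-test over patients carrying both
  compartments; markers with fewer than three complete pairs are skipped.
- `compareGroups`: two-sample t-test by default; when more than 20% of
  either group sits exactly at the imputation floor the Wilcoxon rank-sum
  test is used instead (`method = "auto"`), since the floor creates a tie
  mass that violates the t-test's assumptions. Both tests are always
  available by explicit flag. Fully tied input returns p = 1.
- `ancovaRace`: per marker, `log2(score) ~ race + subtype + grade +
  bmi_category` on listwise-complete cases, sum-to-zero contrasts, race
  main effect by Type III F-test (the convention of the statistics system
  the original analysis was run in). `covariates = character(0)` gives the
  unadjusted one-way ANOVA.
- `correlateScores` / `erCorrelationScreen`: Pearson correlation of log2
  scores, used alike for cross-platform concordance
  (immunohistochemistry, gene expression) and for the continuous
  ER-vs-immune analysis. DSP scores are floored and never zero; external
  platform scores may contain zeros and get a +1 offset on that side only.
- `anovaVsCategorical`: one-way ANOVA of log2 scores across categorical
  platform scores (e.g. HER2 immunohistochemistry levels 0–3), with
  per-category summaries for boxplots.

## Survival screening

`runSurvivalScreen` dichotomizes each marker at the median of the
follow-up-available patients (values at or above the median are "high";
when the median coincides with the floor the strict rule is used so the
floor mass forms the low group — otherwise the low group would be empty),
then runs a two-group log-rank test per marker and compartment for overall
survival and breast-cancer-specific survival (non-breast-cancer deaths
censored). P-values are reported unadjusted: the screen is exploratory by
design and applies no multiplicity correction. The follow-up clock is a
single origin field; the methods text gives both enrollment and diagnosis
as origins, and the package simply consumes the follow-up times it is
given. Zero-event strata are reported as undefined rather than zero.

## Unsupervised views

`clusterHeatmap` z-scores rows (excluding constant rows with a warning)
and clusters rows and columns by Euclidean distance with Ward linkage —
the common defaults of the heatmap tooling this output feeds; both are
configurable, and the numeric outputs (merge heights, leaf orders) rather
than rendered pixels are the tested surface. `pcaCheck` returns leading
principal-component scores with a fixed sign convention (largest-magnitude
loading positive, so results do not depend on observation order) and a
separation statistic — the between-group share of component-1 variance —
used to verify that batch calibration removes the batch structure.

## The synthetic cohort generator

`simulateCohort` emits the raw-data shape the pipeline consumes (counts,
manifest, ROI map, clinical table) plus a truth table, so every stage is
testable without any external download. Counts follow a log-normal law
rounded to integers — the analysis is entirely log2-based and no count law
is identifiable from it; a Poisson final step and an unrounded path are
available (`count_law`). The log2 signal of an experimental marker is

    background + base + compartment_shift·[stroma] + race_shift·[Black]
    + er_coef·(er_score − center) + batch_offset + patient + core + noise

multiplied by a per-ROI technical factor; negative controls draw from the
background law alone and spike-ins encode the technical factor. Technical
factors are normalized to geometric mean 1, which makes spike-in
normalization exactly invertible — the basis of the recoverability check.

Defaults encode the emulated study: 159 patients, 59.1% Black, ER-positive
fractions 59/94 and 53/65 by race, 1–5 cores per patient with 75% having
at least two, five patients without stroma, two staining batches (one
third of patients in the fresh-cut batch) separated by 1.5 log2 units, a
58-marker panel (52 experimental, 3 spike-ins, 3 isotype controls) of
which 19 are low-signal by construction, a −0.8 log2 race shift on the
B7-H3 analogue (the value implied by the reported group medians), negative
ER couplings on the immune analytes, and survival coupled to one marker
with a follow-up subset of 136/159. ER is simulated as a continuous log2
score with status-specific distributions, so both the dichotomous and the
continuous ER analyses are exercisable. The within-patient between-core
variance is not identifiable from the published summaries; its default
(0.25 log2 units) is a free parameter, not an estimate. The replicate-run
noise default (0.18 log2 units) represents adjacent-section assay noise
and puts the median patient-level Spearman rho near 0.96–0.97. Replicates
share the original run's *realized* latent signal — adjacent sections
carry the same biology — with independent noise on top, so a zero-noise
replicate equals the original exactly.

What the generator does **not** emulate: spatial coordinates or
segmentation masks (compartments are labels), marker–marker correlation
beyond the shared ER axis, heavy-tailed count noise, antibody-specific
saturation, or missing-at-random clinical covariates. Passing tests
therefore demonstrate that the chain of operations is implemented
correctly and recovers known structure under the stated noise model — not
that it is robust to every pathology of real staining data.

`simulateProfiles` generates the per-patient, per-compartment mean-score
resolution directly (the deposited-table analogue, 33 analytes after
filtering) and is used for the calibration and power studies, where the
ROI layer would only add runtime.

## Numerical choices and problem sizes

Detection threshold 3 (dimensionless SNR), floor 3/√2, filter fraction 0.5
(strict), FDR level 0.05: all surfaced in `qcParams()` and the analysis
functions. Exact Wilcoxon is used where R's default applies it (small
untied samples), the normal approximation with continuity correction
otherwise. Degenerate inputs are handled explicitly: constant paired
differences give a divergent statistic with p = 0 (all-zero differences
give p = 1), fully tied group comparisons give p = 1, zero-event survival
strata are undefined, constant rows are excluded from z-scored clustering.

The validation suites run at deliberately chosen sizes: oracle equality on
20×10 random instances; batch recovery on a 300-ROI two-batch design with
a 1.5 log2 offset (tolerance ±0.1); null calibration with 2000 replicate
markers (size within three binomial standard errors of 0.05); race-effect
power over 200 simulated cohorts at study size (≥90% detection of the
B7-H3 analogue in both compartments with essentially no other
discoveries); log-rank size and power over 500 seeds at n = 200;
compartment clustering recovery at adjusted Rand index > 0.9.

## Known limitations

The package consumes compartment labels and per-ROI counts; it does not
touch images, segmentation or instrument-native formats. Cores are
averaged before statistics, so no mixed model is fitted at the patient
level (matching the emulated design). No Cox regression or competing-risks
analysis is provided. Exact reproduction of the original cohort's numbers
requires that study's deposited per-patient table, which ships with the
original publication, not with this package; `readPatientProfileTable`
reads that one-row-per-patient-and-compartment layout so the differential
layer can be applied to it directly.
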