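test_that("spike-in normalization follows the geometric-mean formula", {
  mani <- tinyManifest()
  # identical spike-ins in every ROI: output equals input
  m <- tinyCounts(4)
  m[, c("PC1", "PC2")] <- 50
  dsp <- DspExperiment(m, mani, roiData = tinyRoiMap(rownames(m)))
  norm <- normalizeSpikeIn(dsp)
  expect_equal(SummarizedExperiment::assay(norm, "counts"),
               SummarizedExperiment::assay(dsp, "counts"))
  expect_identical(dspStage(norm), "spikein_normalized")

  # one ROI with spike-ins at exactly 2x the reference is halved:
  # with the other three ROIs at 50, setting r1 to 50 * 2^(4/3) makes
  # s(r1)/reference = 2^(4/3 * 3/4) = 2
  m2 <- m
  m2["r1", c("PC1", "PC2")] <- 50 * 2^(4 / 3)
  dsp2 <- DspExperiment(m2, mani, roiData = tinyRoiMap(rownames(m2)))
  norm2 <- normalizeSpikeIn(dsp2)
  s <- exp(colMeans(log(t(m2[, c("PC1", "PC2")]))))
  ref <- exp(mean(log(s)))
  expect_equal(s[["r1"]] / ref, 2, tolerance = 1e-12)
  expect_equal(SummarizedExperiment::assay(norm2, "counts")["A", "r1"],
               m2["r1", "A"] / 2, tolerance = 1e-12)

  # zero spike-in summary is fatal with the ROI named
  m3 <- m
  m3["r3", c("PC1", "PC2")] <- 0
  dsp3 <- DspExperiment(m3, mani, roiData = tinyRoiMap(rownames(m3)))
  expect_error(normalizeSpikeIn(dsp3), "r3")
})

test_that("spike-in normalization recovers generator truth at zero noise", {
  cfg <- dspSimConfig(n_patients = 30, n_no_stroma = 0, seed = 17,
                      noise_sd = 0, count_law = "none")
  co <- simulateCohort(cfg)
  norm <- normalizeSpikeIn(co$dsp)
  rec <- SummarizedExperiment::assay(norm, "counts")
  truth <- co$truth$pre_tech_counts
  rel <- abs(rec - truth) / truth
  expect_lt(max(rel), 1e-9)
})

test_that("SNR computation matches the definition and the oracle", {
  mani <- tinyManifest()
  # marker equal to the negative-control geometric mean gives SNR 1;
  # controls (4, 8, 16)-style forced arithmetic gives SNR 3
  m <- tinyCounts(2)
  m[1, c("NC1", "NC2")] <- c(4, 16)       # geometric mean 8
  m[1, "A"] <- 8                           # SNR 1
  m[1, "B"] <- 24                          # SNR 3
  dsp <- DspExperiment(m, mani, roiData = tinyRoiMap(rownames(m)))
  snr <- computeSNR(dsp, qcParams(normalization_mode = "none"))
  a <- SummarizedExperiment::assay(snr, "snr")
  expect_equal(a["A", "r1"], 1, tolerance = 1e-12)
  expect_equal(a["B", "r1"], 3, tolerance = 1e-12)
  expect_false(any(rownames(snr) %in% c("NC1", "NC2")))
  expect_true(SummarizedExperiment::assay(snr, "detected")["B", "r1"])

  # random matrix against the brute-force per-cell oracle
  set.seed(42)
  big <- matrix(runif(20 * 10, 5, 500), nrow = 20)
  mani10 <- data.frame(
    marker_id = paste0("m", 1:10),
    marker_class = c(rep("experimental", 7), "positive_control",
                     "negative_control", "negative_control"))
  colnames(big) <- mani10$marker_id
  rownames(big) <- paste0("roi", 1:20)
  dspB <- DspExperiment(big, mani10, roiData = tinyRoiMap(rownames(big)))
  snrB <- computeSNR(dspB, qcParams(normalization_mode = "none"))
  want <- oracleSnr(t(big), paste0("m", 1:8), c("m9", "m10"))
  expect_equal(SummarizedExperiment::assay(snrB, "snr"), want,
               tolerance = 1e-12)
})

test_that("isotype-matched SNR uses the matching control only", {
  mani <- tinyManifest()
  m <- tinyCounts(2)
  m[, "NC1"] <- 4    # IgG1
  m[, "NC2"] <- 16   # IgG2a
  m[, "A"] <- 12     # IgG1-hosted
  m[, "B"] <- 12     # IgG2a-hosted
  dsp <- DspExperiment(m, mani, roiData = tinyRoiMap(rownames(m)))
  snr <- computeSNR(dsp, qcParams(normalization_mode = "none",
                                  snr_denominator = "isotype_matched"))
  a <- SummarizedExperiment::assay(snr, "snr")
  expect_equal(unname(a["A", ]), c(3, 3))
  expect_equal(unname(a["B", ]), c(0.75, 0.75))
})

test_that("detection filter applies the either-compartment >50% rule", {
  # 10 tumor and 10 stroma ROIs, hand-built SNR patterns
  mani <- data.frame(
    marker_id = c("allgood", "tumorbad", "edge", "NC"),
    marker_class = c(rep("experimental", 3), "negative_control"))
  n <- 20
  roi <- tinyRoiMap(paste0("r", 1:n),
                    compartments = rep(c("tumor", "stroma"), each = 10))
  counts <- matrix(10, n, 4, dimnames = list(roi$roi_id, mani$marker_id))
  counts[, "NC"] <- 1
  # tumorbad: 6 of 10 tumor values below 3, stroma all fine
  counts[1:6, "tumorbad"] <- 2
  # edge: exactly 50% below threshold in each compartment -> retained
  counts[1:5, "edge"] <- 2
  counts[11:15, "edge"] <- 2
  dsp <- DspExperiment(counts, mani, roiData = roi)
  snr <- computeSNR(dsp, qcParams(normalization_mode = "none"))
  flt <- detectionFilter(snr)
  expect_setequal(flt$retained, c("allgood", "edge"))
  expect_setequal(flt$dropped, "tumorbad")
  expect_true(flt$report$fails_rule[flt$report$marker_id == "tumorbad"])

  # an empty compartment is skipped with a warning, not treated as failing
  tum_only <- dsp[, roi$compartment == "tumor"]
  snr_t <- computeSNR(tum_only, qcParams(normalization_mode = "none"))
  expect_warning(flt_t <- detectionFilter(snr_t), "stroma")
  expect_true("allgood" %in% flt_t$retained)
})

test_that("floor imputation replaces sub-threshold values exactly", {
  mani <- tinyManifest()
  m <- tinyCounts(4)
  m[, c("NC1", "NC2")] <- 1
  m[1, "A"] <- 2.5   # below threshold
  m[2, "A"] <- 3.0   # boundary: unchanged (rule is strictly < 3)
  dsp <- DspExperiment(m, mani, roiData = tinyRoiMap(rownames(m)))
  snr <- computeSNR(dsp, qcParams(normalization_mode = "none"))
  flt <- detectionFilter(snr)
  floored <- imputeFloor(flt$object)
  a <- SummarizedExperiment::assay(floored, "snr")
  expect_identical(a["A", "r1"], 3 / sqrt(2))
  expect_identical(a["A", "r2"], 3.0)
  # detected flags are preserved from the pre-floor state
  expect_false(SummarizedExperiment::assay(floored, "detected")["A", "r1"])
  expect_true(SummarizedExperiment::assay(floored, "detected")["A", "r2"])
  # idempotent
  again <- imputeFloor(floored)
  expect_identical(SummarizedExperiment::assay(again, "snr"), a)
  # a fully floored group's rounded median/IQR collapse to 2.12 (0.00)
  vals <- rep(3 / sqrt(2), 20)
  expect_equal(round(median(vals), 2), 2.12)
  expect_equal(round(IQR(vals), 2), 0)
})

test_that("stage tags enforce the pipeline order", {
  dsp <- tinyDsp()
  expect_error(computeSNR(dsp), "stage")
  norm <- normalizeSpikeIn(dsp)
  expect_error(normalizeSpikeIn(norm), "stage")
  snr <- computeSNR(norm)
  expect_error(imputeFloor(snr), "detectionFilter")
  expect_error(aggregatePatients(norm), "SNR-stage")
})

test_that("single-batch calibration is the identity", {
  co <- simulateCohort(smallSimConfig(seed = 2, batch1_fraction = 1))
  snr <- computeSNR(normalizeSpikeIn(co$dsp))
  flt <- detectionFilter(snr)
  floored <- imputeFloor(flt$object)
  cal <- suppressWarnings(calibrateBatches(floored))
  expect_true(all(cal$calibration$corrections == 0))
  expect_equal(SummarizedExperiment::assay(cal$object, "snr"),
               SummarizedExperiment::assay(floored, "snr"))
})

test_that("two-batch calibration recovers the configured offset", {
  cfg <- dspSimConfig(n_patients = 150, n_no_stroma = 0, seed = 31,
                      panel = flatPanel(n_markers = 5, base = 5, shift = 0),
                      cores_per_patient_probs = c(1, 0, 0, 0, 0),
                      batch_offsets = c(0.75, -0.75),
                      patient_sd = 0.1, core_sd = 0, noise_sd = 0.05,
                      nc_log2_sd = 0.05, tech_log2_sd = 0.1)
  co <- simulateCohort(cfg)   # 150 single-core patients x 2 ROIs = 300 ROIs
  qcp <- qcParams()
  snr <- computeSNR(normalizeSpikeIn(co$dsp), qcp)
  flt <- detectionFilter(snr, qcp)
  floored <- imputeFloor(flt$object, qcp)
  cal <- calibrateBatches(floored, qcp)
  corr <- cal$calibration$corrections[paste0("M", 1:5), ]
  # the correction undoes the batch offset: -(+0.75) for B1, +0.75 for B2
  expect_true(all(abs(corr[, "B1"] - (-0.75)) < 0.1))
  expect_true(all(abs(corr[, "B2"] - 0.75) < 0.1))
  # post-calibration per-batch marker means agree
  a <- log2(SummarizedExperiment::assay(cal$object, "snr"))
  batch <- SummarizedExperiment::colData(cal$object)$batchId
  for (m in paste0("M", 1:5)) {
    mu <- tapply(a[m, ], batch, mean)
    expect_lt(abs(diff(mu)), 0.05)
  }
  # corrections sum to ~0 across batches
  expect_true(all(abs(rowSums(corr)) < 1e-8))
  # idempotence: re-calibration is a no-op
  cal2 <- calibrateBatches(cal$object, qcp)
  expect_true(all(abs(cal2$calibration$corrections) < 1e-12))
  expect_equal(SummarizedExperiment::assay(cal2$object, "snr"),
               SummarizedExperiment::assay(cal$object, "snr"),
               tolerance = 1e-12)
})

test_that("calibration never moves floored cells or crosses the floor", {
  co <- simulateCohort(smallSimConfig(seed = 23))
  qcp <- qcParams()
  snr <- computeSNR(normalizeSpikeIn(co$dsp), qcp)
  flt <- detectionFilter(snr, qcp)
  floored <- imputeFloor(flt$object, qcp)
  cal <- suppressWarnings(calibrateBatches(floored, qcp))
  a <- SummarizedExperiment::assay(cal$object, "snr")
  det <- SummarizedExperiment::assay(cal$object, "detected")
  expect_true(all(a[!det] == qcp$floor_value))
  expect_true(all(a >= qcp$floor_value - 1e-12))
})

test_that("patient aggregation equals the brute-force group mean", {
  # two ROIs with values 10 and 20 average to 15
  mani <- data.frame(marker_id = c("A", "NC"),
                     marker_class = c("experimental", "negative_control"))
  counts <- matrix(c(10, 20, 1, 1), 2, 2,
                   dimnames = list(c("r1", "r2"), c("A", "NC")))
  roi <- tinyRoiMap(c("r1", "r2"), patients = c("P1", "P1"),
                    compartments = c("tumor", "tumor"))
  dsp <- DspExperiment(counts, mani, roiData = roi)
  snr <- computeSNR(dsp, qcParams(normalization_mode = "none"))
  prof <- aggregatePatients(snr)
  expect_equal(unname(profileMatrix(prof, "tumor")["P1", "A"]), 15)
  expect_equal(unname(SummarizedExperiment::assay(prof, "nROIs")[1, 1]), 2)

  # random instance against the looped oracle
  set.seed(7)
  n <- 24
  vals <- matrix(runif(5 * n, 1, 50), nrow = 5,
                 dimnames = list(paste0("m", 1:5), paste0("r", 1:n)))
  pat <- sample(paste0("P", 1:6), n, replace = TRUE)
  comp <- sample(c("tumor", "stroma"), n, replace = TRUE)
  mani5 <- data.frame(marker_id = c(paste0("m", 1:5), "NC"),
                      marker_class = c(rep("experimental", 5),
                                       "negative_control"))
  counts <- rbind(vals, NC = 1)
  roi <- data.frame(roi_id = paste0("r", 1:n), patient_id = pat,
                    core_id = paste0("c", 1:n), compartment = comp,
                    batch_id = "B1")
  dsp <- DspExperiment(t(counts), mani5, roiData = roi)
  snr <- computeSNR(dsp, qcParams(normalization_mode = "none"))
  prof <- aggregatePatients(snr)
  want <- oracleAggregate(vals, pat, comp)
  got <- SummarizedExperiment::assay(prof, "score")
  expect_equal(got[, colnames(want)], want, tolerance = 1e-12)

  # conservation: aggregating a constant matrix returns that constant
  countsK <- matrix(c(rep(8, n), rep(1, n)), ncol = 2,
                    dimnames = list(paste0("r", 1:n), c("m1", "NC")))
  dspK <- DspExperiment(countsK,
                        data.frame(marker_id = c("m1", "NC"),
                                   marker_class = c("experimental",
                                                    "negative_control")),
                        roiData = roi)
  profK <- aggregatePatients(computeSNR(dspK,
                                        qcParams(normalization_mode = "none")))
  expect_true(all(SummarizedExperiment::assay(profK, "score") == 8))
})

test_that("replicate concordance is a rank statistic", {
  tum <- matrix(runif(40, 1, 50), 10, 4,
                dimnames = list(paste0("P", 1:10), paste0("m", 1:4)))
  prof1 <- profileFromMatrices(tum)
  # identical runs: rho = 1 everywhere
  rc <- suppressWarnings(replicateConcordance(prof1, prof1))
  expect_true(all(abs(rc$per_marker$rho - 1) < 1e-12))
  # a monotone transform leaves rho at 1
  prof2 <- profileFromMatrices(tum^1.7 + 2)
  rc2 <- suppressWarnings(replicateConcordance(prof1, prof2))
  expect_true(all(abs(rc2$per_marker$rho - 1) < 1e-12))
  # simulated replicate summary equals a direct rank-correlation oracle
  co <- simulateCohort(smallSimConfig(seed = 12))
  repl <- simulateReplicateRun(co, noise_sd = 0.3)
  p1 <- suppressWarnings(processCohort(co$dsp))$profile
  p2 <- suppressWarnings(processCohort(repl))$profile
  rc3 <- replicateConcordance(p1, p2)
  m1 <- profileMatrix(p1, "tumor")
  m2 <- profileMatrix(p2, "tumor")
  want <- vapply(colnames(m1), function(m) {
    cor(m1[, m], m2[rownames(m1), m], method = "spearman")
  }, numeric(1))
  got <- rc3$per_marker[rc3$per_marker$compartment == "tumor", ]
  expect_equal(got$rho[match(names(want), got$marker_id)], unname(want),
               tolerance = 1e-12)
})
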