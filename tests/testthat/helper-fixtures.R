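# Shared fixtures: a toy panel, toy count matrices and small simulation
# configurations. Everything is built in code; nothing is read from disk.

tinyManifest <- function() {
  data.frame(
    marker_id = c("A", "B", "C", "PC1", "PC2", "NC1", "NC2"),
    display_name = c("A", "B", "C", "PC1", "PC2", "NC1", "NC2"),
    marker_class = c("experimental", "experimental", "experimental",
                     "positive_control", "positive_control",
                     "negative_control", "negative_control"),
    isotype = c("IgG1", "IgG2a", "IgG1", NA, NA, "IgG1", "IgG2a"),
    stringsAsFactors = FALSE)
}

tinyRoiMap <- function(roi_ids, patients = NULL, compartments = NULL,
                       batches = "B1") {
  n <- length(roi_ids)
  data.frame(
    roi_id = roi_ids,
    patient_id = if (is.null(patients)) paste0("P", seq_len(n)) else patients,
    core_id = paste0("c", seq_len(n)),
    compartment = if (is.null(compartments))
      rep(c("tumor", "stroma"), length.out = n) else compartments,
    batch_id = rep(batches, length.out = n),
    replicate_id = "R1",
    stringsAsFactors = FALSE)
}

tinyCounts <- function(n_roi = 4, seed = 1) {
  set.seed(seed)
  mani <- tinyManifest()
  m <- matrix(round(runif(n_roi * nrow(mani), 10, 100)), nrow = n_roi,
              dimnames = list(paste0("r", seq_len(n_roi)), mani$marker_id))
  m
}

tinyDsp <- function(n_roi = 4, seed = 1, batches = "B1", ...) {
  m <- tinyCounts(n_roi, seed)
  DspExperiment(m, tinyManifest(),
                roiData = tinyRoiMap(rownames(m), batches = batches, ...))
}

# A small cohort configuration for fast end-to-end tests.
smallSimConfig <- function(seed = 1, ...) {
  dspSimConfig(n_patients = 40, n_no_stroma = 2, seed = seed, ...)
}

# A flat panel with no race/ER structure, for clean parameter-recovery runs.
flatPanel <- function(n_markers = 6, base = 5, shift = 1) {
  exper <- data.frame(
    marker_id = paste0("M", seq_len(n_markers)),
    tumor_median = 2^base, stroma_median = 2^(base + shift),
    er_coef = 0, race_shift = 0, hazard_coef = 0,
    marker_class = "experimental", stringsAsFactors = FALSE)
  ctrl <- data.frame(
    marker_id = c("PCa", "PCb", "PCc", "NCa", "NCb", "NCc"),
    tumor_median = NA_real_, stroma_median = NA_real_,
    er_coef = 0, race_shift = 0, hazard_coef = 0,
    marker_class = rep(c("positive_control", "negative_control"), each = 3),
    stringsAsFactors = FALSE)
  panel <- rbind(exper, ctrl)
  panel$base_log2 <- log2(panel$tumor_median)
  panel$comp_shift <- log2(panel$stroma_median) - log2(panel$tumor_median)
  panel$display_name <- panel$marker_id
  panel$isotype <- rep(c("IgG1", "IgG2a", "Rb"), length.out = nrow(panel))
  panel$isotype[panel$marker_class == "negative_control"] <-
    c("IgG1", "IgG2a", "Rb")
  panel
}

# Build a PatientProfile directly from per-compartment matrices
# (patients x markers).
profileFromMatrices <- function(tumor, stroma = NULL) {
  mk <- colnames(tumor)
  score <- t(tumor)
  pid <- rownames(tumor)
  comp <- rep("tumor", length(pid))
  if (!is.null(stroma)) {
    score <- cbind(score, t(stroma))
    pid <- c(pid, rownames(stroma))
    comp <- c(comp, rep("stroma", nrow(stroma)))
  }
  colnames(score) <- paste(pid, comp, sep = ".")
  n <- matrix(1, nrow(score), ncol(score), dimnames = dimnames(score))
  PatientProfile(score, n, patientId = pid, compartment = comp)
}
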