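## Synthetic cohort generator. Emits ROI-level count tables, clinical and
## ROI-map tables, and a ground-truth table with the statistical structure
## the analysis assumes: tumor/stroma compartment shifts, an ER-immune
## anticorrelation, a race shift on the B7-H3 analogue, per-batch offsets,
## per-ROI technical factors recoverable by spike-in normalization, and
## survival coupled to marker levels. A patient-profile-level generator
## (the per-patient mean-score resolution of the deposited dataset) is also
## provided for fast calibration/power simulations.

#' Default synthetic antibody panel
#'
#' A 58-marker panel: 33 robust experimental analytes whose tumor/stroma
#' abundances follow the magnitudes typical of breast-tumor DSP panels,
#' 19 synthetic low-signal analytes that sit below the detection limit in
#' most ROIs (so the detection filter has work to do), 3 spike-in positive
#' controls and 3 isotype negative controls. Per-marker columns give the
#' baseline tumor log2 signal-to-noise, the stroma log2 shift, the log2
#' slope on the continuous ER score (negative for immune analytes), the
#' race log2 shift (nonzero only for the B7-H3 analogue, -0.8), and a
#' log-hazard coefficient used by the survival simulation.
#'
#' @return a \code{data.frame} with one row per marker.
#' @export
defaultPanel <- function() {
  robust <- data.frame(
    marker_id = c("Fibronectin", "PanCk", "SMA", "CD127", "EpCAM", "CD4",
                  "CD45", "CD14", "CD11c", "CD68", "Ki-67", "Bcl-2", "CD3",
                  "FAPa", "CD40", "ER", "CD8", "CD25", "HLA-DR", "NY-ESO-1",
                  "CD45RO", "HER2", "CD34", "GZMB", "CTLA4", "B2M", "CD56",
                  "OX40L", "S100B", "Tim-3", "STING", "B7-H3", "CD44"),
    tumor_median = c(34.94, 439.06, 392.49, 69.42, 94.09, 5.66, 14.12,
                     14.29, 9.92, 18.26, 14.39, 22.28, 2.3, 3.65, 2.4,
                     33.68, 7.20, 3.72, 15.08, 8.26, 4.86, 11.20, 10.01,
                     14.85, 5.96, 6.49, 2.4, 3.83, 7.31, 28.26, 11.55,
                     51.01, 150),
    stroma_median = c(174.79, 22.33, 1248.94, 30.22, 17.75, 13.29, 39.29,
                      26.38, 24.48, 38.59, 5.62, 8.91, 6.52, 6.84, 4.89,
                      3.64, 12.68, 2.4, 38.11, 3.94, 5.80, 3.32, 22.89,
                      15.26, 6.28, 9.37, 3.19, 3.93, 10.90, 22.69, 15.47,
                      61.71, 180),
    er_coef = c(0.08, 0.15, 0, 0, -0.15, -0.10, -0.10, -0.10, -0.10,
                -0.10, -0.12, 0.30, -0.10, 0, -0.15, 1, -0.10, -0.10, 0,
                0, -0.08, 0, 0, 0, 0, -0.10, 0, -0.10, -0.12, 0, 0, 0,
                -0.15),
    race_shift = c(rep(0, 31), -0.8, 0),
    hazard_coef = c(rep(0, 4), 0.4, rep(0, 28)),
    stringsAsFactors = FALSE)
  ## robust analytes are detectable in both compartments by construction:
  ## keep every compartment median comfortably above the detection limit so
  ## the filter's fate is set by design, not by noise draws
  robust$tumor_median <- pmax(robust$tumor_median, 5.5)
  robust$stroma_median <- pmax(robust$stroma_median, 5.5)
  low <- data.frame(
    marker_id = c("PD-1", "PD-L1", "PD-L2", "LAG-3", "ICOS", "CD20",
                  "CD80", "CD86", "4-1BB", "GITR", "IDO1", "VISTA", "ARG1",
                  "CD163", "FOXP3", "CD66b", "TGFB1", "CD19", "PTEN"),
    tumor_median = rep(1.7, 19), stroma_median = rep(1.8, 19),
    er_coef = 0, race_shift = 0, hazard_coef = 0,
    stringsAsFactors = FALSE)
  exper <- rbind(robust, low)
  exper$marker_class <- "experimental"
  ctrl <- data.frame(
    marker_id = c("ERCC-A", "ERCC-B", "ERCC-C",
                  "Ms IgG1", "Ms IgG2a", "Rb IgG"),
    tumor_median = NA_real_, stroma_median = NA_real_,
    er_coef = 0, race_shift = 0, hazard_coef = 0,
    marker_class = rep(c("positive_control", "negative_control"), each = 3),
    stringsAsFactors = FALSE)
  panel <- rbind(exper, ctrl)
  panel$base_log2 <- log2(panel$tumor_median)
  panel$comp_shift <- log2(panel$stroma_median) - log2(panel$tumor_median)
  panel$display_name <- panel$marker_id
  iso <- c("Ms IgG1", "Ms IgG2a", "Rb IgG")
  panel$isotype <- iso[(seq_len(nrow(panel)) - 1L) %% 3L + 1L]
  panel$isotype[panel$marker_class == "negative_control"] <-
    panel$marker_id[panel$marker_class == "negative_control"]
  panel
}

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: 159
#' patients (59.1\% Black), ER-positive fractions of 59/94 (Black) and
#' 53/65 (White), 1-5 cores per patient with 75\% of patients having at
#' least two, five patients without a stromal compartment, two staining
#' batches (about one third of patients in the fresh-cut first batch) with
#' a 1.5 log2-unit offset between them, and a follow-up subset of 136/159
#' patients for survival.
#'
#' @param n_patients number of patients.
#' @param black_fraction expected fraction of Black patients.
#' @param er_positive_fraction named vector, P(ER+) by race.
#' @param cores_per_patient_probs probabilities for 1..5 cores.
#' @param n_no_stroma number of single-core patients whose core lacks a
#'   stromal compartment.
#' @param batch1_fraction expected fraction of patients in batch 1.
#' @param batch_offsets per-batch log2 offsets (centered); length 2 default
#'   \code{c(0.75, -0.75)}.
#' @param panel marker table, see [defaultPanel()].
#' @param nc_log2_mean,nc_log2_sd log2 location/spread of negative-control
#'   background counts.
#' @param pc_log2_mean,pc_log2_sd log2 location/spread of spike-in counts
#'   (spread 0: spike-ins encode the technical factor exactly).
#' @param tech_log2_sd log2 spread of per-ROI technical factors
#'   (normalized to geometric mean 1 so spike-in normalization is exactly
#'   invertible).
#' @param patient_sd per-(patient, marker) biological spread, log2 units.
#' @param core_sd per-(core, marker) spread, log2 units.
#' @param noise_sd per-cell measurement noise, log2 units.
#' @param er_mean_pos,er_sd_pos,er_mean_neg,er_sd_neg the continuous log2
#'   ER-score law by clinical ER status.
#' @param count_law \code{"round"} (default), \code{"poisson"} or
#'   \code{"none"} (leave real-valued).
#' @param base_hazard baseline event rate per year.
#' @param censor_range years of potential follow-up, uniform.
#' @param bc_death_fraction fraction of deaths attributed to breast cancer.
#' @param followup_fraction fraction of patients with follow-up available.
#' @param seed mandatory RNG seed.
#' @return a validated \code{SimConfig} list.
#' @export
dspSimConfig <- function(n_patients = 159,
                         black_fraction = 94 / 159,
                         er_positive_fraction = c(Black = 59 / 94,
                                                  White = 53 / 65),
                         cores_per_patient_probs = c(0.25, 0.35, 0.20,
                                                     0.12, 0.08),
                         n_no_stroma = 5,
                         batch1_fraction = 1 / 3,
                         batch_offsets = c(0.75, -0.75),
                         panel = defaultPanel(),
                         nc_log2_mean = 6, nc_log2_sd = 0.3,
                         pc_log2_mean = 12, pc_log2_sd = 0,
                         tech_log2_sd = 0.5,
                         patient_sd = 0.45,
                         core_sd = 0.25,
                         noise_sd = 0.35,
                         er_mean_pos = log2(49), er_sd_pos = 1.5,
                         er_mean_neg = log2(3.2), er_sd_neg = 0.8,
                         count_law = c("round", "poisson", "none"),
                         base_hazard = 0.025,
                         censor_range = c(2, 17),
                         bc_death_fraction = 18 / 28,
                         followup_fraction = 136 / 159,
                         seed = 1L) {
  count_law <- match.arg(count_law)
  cfg <- list(n_patients = n_patients, black_fraction = black_fraction,
              er_positive_fraction = er_positive_fraction,
              cores_per_patient_probs = cores_per_patient_probs,
              n_no_stroma = n_no_stroma,
              batch1_fraction = batch1_fraction,
              batch_offsets = batch_offsets, panel = panel,
              nc_log2_mean = nc_log2_mean, nc_log2_sd = nc_log2_sd,
              pc_log2_mean = pc_log2_mean, pc_log2_sd = pc_log2_sd,
              tech_log2_sd = tech_log2_sd, patient_sd = patient_sd,
              core_sd = core_sd, noise_sd = noise_sd,
              er_mean_pos = er_mean_pos, er_sd_pos = er_sd_pos,
              er_mean_neg = er_mean_neg, er_sd_neg = er_sd_neg,
              count_law = count_law, base_hazard = base_hazard,
              censor_range = censor_range,
              bc_death_fraction = bc_death_fraction,
              followup_fraction = followup_fraction, seed = seed)
  .validateSimConfig(cfg)
  structure(cfg, class = "SimConfig")
}

.validateSimConfig <- function(cfg) {
  fracs <- c(cfg$black_fraction, cfg$er_positive_fraction,
             cfg$batch1_fraction, cfg$bc_death_fraction,
             cfg$followup_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(cfg$nc_log2_sd, cfg$tech_log2_sd, cfg$patient_sd, cfg$core_sd,
            cfg$noise_sd, cfg$pc_log2_sd) < 0)) {
    stop("dispersions must be non-negative", call. = FALSE)
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop("a seed is mandatory", call. = FALSE)
  }
  if (cfg$n_patients < 0) {
    stop("n_patients must be non-negative", call. = FALSE)
  }
  if (abs(sum(cfg$cores_per_patient_probs) - 1) > 1e-8) {
    stop("cores_per_patient_probs must sum to 1", call. = FALSE)
  }
  if (cfg$base_hazard <= 0) {
    stop("base_hazard must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

## Sample the clinical covariates; category frequencies follow the cohort
## margins by race (BMI, subtype, stage, grade, size, LN status).
.simulateClinical <- function(cfg) {
  n <- cfg$n_patients
  patient_id <- sprintf("P%03d", seq_len(n))
  race <- ifelse(stats::runif(n) < cfg$black_fraction, "Black", "White")
  p_er <- cfg$er_positive_fraction[race]
  er <- ifelse(stats::runif(n) < p_er, "POS", "NEG")
  pr <- ifelse(er == "POS",
               ifelse(stats::runif(n) < 0.78, "POS", "NEG"),
               ifelse(stats::runif(n) < 0.10, "POS", "NEG"))
  her2 <- ifelse(stats::runif(n) < 0.166, "POS", "NEG")
  hr_pos <- er == "POS" | pr == "POS"
  subtype <- ifelse(her2 == "POS", "HER2positive",
                    ifelse(hr_pos, "LuminalA", "TripleNegative"))
  pick <- function(levels, probs_black, probs_white) {
    out <- character(n)
    for (i in seq_len(n)) {
      p <- if (race[i] == "Black") probs_black else probs_white
      out[i] <- sample(levels, 1L, prob = p)
    }
    out
  }
  bmi <- pick(c("<25", "25-29", "30+"), c(0.20, 0.29, 0.51),
              c(0.43, 0.21, 0.36))
  stage <- pick(c("I", "II", "III/IV"), c(0.33, 0.50, 0.17),
                c(0.53, 0.39, 0.08))
  grade <- pick(c("LOW", "MED", "HIGH"), c(0.10, 0.26, 0.64),
                c(0.20, 0.45, 0.35))
  size <- pick(c("<1.0", "1-1.9", ">=2.0"), c(0.09, 0.33, 0.58),
               c(0.16, 0.45, 0.39))
  ln <- pick(c("POS", "NEG"), c(0.47, 0.53), c(0.33, 0.67))
  data.frame(patient_id = patient_id, race = race,
             age_years = round(stats::rnorm(n, 52.6, 10.2), 1),
             bmi_category = bmi, er_status = er, pr_status = pr,
             her2_status = her2, subtype = subtype, stage = stage,
             grade = grade, tumor_size_cat = size, ln_status = ln,
             stringsAsFactors = FALSE)
}

.applyCountLaw <- function(x, law) {
  switch(law,
         round = round(x),
         poisson = matrix(stats::rpois(length(x), lambda = x),
                          nrow = nrow(x), dimnames = dimnames(x)),
         none = x)
}

#' Simulate a full ROI-level cohort
#'
#' Generates clinical records, an ROI map, a raw count matrix and a truth
#' table. Experimental counts follow
#' \code{round(2^(background + signal) * technical_factor)} where the log2
#' signal is the sum of the marker baseline, the stroma shift, the race
#' shift, the ER-score term, the batch offset, patient-, core- and
#' cell-level noise. Negative controls draw from the background law alone;
#' spike-in positive controls encode the technical factor. The same seed
#' yields byte-identical output.
#'
#' @param config a [dspSimConfig()] object.
#' @return a list of class \code{DspCohort} with elements \code{dsp}
#'   (a raw-stage [DspExperiment-class]), \code{clinical}, \code{roiMap},
#'   \code{truth} (marker/batch/ROI/patient truth tables and latent
#'   matrices) and \code{config}.
#' @export
simulateCohort <- function(config = dspSimConfig()) {
  .validateSimConfig(config)
  cfg <- config
  set.seed(cfg$seed)
  panel <- cfg$panel
  manifest <- panel[, c("marker_id", "display_name", "marker_class",
                        "isotype")]
  if (cfg$n_patients == 0L) {
    empty_truth <- list(
      markers = data.frame(marker_id = character(0)),
      batches = data.frame(batch_id = character(0)),
      rois = data.frame(roi_id = character(0)),
      patients = data.frame(patient_id = character(0)))
    return(structure(list(dsp = NULL,
                          clinical = data.frame(patient_id = character(0)),
                          roiMap = data.frame(roi_id = character(0)),
                          truth = empty_truth, config = cfg),
                     class = "DspCohort"))
  }
  clinical <- .simulateClinical(cfg)
  n <- cfg$n_patients

  ## continuous ER score per patient
  er_pos <- clinical$er_status == "POS"
  er_score <- ifelse(er_pos,
                     stats::rnorm(n, cfg$er_mean_pos, cfg$er_sd_pos),
                     stats::rnorm(n, cfg$er_mean_neg, cfg$er_sd_neg))
  er_center <- sum(c(cfg$er_mean_pos, cfg$er_mean_neg) * c(0.70, 0.30))

  ## cores and ROIs
  cores <- sample(seq_along(cfg$cores_per_patient_probs), n, replace = TRUE,
                  prob = cfg$cores_per_patient_probs)
  n_ns <- min(cfg$n_no_stroma, n)
  no_stroma <- if (n_ns > 0) sample(seq_len(n), n_ns) else integer(0)
  cores[no_stroma] <- 1L
  batch <- ifelse(stats::runif(n) < cfg$batch1_fraction, "B1", "B2")
  offsets <- cfg$batch_offsets - mean(cfg$batch_offsets)
  names(offsets) <- paste0("B", seq_along(offsets))

  roi <- do.call(rbind, lapply(seq_len(n), function(i) {
    out <- do.call(rbind, lapply(seq_len(cores[i]), function(k) {
      comp <- if (i %in% no_stroma) "tumor" else c("tumor", "stroma")
      data.frame(patient_id = clinical$patient_id[i],
                 core_id = sprintf("%s_c%d", clinical$patient_id[i], k),
                 compartment = comp, stringsAsFactors = FALSE)
    }))
    out
  }))
  roi$roi_id <- sprintf("%s_%s", roi$core_id,
                        substr(roi$compartment, 1, 1))
  roi$batch_id <- batch[match(roi$patient_id, clinical$patient_id)]
  roi$replicate_id <- "R1"
  roi <- roi[, c("roi_id", "patient_id", "core_id", "compartment",
                 "batch_id", "replicate_id")]
  nroi <- nrow(roi)

  ## latent effects
  exp_idx <- panel$marker_class == "experimental"
  mk <- panel$marker_id
  u_pat <- matrix(stats::rnorm(n * sum(exp_idx), 0, cfg$patient_sd),
                  nrow = n, dimnames = list(clinical$patient_id,
                                            mk[exp_idx]))
  core_ids <- unique(roi$core_id)
  u_core <- matrix(stats::rnorm(length(core_ids) * sum(exp_idx), 0,
                                cfg$core_sd),
                   nrow = length(core_ids),
                   dimnames = list(core_ids, mk[exp_idx]))
  tech <- 2^stats::rnorm(nroi, 0, cfg$tech_log2_sd)
  tech <- tech / .geomean(tech)
  names(tech) <- roi$roi_id

  ## per-cell log2 signal: markers x ROIs
  pidx <- match(roi$patient_id, clinical$patient_id)
  stroma <- as.numeric(roi$compartment == "stroma")
  black <- as.numeric(clinical$race[pidx] == "Black")
  erdev <- er_score[pidx] - er_center

  log2sig <- matrix(NA_real_, nrow = nrow(panel), ncol = nroi,
                    dimnames = list(mk, roi$roi_id))
  for (j in which(exp_idx)) {
    mu <- cfg$nc_log2_mean + panel$base_log2[j] +
      panel$comp_shift[j] * stroma + panel$race_shift[j] * black +
      panel$er_coef[j] * erdev +
      offsets[roi$batch_id] +
      u_pat[cbind(pidx, match(mk[j], colnames(u_pat)))] +
      u_core[cbind(match(roi$core_id, core_ids),
                   match(mk[j], colnames(u_core)))]
    log2sig[j, ] <- mu + stats::rnorm(nroi, 0, cfg$noise_sd)
  }
  nc_idx <- which(panel$marker_class == "negative_control")
  for (j in nc_idx) {
    log2sig[j, ] <- cfg$nc_log2_mean + stats::rnorm(nroi, 0, cfg$nc_log2_sd)
  }
  pc_idx <- which(panel$marker_class == "positive_control")
  for (j in pc_idx) {
    log2sig[j, ] <- cfg$pc_log2_mean + stats::rnorm(nroi, 0, cfg$pc_log2_sd)
  }
  pre_tech <- 2^log2sig
  counts <- .applyCountLaw(sweep(pre_tech, 2, tech, `*`), cfg$count_law)

  ## survival: log-hazard from the patient-level true tumor signal
  hz <- panel$hazard_coef[exp_idx]
  names(hz) <- mk[exp_idx]
  true_tumor <- outer(rep(1, n), panel$base_log2[exp_idx]) + u_pat +
    outer(as.numeric(clinical$race == "Black"),
          panel$race_shift[exp_idx]) +
    outer(er_score - er_center, panel$er_coef[exp_idx])
  colnames(true_tumor) <- mk[exp_idx]
  lp <- drop(scale(true_tumor, center = TRUE, scale = FALSE) %*% hz)
  event_time <- stats::rexp(n, rate = cfg$base_hazard * exp(lp))
  censor_time <- stats::runif(n, cfg$censor_range[1], cfg$censor_range[2])
  followup <- pmin(event_time, censor_time)
  dead <- event_time <= censor_time
  bc_death <- dead & stats::runif(n) < cfg$bc_death_fraction
  has_fu <- stats::runif(n) < cfg$followup_fraction
  clinical$followup_years <- ifelse(has_fu, round(followup, 3), NA)
  clinical$vital_status <- ifelse(has_fu, ifelse(dead, "dead", "alive"),
                                  NA)
  clinical$breast_cancer_death <- ifelse(has_fu, bc_death, NA)

  truth <- list(
    markers = data.frame(marker_id = mk[exp_idx],
                         base_log2 = panel$base_log2[exp_idx],
                         comp_shift = panel$comp_shift[exp_idx],
                         race_shift = panel$race_shift[exp_idx],
                         er_coef = panel$er_coef[exp_idx],
                         hazard_coef = panel$hazard_coef[exp_idx],
                         stringsAsFactors = FALSE),
    batches = data.frame(batch_id = names(offsets),
                         offset_log2 = as.numeric(offsets),
                         stringsAsFactors = FALSE),
    rois = data.frame(roi_id = roi$roi_id, tech_factor = as.numeric(tech),
                      stringsAsFactors = FALSE),
    patients = data.frame(patient_id = clinical$patient_id,
                          er_score = er_score, survival_lp = lp,
                          stringsAsFactors = FALSE),
    latent_log2 = log2sig,
    pre_tech_counts = pre_tech)

  dsp <- DspExperiment(counts, manifest, roiData = roi, stage = "raw")
  structure(list(dsp = dsp, clinical = clinical, roiMap = roi,
                 truth = truth, config = cfg),
            class = "DspCohort")
}

#' Simulate a replicate assay run on adjacent sections
#'
#' The replicate shares the cohort's realized latent signal (adjacent
#' sections carry the same biology) and the same technical factors, with
#' independent log2 measurement noise of standard deviation \code{noise_sd}
#' added on top. With \code{noise_sd = 0} the replicate equals the original
#' exactly.
#'
#' @param cohort a \code{DspCohort} from [simulateCohort()].
#' @param noise_sd replicate-specific log2 noise; default 0.18.
#' @return a raw-stage [DspExperiment-class] with \code{replicate_id}
#'   \code{"R2"}.
#' @export
simulateReplicateRun <- function(cohort, noise_sd = 0.18) {
  stopifnot(inherits(cohort, "DspCohort"), noise_sd >= 0)
  cfg <- cohort$config
  set.seed(cfg$seed + 1000003L)
  log2sig <- cohort$truth$latent_log2
  eps <- matrix(stats::rnorm(length(log2sig), 0, noise_sd),
                nrow = nrow(log2sig))
  tech <- cohort$truth$rois$tech_factor
  counts <- .applyCountLaw(sweep(2^(log2sig + eps), 2, tech, `*`),
                           cfg$count_law)
  roi <- cohort$roiMap
  roi$replicate_id <- "R2"
  manifest <- cfg$panel[, c("marker_id", "display_name", "marker_class",
                            "isotype")]
  DspExperiment(counts, manifest, roiData = roi, stage = "raw")
}

#' Simulate patient-level mean-score profiles directly
#'
#' Generates the per-patient, per-compartment mean-score resolution of the
#' processed data (the deposited-table analogue) without the ROI layer:
#' each (patient, marker, compartment) log2 score is baseline + compartment
#' shift + race shift + ER term + patient effect + mean measurement noise,
#' exponentiated and floored at the detection floor. Used for fast
#' null-calibration and power simulations.
#'
#' @param config a [dspSimConfig()]; only the profile-relevant fields are
#'   used.
#' @param params a [qcParams()] supplying the threshold/floor.
#' @return list with \code{profile} (a [PatientProfile-class]),
#'   \code{clinical} and \code{truth}.
#' @export
simulateProfiles <- function(config = dspSimConfig(),
                             params = qcParams()) {
  .validateSimConfig(config)
  cfg <- config
  set.seed(cfg$seed)
  clinical <- .simulateClinical(cfg)
  n <- cfg$n_patients
  panel <- cfg$panel[cfg$panel$marker_class == "experimental", ]
  ## keep the analytes detectable in at least one compartment (the filtered
  ## panel analogue)
  keep <- is.finite(panel$base_log2) &
    pmax(panel$base_log2, panel$base_log2 + panel$comp_shift) >= log2(3)
  panel <- panel[keep, ]
  er_pos <- clinical$er_status == "POS"
  er_score <- ifelse(er_pos,
                     stats::rnorm(n, cfg$er_mean_pos, cfg$er_sd_pos),
                     stats::rnorm(n, cfg$er_mean_neg, cfg$er_sd_neg))
  er_center <- sum(c(cfg$er_mean_pos, cfg$er_mean_neg) * c(0.70, 0.30))
  black <- as.numeric(clinical$race == "Black")
  nro <- sample(seq_along(cfg$cores_per_patient_probs), n, replace = TRUE,
                prob = cfg$cores_per_patient_probs)
  m <- nrow(panel)
  build <- function(compartment) {
    stroma <- as.numeric(compartment == "stroma")
    mu <- outer(rep(1, n), panel$base_log2 + panel$comp_shift * stroma) +
      outer(black, panel$race_shift) +
      outer(er_score - er_center, panel$er_coef) +
      matrix(stats::rnorm(n * m, 0, cfg$patient_sd), n, m) +
      matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m) /
        sqrt(matrix(nro, n, m))
    val <- 2^mu
    val[val < params$snr_threshold] <- params$floor_value
    t(val)
  }
  tum <- build("tumor")
  str <- build("stroma")
  score <- cbind(tum, str)
  rownames(score) <- panel$marker_id
  colnames(score) <- c(paste0(clinical$patient_id, ".tumor"),
                       paste0(clinical$patient_id, ".stroma"))
  nmat <- matrix(rep(nro, 2), nrow = m, ncol = 2 * n, byrow = TRUE,
                 dimnames = dimnames(score))
  profile <- PatientProfile(score, nmat,
                            patientId = rep(clinical$patient_id, 2),
                            compartment = rep(c("tumor", "stroma"),
                                              each = n))
  truth <- list(markers = panel[, c("marker_id", "comp_shift",
                                    "race_shift", "er_coef")],
                patients = data.frame(patient_id = clinical$patient_id,
                                      er_score = er_score))
  list(profile = profile, clinical = clinical, truth = truth)
}

#' Write the tables of a simulated cohort to a directory
#'
#' Emits counts, manifest, ROI map, clinical and truth tables in the
#' package's delimited formats.
#'
#' @param cohort a \code{DspCohort}.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(cohort$dsp, file.path(dir, "counts.tsv"))
  .writeDelim(cohort$config$panel[, c("marker_id", "display_name",
                                      "marker_class", "isotype")],
              file.path(dir, "manifest.tsv"))
  .writeDelim(cohort$roiMap, file.path(dir, "roi_map.tsv"))
  .writeDelim(cohort$clinical, file.path(dir, "clinical.tsv"))
  .writeDelim(cohort$truth$markers, file.path(dir, "truth_markers.tsv"))
  .writeDelim(cohort$truth$batches, file.path(dir, "truth_batches.tsv"))
  .writeDelim(cohort$truth$rois, file.path(dir, "truth_rois.tsv"))
  .writeDelim(cohort$truth$patients, file.path(dir, "truth_patients.tsv"))
  invisible(dir)
}
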