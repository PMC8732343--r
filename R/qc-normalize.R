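## The core processing chain: spike-in normalization -> signal-to-noise
## against isotype negative controls -> detection filter -> floor
## imputation -> mixed-model batch calibration -> per-patient compartment
## aggregation, plus replicate concordance QC. Stage tags on the
## DspExperiment enforce the order; calling an operation out of order is an
## error.

#' Spike-in normalization
#'
#' Scales every ROI by \code{reference / s(roi)} where \code{s(roi)} is the
#' geometric mean of the ROI's spike-in (positive-control) counts and the
#' reference is the across-ROI geometric mean of those summaries. This
#' removes per-ROI technical variation (collection efficiency,
#' hybridization) while leaving the cohort-level scale unchanged. Spike-in
#' columns are retained for audit.
#'
#' @param x a raw-stage [DspExperiment-class].
#' @return a [DspExperiment-class] at stage \code{"spikein_normalized"}.
#' @export
normalizeSpikeIn <- function(x) {
  stopifnot(is(x, "DspExperiment"))
  pc <- positiveControlMarkers(x)
  if (length(pc) == 0L) {
    stop("no positive-control (spike-in) markers in the panel",
         call. = FALSE)
  }
  counts <- assay(x, "counts")
  s <- .colGeomeans(counts[pc, , drop = FALSE] )
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    stop(sprintf("zero spike-in summary for ROI(s): %s",
                 paste(colnames(x)[zero], collapse = ", ")), call. = FALSE)
  }
  reference <- .geomean(s)
  assay(x, "counts") <- sweep(counts, 2, reference / s, `*`)
  .advanceStage(x, from = "raw", to = "spikein_normalized")
}

#' Housekeeping normalization (alternative mode)
#'
#' Same geometric-mean scaling as [normalizeSpikeIn()] but using a supplied
#' set of housekeeping markers as the per-ROI summary. Offered for
#' comparison only; spike-in normalization is the default mode.
#'
#' @param x a raw-stage [DspExperiment-class].
#' @param housekeeping character vector of marker ids.
#' @return a [DspExperiment-class] at stage \code{"spikein_normalized"}.
#' @export
normalizeHousekeeping <- function(x, housekeeping) {
  stopifnot(is(x, "DspExperiment"), length(housekeeping) >= 1L,
            all(housekeeping %in% rownames(x)))
  counts <- assay(x, "counts")
  s <- .colGeomeans(counts[housekeeping, , drop = FALSE])
  if (any(s <= 0 | !is.finite(s))) {
    stop("zero housekeeping summary for at least one ROI", call. = FALSE)
  }
  assay(x, "counts") <- sweep(counts, 2, .geomean(s) / s, `*`)
  .advanceStage(x, from = "raw", to = "spikein_normalized")
}

#' Signal-to-noise ratios against the isotype negative controls
#'
#' Divides each normalized marker count by a per-ROI background summary:
#' by default the geometric mean of all negative-control counts in the same
#' ROI, or (mode \code{"isotype_matched"}) the geometric mean of the
#' controls sharing the marker's isotype host. Negative-control rows are
#' dropped from the output; a \code{"detected"} assay flags cells at or
#' above the detection threshold.
#'
#' @param x a [DspExperiment-class] at stage \code{"spikein_normalized"}
#'   (or \code{"raw"} when \code{params$normalization_mode == "none"}).
#' @param params a [qcParams()].
#' @return a [DspExperiment-class] at stage \code{"snr"} with assays
#'   \code{"snr"} and \code{"detected"}.
#' @export
computeSNR <- function(x, params = qcParams()) {
  stopifnot(is(x, "DspExperiment"))
  from <- if (params$normalization_mode == "none") {
    c("raw", "spikein_normalized")
  } else {
    "spikein_normalized"
  }
  nc <- negativeControlMarkers(x)
  if (length(nc) == 0L) {
    stop("no negative-control markers in the panel", call. = FALSE)
  }
  counts <- assay(x, "counts")
  keep <- setdiff(rownames(x), nc)
  if (params$snr_denominator == "geometric_mean_all_nc") {
    denom <- .colGeomeans(counts[nc, , drop = FALSE])
    bad <- denom <= 0 | !is.finite(denom)
    if (any(bad)) {
      stop(sprintf("non-positive negative-control summary for ROI(s): %s",
                   paste(colnames(x)[bad], collapse = ", ")), call. = FALSE)
    }
    snr <- sweep(counts[keep, , drop = FALSE], 2, denom, `/`)
  } else {
    iso <- rowData(x)$isotype
    names(iso) <- rownames(x)
    snr <- matrix(NA_real_, length(keep), ncol(x),
                  dimnames = list(keep, colnames(x)))
    for (m in keep) {
      matched <- nc[!is.na(iso[nc]) & !is.na(iso[m]) &
                      iso[nc] == iso[m]]
      if (length(matched) == 0L) {
        matched <- nc   # no matching host: pool all controls
      }
      denom <- .colGeomeans(counts[matched, , drop = FALSE])
      if (any(denom <= 0 | !is.finite(denom))) {
        stop("non-positive negative-control summary", call. = FALSE)
      }
      snr[m, ] <- counts[m, ] / denom
    }
  }
  out <- x[keep, ]
  assays <- SimpleList(snr = snr,
                       detected = snr >= params$snr_threshold)
  se <- SummarizedExperiment(assays = assays, rowData = rowData(out),
                             colData = colData(out),
                             metadata = metadata(out))
  out <- new("DspExperiment", se)
  metadata(out)$stage <- dspStage(x)
  out <- .advanceStage(out, from = from, to = "snr")
  metadata(out)$snr_params <- params
  out
}

#' Detection filter
#'
#' Drops an experimental marker when, in the tumor ROIs or in the stroma
#' ROIs considered separately, strictly more than
#' \code{max_undetected_fraction} of its values fall below the detection
#' threshold. Controls are exempt from dropping but appear in the report.
#' A compartment with zero ROIs is skipped with a warning rather than
#' counted as failing.
#'
#' @param x a [DspExperiment-class] at stage \code{"snr"} with compartment
#'   labels in its ROI annotation.
#' @param params a [qcParams()].
#' @return a list with \code{object} (the filtered [DspExperiment-class]),
#'   \code{retained}, \code{dropped} (experimental marker ids) and
#'   \code{report} (per-marker undetected fractions by compartment).
#' @export
detectionFilter <- function(x, params = qcParams()) {
  stopifnot(is(x, "DspExperiment"))
  if (dspStage(x) != "snr") {
    stop("detectionFilter requires stage 'snr'", call. = FALSE)
  }
  comp <- colData(x)$compartment
  if (is.null(comp)) {
    stop("compartment labels are required for the detection filter",
         call. = FALSE)
  }
  snr <- assay(x, "snr")
  frac_und <- function(compartment) {
    idx <- which(comp == compartment)
    if (length(idx) == 0L) {
      warning(sprintf("no ROIs in the %s compartment; skipped",
                      compartment))
      return(rep(NA_real_, nrow(snr)))
    }
    rowMeans(snr[, idx, drop = FALSE] < params$snr_threshold)
  }
  ft <- frac_und("tumor")
  fs <- frac_und("stroma")
  report <- data.frame(marker_id = rownames(x),
                       marker_class = rowData(x)$markerClass,
                       undetected_tumor = ft, undetected_stroma = fs,
                       stringsAsFactors = FALSE)
  fails <- (!is.na(ft) & ft > params$max_undetected_fraction) |
    (!is.na(fs) & fs > params$max_undetected_fraction)
  report$fails_rule <- fails
  is_exp <- rowData(x)$markerClass == "experimental"
  dropped <- rownames(x)[fails & is_exp]
  retained <- rownames(x)[is_exp & !fails]
  obj <- x[setdiff(rownames(x), dropped), ]
  metadata(obj)$filtered <- TRUE
  list(object = obj, retained = retained, dropped = dropped,
       report = report)
}

#' Floor imputation for values below the detection limit
#'
#' Replaces every signal-to-noise value below the threshold with the single
#' constant \code{floor_value} (default \eqn{3/\sqrt{2}}), a midpoint-style
#' stand-in for sub-detection signal. Detection flags from the pre-floor
#' state are preserved. Idempotent.
#'
#' @param x a filtered [DspExperiment-class] at stage \code{"snr"}.
#' @param params a [qcParams()].
#' @return the floored [DspExperiment-class].
#' @export
imputeFloor <- function(x, params = qcParams()) {
  stopifnot(is(x, "DspExperiment"))
  if (dspStage(x) != "snr") {
    stop("imputeFloor requires stage 'snr'", call. = FALSE)
  }
  if (!isTRUE(metadata(x)$filtered)) {
    stop("run detectionFilter before imputeFloor", call. = FALSE)
  }
  snr <- assay(x, "snr")
  snr[snr < params$snr_threshold] <- params$floor_value
  assay(x, "snr") <- snr
  metadata(x)$floored <- TRUE
  x
}

#' Batch calibration via a per-marker mixed model
#'
#' For each marker, fits \code{log2(SNR) ~ 1 + (1 | batch)} by REML on the
#' detected (above-floor) cells, takes the centered conditional modes of
#' the batch effects as additive log2 correction factors, and subtracts
#' each batch's factor from that marker's detected cells. Floored cells are
#' never moved, and the floor is re-applied so no calibrated value sits
#' below it — the imputation constant stays batch-invariant. Single-batch
#' input returns zero corrections and unchanged data; a marker with fewer
#' than two detected values in some batch gets a zero correction for that
#' (marker, batch) with a warning. Re-applying the calibration is a no-op:
#' the residual batch variance collapses to the boundary.
#'
#' @param x a floored [DspExperiment-class] at stage \code{"snr"}.
#' @param params a [qcParams()].
#' @return a list with \code{object} (stage \code{"calibrated"}) and
#'   \code{calibration} (per-(marker, batch) corrections plus
#'   variance-component summaries).
#' @export
calibrateBatches <- function(x, params = qcParams()) {
  stopifnot(is(x, "DspExperiment"))
  if (!dspStage(x) %in% c("snr", "calibrated")) {
    stop("calibrateBatches requires an SNR-stage object", call. = FALSE)
  }
  if (!isTRUE(metadata(x)$floored)) {
    stop("run imputeFloor before calibrateBatches", call. = FALSE)
  }
  batch <- colData(x)$batchId
  if (is.null(batch)) {
    stop("batch labels are required for calibration", call. = FALSE)
  }
  batches <- sort(unique(batch))
  snr <- assay(x, "snr")
  detected <- assay(x, "detected")
  corr <- matrix(0, nrow = nrow(x), ncol = length(batches),
                 dimnames = list(rownames(x), batches))
  vc <- data.frame(marker_id = rownames(x), batch_sd = NA_real_,
                   residual_sd = NA_real_, stringsAsFactors = FALSE)
  if (length(batches) > 1L) {
    for (m in rownames(x)) {
      det <- detected[m, ]
      n_per_batch <- table(factor(batch[det], levels = batches))
      deficient <- names(n_per_batch)[n_per_batch < 2L]
      usable <- setdiff(batches, deficient)
      if (length(deficient)) {
        warning(sprintf(
          "marker '%s': <2 detected values in batch(es) %s; correction 0",
          m, paste(deficient, collapse = ", ")))
      }
      if (length(usable) < 2L) {
        next
      }
      sel <- det & batch %in% usable
      df <- data.frame(y = log2(snr[m, sel]),
                       batch = factor(batch[sel], levels = usable))
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(y ~ 1 + (1 | batch), data = df, REML = TRUE))),
        error = function(e) NULL)
      if (is.null(fit)) {
        next
      }
      b <- lme4::ranef(fit)$batch[, 1]
      names(b) <- rownames(lme4::ranef(fit)$batch)
      b <- b[usable]
      b[is.na(b)] <- 0
      b <- b - mean(b)
      corr[m, usable] <- -b
      vcs <- as.data.frame(lme4::VarCorr(fit))
      vc[vc$marker_id == m, c("batch_sd", "residual_sd")] <-
        vcs$sdcor[match(c("batch", "Residual"), vcs$grp)]
    }
  }
  adj <- corr[, match(batch, batches), drop = FALSE]
  shifted <- 2^(log2(snr) + adj)
  out <- snr
  out[detected] <- pmax(shifted[detected], params$floor_value)
  assay(x, "snr") <- out
  x <- .advanceStage(x, from = c("snr", "calibrated"), to = "calibrated")
  calibration <- list(
    corrections = corr,
    variance_components = vc,
    batches = batches)
  list(object = x, calibration = calibration)
}

#' Aggregate ROI values into per-patient compartment means
#'
#' Arithmetic mean of the calibrated signal-to-noise values per
#' (patient, marker, compartment), on the linear scale. Contributing-ROI
#' counts are recorded; patients lacking a compartment simply have no
#' column for it.
#'
#' @param x a [DspExperiment-class] at stage \code{"calibrated"} (or
#'   \code{"snr"} for single-batch designs skipping calibration).
#' @return a [PatientProfile-class].
#' @export
aggregatePatients <- function(x) {
  stopifnot(is(x, "DspExperiment"))
  if (!dspStage(x) %in% c("snr", "calibrated")) {
    stop("aggregatePatients requires an SNR-stage object", call. = FALSE)
  }
  cd <- colData(x)
  if (is.null(cd$patientId) || is.null(cd$compartment)) {
    stop("patient and compartment labels are required", call. = FALSE)
  }
  if (anyNA(cd$patientId)) {
    stop("ROI with unknown patient", call. = FALSE)
  }
  key <- paste(cd$patientId, cd$compartment, sep = ".")
  groups <- unique(key)
  snr <- assay(x, "snr")
  score <- matrix(NA_real_, nrow(x), length(groups),
                  dimnames = list(rownames(x), groups))
  nmat <- score
  for (g in seq_along(groups)) {
    idx <- which(key == groups[g])
    score[, g] <- rowMeans(snr[, idx, drop = FALSE])
    nmat[, g] <- length(idx)
  }
  first <- match(groups, key)
  PatientProfile(score, nmat, patientId = cd$patientId[first],
                 compartment = cd$compartment[first],
                 markerData = rowData(x))
}

#' Replicate concordance
#'
#' Spearman rank correlation per marker and compartment between two
#' processed runs over their shared patients, with a per-compartment
#' summary (median, min, max). Markers with fewer than three shared
#' patients in a compartment are omitted with a warning.
#'
#' @param profile1,profile2 two [PatientProfile-class] objects sharing
#'   patient and marker keys.
#' @return a list with \code{per_marker} (marker, compartment, n, rho) and
#'   \code{summary} (compartment, median/min/max rho).
#' @export
replicateConcordance <- function(profile1, profile2) {
  res <- list()
  for (compartment in c("tumor", "stroma")) {
    m1 <- profileMatrix(profile1, compartment)
    m2 <- profileMatrix(profile2, compartment)
    shared_p <- intersect(rownames(m1), rownames(m2))
    shared_m <- intersect(colnames(m1), colnames(m2))
    for (mk in shared_m) {
      v1 <- m1[shared_p, mk]
      v2 <- m2[shared_p, mk]
      ok <- stats::complete.cases(v1, v2)
      if (sum(ok) < 3L) {
        warning(sprintf("marker '%s' (%s): <3 shared patients; omitted",
                        mk, compartment))
        next
      }
      rho <- suppressWarnings(
        stats::cor(v1[ok], v2[ok], method = "spearman"))
      res[[length(res) + 1L]] <-
        data.frame(marker_id = mk, compartment = compartment,
                   n = sum(ok), rho = rho, stringsAsFactors = FALSE)
    }
  }
  per_marker <- if (length(res)) do.call(rbind, res) else
    data.frame(marker_id = character(0), compartment = character(0),
               n = integer(0), rho = numeric(0))
  summary <- do.call(rbind, lapply(split(per_marker, per_marker$compartment),
                                   function(d) {
    data.frame(compartment = d$compartment[1], n_markers = nrow(d),
               median_rho = stats::median(d$rho), min_rho = min(d$rho),
               max_rho = max(d$rho), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_marker = per_marker, summary = summary)
}

#' Run the full processing chain on a raw cohort
#'
#' Convenience wrapper: spike-in normalization, SNR, detection filter,
#' floor imputation, batch calibration and patient aggregation in order.
#'
#' @param x a raw-stage [DspExperiment-class] with ROI annotations.
#' @param params a [qcParams()].
#' @return a list with \code{profile}, \code{snr} (the calibrated
#'   [DspExperiment-class]), \code{filter} (retained/dropped/report) and
#'   \code{calibration}.
#' @export
processCohort <- function(x, params = qcParams()) {
  norm <- switch(params$normalization_mode,
                 spikein = normalizeSpikeIn(x),
                 housekeeping = stop(
                   "use normalizeHousekeeping() directly for this mode",
                   call. = FALSE),
                 none = x)
  snr <- computeSNR(norm, params)
  flt <- detectionFilter(snr, params)
  floored <- imputeFloor(flt$object, params)
  cal <- calibrateBatches(floored, params)
  profile <- aggregatePatients(cal$object)
  list(profile = profile, snr = cal$object, filter = flt,
       calibration = cal$calibration)
}
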