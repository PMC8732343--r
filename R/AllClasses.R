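#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<- colData colData<-
NULL

.MARKER_CLASSES <- c("experimental", "positive_control", "negative_control")
.COMPARTMENTS <- c("tumor", "stroma")
.STAGES <- c("raw", "spikein_normalized", "snr", "calibrated")

#' DspExperiment: ROI-level digital spatial profiling container
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one assay of
#' marker values per region of interest (ROI). Rows are panel markers
#' (\code{rowData} carries the panel manifest: \code{markerClass},
#' \code{displayName}, \code{isotype}); columns are ROI segments
#' (\code{colData} carries the ROI-to-patient map: \code{patientId},
#' \code{coreId}, \code{compartment}, \code{batchId}, \code{replicateId}).
#' The processing stage (\code{"raw"}, \code{"spikein_normalized"},
#' \code{"snr"}, \code{"calibrated"}) is tracked in \code{metadata()} and
#' enforced by every pipeline operation, so stages can only move forward.
#'
#' @seealso [DspExperiment()], [dspStage()], [normalizeSpikeIn()]
#' @export
setClass("DspExperiment", contains = "SummarizedExperiment")

setValidity("DspExperiment", function(object) {
  msg <- character(0)
  rd <- rowData(object)
  if (!"markerClass" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain a 'markerClass' column")
  } else if (!all(rd$markerClass %in% .MARKER_CLASSES)) {
    msg <- c(msg, sprintf("markerClass values must be one of: %s",
                          paste(.MARKER_CLASSES, collapse = ", ")))
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "marker ids (rownames) must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "ROI ids (colnames) must be present and unique")
  }
  stage <- metadata(object)$stage
  if (is.null(stage) || !stage %in% .STAGES) {
    msg <- c(msg, sprintf("metadata()$stage must be one of: %s",
                          paste(.STAGES, collapse = ", ")))
  }
  if (length(assayNames(object)) >= 1L) {
    a <- assay(object, 1L)
    if (any(is.finite(a) & a < 0)) {
      msg <- c(msg, "assay values must be non-negative")
    }
  }
  cd <- colData(object)
  if ("compartment" %in% colnames(cd)) {
    comp <- cd$compartment
    if (!all(is.na(comp) | comp %in% .COMPARTMENTS)) {
      msg <- c(msg, "compartment must be 'tumor' or 'stroma'")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DspExperiment
#'
#' @param counts numeric matrix of non-negative marker values with ROIs in
#'   rows and markers in columns (the layout of the input count tables), or
#'   markers in rows and ROIs in columns; orientation is resolved against the
#'   manifest marker ids.
#' @param manifest a \code{data.frame} panel manifest with columns
#'   \code{marker_id}, \code{marker_class} (one of \code{"experimental"},
#'   \code{"positive_control"}, \code{"negative_control"}) and optionally
#'   \code{display_name} and \code{isotype}.
#' @param roiData optional \code{data.frame} keyed by \code{roi_id} with
#'   columns \code{patient_id}, \code{core_id}, \code{compartment},
#'   \code{batch_id} and optionally \code{replicate_id}, \code{segment_area}.
#' @param stage processing stage tag, default \code{"raw"}.
#' @return a [DspExperiment-class] object.
#' @examples
#' mani <- data.frame(marker_id = c("A", "B", "NC1"),
#'                    marker_class = c("experimental", "experimental",
#'                                     "negative_control"))
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("r1", "r2"), mani$marker_id))
#' dsp <- DspExperiment(m, mani)
#' dspStage(dsp)
#' @export
DspExperiment <- function(counts, manifest, roiData = NULL, stage = "raw") {
  manifest <- .checkManifest(manifest)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have ROI and marker names", call. = FALSE)
  }
  ## orient to markers x ROIs
  if (all(manifest$marker_id %in% colnames(counts))) {
    counts <- t(counts)
  } else if (!all(manifest$marker_id %in% rownames(counts))) {
    missing <- setdiff(manifest$marker_id,
                       union(rownames(counts), colnames(counts)))
    stop(sprintf("count matrix is missing manifest marker(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(rownames(counts), manifest$marker_id)
  if (length(extra)) {
    warning(sprintf("dropping %d column(s) not in the manifest: %s",
                    length(extra), paste(extra, collapse = ", ")))
    counts <- counts[manifest$marker_id, , drop = FALSE]
  }
  counts <- counts[manifest$marker_id, , drop = FALSE]
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count at marker '%s', ROI '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]),
         call. = FALSE)
  }
  if (!any(manifest$marker_class == "negative_control")) {
    stop("manifest must declare at least one negative-control marker",
         call. = FALSE)
  }
  rd <- DataFrame(markerClass = manifest$marker_class,
                  displayName = if ("display_name" %in% names(manifest))
                    manifest$display_name else manifest$marker_id,
                  isotype = if ("isotype" %in% names(manifest))
                    manifest$isotype else NA_character_,
                  row.names = manifest$marker_id)
  cd <- .checkRoiData(roiData, colnames(counts))
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = rd, colData = cd,
    metadata = list(stage = stage, filtered = FALSE, floored = FALSE))
  new("DspExperiment", se)
}

.checkManifest <- function(manifest) {
  manifest <- as.data.frame(manifest)
  req <- c("marker_id", "marker_class")
  if (!all(req %in% names(manifest))) {
    stop("manifest needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$marker_id)) {
    stop("duplicate marker_id in manifest", call. = FALSE)
  }
  if (!all(manifest$marker_class %in% .MARKER_CLASSES)) {
    stop("marker_class must be one of: ",
         paste(.MARKER_CLASSES, collapse = ", "), call. = FALSE)
  }
  manifest
}

.checkRoiData <- function(roiData, roi_ids) {
  if (is.null(roiData)) {
    return(DataFrame(row.names = roi_ids))
  }
  roiData <- as.data.frame(roiData)
  if (!"roi_id" %in% names(roiData)) {
    stop("roiData needs a 'roi_id' column", call. = FALSE)
  }
  if (anyDuplicated(roiData$roi_id)) {
    stop("duplicate roi_id in ROI map", call. = FALSE)
  }
  missing <- setdiff(roi_ids, roiData$roi_id)
  if (length(missing)) {
    stop(sprintf("ROI map is missing ROI(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  roiData <- roiData[match(roi_ids, roiData$roi_id), , drop = FALSE]
  cd <- DataFrame(row.names = roi_ids)
  rename <- c(patient_id = "patientId", core_id = "coreId",
              compartment = "compartment", batch_id = "batchId",
              replicate_id = "replicateId", segment_area = "segmentArea")
  for (nm in names(rename)) {
    if (nm %in% names(roiData)) {
      cd[[rename[[nm]]]] <- roiData[[nm]]
    }
  }
  if ("compartment" %in% colnames(cd) &&
      !all(is.na(cd$compartment) | cd$compartment %in% .COMPARTMENTS)) {
    stop("compartment must be 'tumor' or 'stroma'", call. = FALSE)
  }
  cd
}

#' Processing stage of a DspExperiment
#'
#' @param x a [DspExperiment-class].
#' @return the stage tag, one of \code{"raw"}, \code{"spikein_normalized"},
#'   \code{"snr"}, \code{"calibrated"}.
#' @export
dspStage <- function(x) {
  metadata(x)$stage
}

.advanceStage <- function(x, from, to) {
  cur <- dspStage(x)
  if (!cur %in% from) {
    stop(sprintf("operation requires stage %s but object is at stage '%s'",
                 paste(sQuote(from), collapse = " or "), cur), call. = FALSE)
  }
  metadata(x)$stage <- to
  x
}

#' Marker metadata accessors
#'
#' Convenience accessors over \code{rowData}: the marker classes and the ids
#' of experimental, positive-control (spike-in) and negative-control
#' (isotype) markers.
#'
#' @param x a [DspExperiment-class].
#' @return character vector of marker ids (or classes for
#'   \code{markerClasses}).
#' @export
markerClasses <- function(x) {
  stats::setNames(rowData(x)$markerClass, rownames(x))
}

#' @rdname markerClasses
#' @export
experimentalMarkers <- function(x) {
  rownames(x)[rowData(x)$markerClass == "experimental"]
}

#' @rdname markerClasses
#' @export
positiveControlMarkers <- function(x) {
  rownames(x)[rowData(x)$markerClass == "positive_control"]
}

#' @rdname markerClasses
#' @export
negativeControlMarkers <- function(x) {
  rownames(x)[rowData(x)$markerClass == "negative_control"]
}

#' ROI annotation of a DspExperiment
#'
#' @param x a [DspExperiment-class].
#' @return \code{colData} as a base \code{data.frame} with an \code{roi_id}
#'   column.
#' @export
roiData <- function(x) {
  df <- as.data.frame(colData(x))
  df <- cbind(roi_id = colnames(x), df)
  rownames(df) <- NULL
  df
}

setMethod("show", "DspExperiment", function(object) {
  cls <- table(factor(rowData(object)$markerClass, levels = .MARKER_CLASSES))
  cat(sprintf("DspExperiment [stage: %s]\n", dspStage(object)))
  cat(sprintf("  %d markers (%d experimental, %d positive ctrl, %d negative ctrl) x %d ROIs\n",
              nrow(object), cls[["experimental"]], cls[["positive_control"]],
              cls[["negative_control"]], ncol(object)))
  if ("compartment" %in% colnames(colData(object))) {
    comp <- table(colData(object)$compartment)
    cat("  compartments:",
        paste(sprintf("%s=%d", names(comp), comp), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' PatientProfile: per-patient, per-compartment mean marker scores
#'
#' A \linkS4class{SummarizedExperiment} subclass whose columns are
#' (patient, compartment) pairs and rows are markers. Assay \code{"score"}
#' holds the mean calibrated signal-to-noise value over the contributing
#' ROIs; assay \code{"nROIs"} holds the contributing-ROI counts. This is the
#' unit of every downstream statistical analysis. Patients lacking a
#' compartment simply have no column for it.
#'
#' @export
setClass("PatientProfile", contains = "SummarizedExperiment")

setValidity("PatientProfile", function(object) {
  msg <- character(0)
  if (!all(c("score", "nROIs") %in% assayNames(object))) {
    msg <- c(msg, "assays 'score' and 'nROIs' are required")
  }
  cd <- colData(object)
  if (!all(c("patientId", "compartment") %in% colnames(cd))) {
    msg <- c(msg, "colData needs 'patientId' and 'compartment'")
  } else if (!all(cd$compartment %in% .COMPARTMENTS)) {
    msg <- c(msg, "compartment must be 'tumor' or 'stroma'")
  }
  if ("nROIs" %in% assayNames(object)) {
    n <- assay(object, "nROIs")
    sc <- assay(object, "score")
    if (any(!is.na(sc) & (is.na(n) | n < 1))) {
      msg <- c(msg, "every score must have >= 1 contributing ROI")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PatientProfile
#'
#' @param score markers x (patient, compartment) matrix of mean scores.
#' @param nROIs matching matrix of contributing-ROI counts.
#' @param patientId,compartment per-column annotations.
#' @param markerData optional \code{DataFrame} of marker metadata.
#' @return a [PatientProfile-class].
#' @export
PatientProfile <- function(score, nROIs, patientId, compartment,
                           markerData = NULL) {
  score <- as.matrix(score)
  if (is.null(markerData)) {
    markerData <- DataFrame(row.names = rownames(score))
  }
  se <- SummarizedExperiment(
    assays = SimpleList(score = score, nROIs = as.matrix(nROIs)),
    rowData = markerData,
    colData = DataFrame(patientId = patientId, compartment = compartment,
                        row.names = colnames(score)))
  new("PatientProfile", se)
}

#' Extract a patients-by-markers score matrix for one compartment
#'
#' @param profile a [PatientProfile-class].
#' @param compartment \code{"tumor"} or \code{"stroma"}.
#' @param markers optional marker subset.
#' @return numeric matrix, rows = patients, columns = markers.
#' @export
profileMatrix <- function(profile, compartment = c("tumor", "stroma"),
                          markers = NULL) {
  compartment <- match.arg(compartment)
  keep <- colData(profile)$compartment == compartment
  m <- t(assay(profile, "score")[, keep, drop = FALSE])
  rownames(m) <- colData(profile)$patientId[keep]
  if (!is.null(markers)) {
    m <- m[, markers, drop = FALSE]
  }
  m
}

#' @rdname profileMatrix
#' @export
profilePatients <- function(profile) {
  unique(colData(profile)$patientId)
}

setMethod("show", "PatientProfile", function(object) {
  cd <- colData(object)
  cat(sprintf("PatientProfile: %d markers x %d patient-compartment columns\n",
              nrow(object), ncol(object)))
  cat(sprintf("  %d patients; tumor columns: %d, stroma columns: %d\n",
              length(unique(cd$patientId)), sum(cd$compartment == "tumor"),
              sum(cd$compartment == "stroma")))
  invisible(NULL)
})

#' Quality-control and processing parameters
#'
#' Bundles the tunable constants of the processing chain: the
#' signal-to-noise detection threshold (default 3), the imputation floor
#' (default \eqn{3/\sqrt{2} \approx 2.1213}) substituted for values below
#' the detection limit, the maximum tolerated fraction of undetected values
#' per compartment before a marker is dropped (default 0.5, strict), the
#' negative-control denominator mode, and the normalization mode.
#'
#' @param snr_threshold positive detection cutoff on the signal-to-noise
#'   ratio.
#' @param floor_value constant substituted for values below the threshold;
#'   must be below \code{snr_threshold}.
#' @param max_undetected_fraction in (0, 1); a marker is dropped when
#'   strictly more than this fraction of its values in either compartment is
#'   undetected.
#' @param snr_denominator \code{"geometric_mean_all_nc"} (pooled geometric
#'   mean of all negative isotype controls in the ROI, the default) or
#'   \code{"isotype_matched"} (geometric mean of the controls sharing the
#'   marker's isotype host).
#' @param normalization_mode \code{"spikein"} (default), \code{"housekeeping"}
#'   or \code{"none"}.
#' @return an object of class \code{QcParams}.
#' @examples
#' p <- qcParams()
#' p$floor_value            # 3 / sqrt(2)
#' @export
qcParams <- function(snr_threshold = 3,
                     floor_value = 3 / sqrt(2),
                     max_undetected_fraction = 0.5,
                     snr_denominator = c("geometric_mean_all_nc",
                                         "isotype_matched"),
                     normalization_mode = c("spikein", "housekeeping",
                                            "none")) {
  snr_denominator <- match.arg(snr_denominator)
  normalization_mode <- match.arg(normalization_mode)
  stopifnot(snr_threshold > 0,
            floor_value < snr_threshold,
            max_undetected_fraction > 0, max_undetected_fraction < 1)
  structure(list(snr_threshold = snr_threshold,
                 floor_value = floor_value,
                 max_undetected_fraction = max_undetected_fraction,
                 snr_denominator = snr_denominator,
                 normalization_mode = normalization_mode),
            class = "QcParams")
}
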