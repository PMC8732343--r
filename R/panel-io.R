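## Readers and writers for every table the pipeline touches. All readers
## validate strictly and return checked in-memory structures; the delimiter
## (tab or comma) is auto-detected from the header line.

.RACE_MAP <- list(Black = c("black"), White = c("white"))
.POSNEG_MAP <- list(POS = c("pos", "positive", "+", "1"),
                    NEG = c("neg", "negative", "-", "0"))
.SUBTYPE_MAP <- list(LuminalA = c("luminala", "luminal a", "luminal_a"),
                     HER2positive = c("her2positive", "her2-positive",
                                      "her2 positive", "her2+"),
                     TripleNegative = c("triplenegative", "triple-negative",
                                        "triple negative", "tnbc"))
.BMI_MAP <- list(`<25` = c("<25", "under25", "normal"),
                 `25-29` = c("25-29", "25–29", "overweight"),
                 `30+` = c("30+", ">=30", "obese"))
.STAGE_MAP <- list(I = c("i", "1"), II = c("ii", "2"),
                   `III/IV` = c("iii/iv", "iii", "iv", "3", "4", "3/4"))
.GRADE_MAP <- list(LOW = c("low", "well"), MED = c("med", "intermediate",
                                                   "moderate"),
                   HIGH = c("high", "poor"))
.SIZE_MAP <- list(`<1.0` = c("<1.0", "<1"), `1-1.9` = c("1-1.9", "1.0-1.9",
                                                        "1–1.9"),
                  `>=2.0` = c(">=2.0", "≥2.0", "2.0+", ">2.0"))
.VITAL_MAP <- list(alive = c("alive", "0"), dead = c("dead", "deceased", "1"))

#' Read a panel manifest
#'
#' @param path delimited text file with columns \code{marker_id},
#'   \code{marker_class} and optionally \code{display_name}, \code{isotype}.
#' @return validated manifest \code{data.frame}.
#' @export
readPanelManifest <- function(path) {
  df <- .readDelim(path)
  .checkManifest(df)
}

#' Read an ROI-level count table
#'
#' The file must have a header of marker ids and one row per ROI, with the
#' ROI id in the first column. Every manifest marker must be present;
#' negative cells and duplicate ROI ids are fatal.
#'
#' @param path delimited text file.
#' @param manifest panel manifest \code{data.frame} (see
#'   [readPanelManifest()]).
#' @param roiMap optional ROI map \code{data.frame} (see [readRoiMap()]).
#' @return a [DspExperiment-class] at stage \code{"raw"}.
#' @export
readCounts <- function(path, manifest, roiMap = NULL) {
  df <- .readDelim(path)
  if (ncol(df) < 2L) {
    stop("count table needs an ROI id column plus marker columns",
         call. = FALSE)
  }
  roi_id <- as.character(df[[1L]])
  if (anyDuplicated(roi_id)) {
    stop(sprintf("duplicate roi_id in count table: %s",
                 paste(unique(roi_id[duplicated(roi_id)]), collapse = ", ")),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    stop("non-numeric cell(s) in count table", call. = FALSE)
  }
  rownames(m) <- roi_id
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count at row '%s', column '%s'",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]),
         call. = FALSE)
  }
  manifest <- .checkManifest(manifest)
  nc <- manifest$marker_id[manifest$marker_class == "negative_control"]
  if (!all(nc %in% colnames(m))) {
    stop(sprintf("count table is missing negative-control column(s): %s",
                 paste(setdiff(nc, colnames(m)), collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(manifest$marker_id, colnames(m))
  if (length(missing)) {
    stop(sprintf("count table is missing manifest marker(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  DspExperiment(m, manifest, roiData = roiMap, stage = "raw")
}

#' Read an ROI-to-patient map
#'
#' @param path delimited text with columns \code{roi_id}, \code{patient_id},
#'   \code{core_id}, \code{compartment}, \code{batch_id} and optionally
#'   \code{replicate_id}, \code{segment_area}.
#' @param clinical optional clinical table; if given, every
#'   \code{patient_id} must exist in it.
#' @return validated \code{data.frame}.
#' @export
readRoiMap <- function(path, clinical = NULL) {
  df <- .readDelim(path)
  req <- c("roi_id", "patient_id", "compartment")
  if (!all(req %in% names(df))) {
    stop("ROI map needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$roi_id)) {
    stop("duplicate roi_id in ROI map", call. = FALSE)
  }
  df$compartment <- .normalizeLevels(
    df$compartment, list(tumor = "tumor", stroma = c("stroma", "stromal")),
    field = "compartment", allow_missing = FALSE)
  if (!is.null(clinical)) {
    unknown <- setdiff(df$patient_id, clinical$patient_id)
    if (length(unknown)) {
      stop(sprintf("ROI map references unknown patient(s): %s",
                   paste(utils::head(unknown, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}

#' Read and validate a clinical table
#'
#' Category labels are normalized case-insensitively against a fixed synonym
#' map to the canonical spellings (\code{Black}/\code{White},
#' \code{POS}/\code{NEG}, \code{LuminalA}/\code{HER2positive}/
#' \code{TripleNegative}, ...). Missing cells are kept as \code{NA};
#' downstream analyses decide exclusion. The molecular subtype must be
#' consistent with the receptor status under the standard rule (luminal A =
#' HR+/HER2-; HER2-positive = any HER2+; triple-negative = HR-/HER2-), and a
#' breast-cancer death implies vital status dead.
#'
#' @param path delimited text file with a \code{patient_id} column plus the
#'   demographic/pathology/follow-up fields.
#' @return validated \code{data.frame}, one row per patient.
#' @export
readClinical <- function(path) {
  df <- .readDelim(path)
  if (nrow(df) == 0L) {
    warning("clinical table is empty")
    return(df)
  }
  if (!"patient_id" %in% names(df)) {
    stop("clinical table needs a 'patient_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  norm <- function(col, map, allow_missing = TRUE) {
    if (col %in% names(df)) {
      df[[col]] <<- .normalizeLevels(df[[col]], map, field = col,
                                     allow_missing = allow_missing)
    }
  }
  norm("race", .RACE_MAP, allow_missing = FALSE)
  for (col in c("er_status", "pr_status", "her2_status", "ln_status")) {
    norm(col, .POSNEG_MAP)
  }
  norm("subtype", .SUBTYPE_MAP)
  norm("bmi_category", .BMI_MAP)
  norm("stage", .STAGE_MAP)
  norm("grade", .GRADE_MAP)
  norm("tumor_size_cat", .SIZE_MAP)
  norm("vital_status", .VITAL_MAP)
  if ("breast_cancer_death" %in% names(df)) {
    df$breast_cancer_death <- as.logical(df$breast_cancer_death)
  }
  .checkSubtypeConsistency(df)
  if (all(c("breast_cancer_death", "vital_status") %in% names(df))) {
    bad <- !is.na(df$breast_cancer_death) & df$breast_cancer_death &
      !is.na(df$vital_status) & df$vital_status != "dead"
    if (any(bad)) {
      stop(sprintf("breast_cancer_death without vital_status 'dead' for: %s",
                   paste(df$patient_id[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  if ("followup_years" %in% names(df) &&
      any(!is.na(df$followup_years) & df$followup_years < 0)) {
    stop("negative followup_years", call. = FALSE)
  }
  df
}

.checkSubtypeConsistency <- function(df) {
  need <- c("subtype", "er_status", "pr_status", "her2_status")
  if (!all(need %in% names(df))) {
    return(invisible(NULL))
  }
  hr_pos <- df$er_status == "POS" | df$pr_status == "POS"
  expected <- ifelse(df$her2_status == "POS", "HER2positive",
                     ifelse(hr_pos, "LuminalA", "TripleNegative"))
  complete <- stats::complete.cases(df[, need])
  bad <- complete & df$subtype != expected
  if (any(bad)) {
    stop(sprintf(
      "subtype inconsistent with receptor status for patient(s): %s",
      paste(df$patient_id[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Write a results table with the standard layout and formatting
#'
#' Numeric formatting follows the published table conventions: medians and
#' IQRs to two decimals, p/q-values in scientific notation. If the results
#' carry a \code{"file_columns"} attribute (set by the analysis functions),
#' only those columns are written, in that order.
#'
#' @param results a results \code{data.frame} from a downstream module.
#' @param path output file path; tab-delimited.
#' @return the path, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  results <- as.data.frame(results)
  cols <- attr(results, "file_columns")
  if (!is.null(cols)) {
    results <- results[, intersect(cols, names(results)), drop = FALSE]
  }
  out <- results
  for (nm in names(out)) {
    if (grepl("(median|iqr)$", nm, ignore.case = TRUE)) {
      out[[nm]] <- sprintf("%.2f", results[[nm]])
    } else if (grepl("(^|_)(p|q)(_value)?$", nm)) {
      out[[nm]] <- sprintf("%.3e", results[[nm]])
    }
  }
  ok <- tryCatch({
    .writeDelim(out, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write results table to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  .readDelim(path)
}

#' Read or write a patient-profile table
#'
#' The on-disk layout mirrors the deposited per-patient dataset: one row per
#' (patient, compartment), one column per marker, preceded by
#' \code{patient_id} and \code{compartment} columns. An optional
#' \code{n_rois} column carries contributing-ROI counts; when absent the
#' counts are recorded as 1 (the file resolution does not retain them).
#'
#' @param path delimited text file.
#' @return [readPatientProfileTable()]: a [PatientProfile-class];
#'   [writePatientProfileTable()]: the path, invisibly.
#' @export
readPatientProfileTable <- function(path) {
  df <- .readDelim(path)
  req <- c("patient_id", "compartment")
  if (!all(req %in% names(df))) {
    stop("profile table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df$compartment <- .normalizeLevels(
    df$compartment, list(tumor = "tumor", stroma = c("stroma", "stromal")),
    field = "compartment", allow_missing = FALSE)
  meta_cols <- intersect(c("patient_id", "compartment", "n_rois"), names(df))
  markers <- setdiff(names(df), meta_cols)
  score <- t(as.matrix(df[, markers, drop = FALSE]))
  colnames(score) <- paste(df$patient_id, df$compartment, sep = ".")
  n <- if ("n_rois" %in% names(df)) {
    matrix(rep(df$n_rois, each = nrow(score)), nrow = nrow(score),
           dimnames = dimnames(score))
  } else {
    matrix(1, nrow(score), ncol(score), dimnames = dimnames(score))
  }
  PatientProfile(score, n, df$patient_id, df$compartment)
}

#' @rdname readPatientProfileTable
#' @param profile a [PatientProfile-class].
#' @export
writePatientProfileTable <- function(profile, path) {
  cd <- colData(profile)
  df <- data.frame(patient_id = cd$patientId, compartment = cd$compartment,
                   n_rois = apply(assay(profile, "nROIs"), 2, max),
                   t(assay(profile, "score")), check.names = FALSE)
  .writeDelim(df, path)
  invisible(path)
}

#' Write a DspExperiment assay as a delimited ROI x marker table
#'
#' @param x a [DspExperiment-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCounts <- function(x, path) {
  df <- data.frame(roi_id = colnames(x), t(assay(x, 1L)),
                   check.names = FALSE)
  .writeDelim(df, path)
  invisible(path)
}
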