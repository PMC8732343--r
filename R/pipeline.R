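## End-to-end orchestration: simulate (or read) -> QC -> differential ->
## survival -> exploratory, written to a deterministic directory layout
## with a run manifest (package version, config hash, seed).

#' Run configuration
#'
#' Either \code{sim_config} (synthetic run) or the four input paths
#' (\code{counts}, \code{manifest}, \code{roi_map}, \code{clinical}) must
#' be supplied. All thresholds surface through \code{qc_params}.
#'
#' @param out_dir output directory.
#' @param sim_config a [dspSimConfig()] for synthetic runs, or NULL.
#' @param counts,manifest,roi_map,clinical input file paths for real-data
#'   runs.
#' @param qc_params a [qcParams()].
#' @param comparisons subset of \code{c("compartment", "er", "her2",
#'   "race", "race-unadjusted")}.
#' @param endpoints subset of \code{c("os", "bcss")}; empty to skip
#'   survival.
#' @param seed integer seed recorded in the manifest; overrides the seed in
#'   \code{sim_config}.
#' @return a validated \code{RunConfig} list.
#' @export
runConfig <- function(out_dir,
                      sim_config = dspSimConfig(),
                      counts = NULL, manifest = NULL, roi_map = NULL,
                      clinical = NULL,
                      qc_params = qcParams(),
                      comparisons = c("compartment", "er", "race"),
                      endpoints = c("os", "bcss"),
                      seed = 1L) {
  paths <- c(counts = counts, manifest = manifest, roi_map = roi_map,
             clinical = clinical)
  if (is.null(sim_config)) {
    if (length(paths) < 4L || !all(file.exists(paths))) {
      stop("real-data runs need existing counts/manifest/roi_map/clinical paths",
           call. = FALSE)
    }
  }
  bad <- setdiff(comparisons,
                 c("compartment", "er", "her2", "race", "race-unadjusted"))
  if (length(bad)) {
    stop("unknown comparison(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(endpoints)) {
    stopifnot(all(endpoints %in% c("os", "bcss")))
  }
  structure(list(out_dir = out_dir, sim_config = sim_config,
                 paths = paths, qc_params = qc_params,
                 comparisons = comparisons, endpoints = endpoints,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[setdiff(names(config), "out_dir")], file = tmp)
  unname(tools::md5sum(tmp))
}

.log <- function(con, ...) {
  msg <- sprintf(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the whole pipeline
#'
#' Executes every stage and writes \code{qc/}, \code{differential/},
#' \code{survival/} (only when endpoints are requested),
#' \code{exploratory/}, \code{logs/} and \code{manifest.txt} under the
#' configured output directory. A stage failure aborts with the stage name;
#' partial outputs are preserved. Identical config + seed reproduces the
#' output byte for byte.
#'
#' @param config a [runConfig()].
#' @return the output directory, invisibly.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$out_dir
  dir.create(file.path(out, "logs"), recursive = TRUE,
             showWarnings = FALSE)
  logcon <- file(file.path(out, "logs", "run.log"), open = "wt")
  on.exit(close(logcon))
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$sim_config)) {
      sim <- config$sim_config
      sim$seed <- config$seed
      cohort <- simulateCohort(sim)
      dsp <- cohort$dsp
      clinical <- cohort$clinical
      .log(logcon, "simulated cohort: %d patients, %d ROIs",
           nrow(clinical), ncol(dsp))
    } else {
      manifest <- readPanelManifest(config$paths[["manifest"]])
      clinical <- readClinical(config$paths[["clinical"]])
      roi_map <- readRoiMap(config$paths[["roi_map"]], clinical)
      dsp <- readCounts(config$paths[["counts"]], manifest, roi_map)
      .log(logcon, "read cohort: %d patients, %d ROIs",
           nrow(clinical), ncol(dsp))
    }

    stage <- "qc"
    dir.create(file.path(out, "qc"), showWarnings = FALSE)
    qc <- processCohort(dsp, config$qc_params)
    writeResultsTable(qc$filter$report,
                      file.path(out, "qc", "detection_report.tsv"))
    writeLines(qc$filter$retained,
               file.path(out, "qc", "retained_markers.txt"))
    writeLines(qc$filter$dropped,
               file.path(out, "qc", "dropped_markers.txt"))
    .writeDelim(data.frame(marker_id = rownames(qc$calibration$corrections),
                           qc$calibration$corrections,
                           check.names = FALSE),
                file.path(out, "qc", "batch_corrections.tsv"))
    writePatientProfileTable(qc$profile,
                             file.path(out, "qc", "patient_profiles.tsv"))
    .log(logcon, "qc: %d retained, %d dropped markers",
         length(qc$filter$retained), length(qc$filter$dropped))

    stage <- "differential"
    dir.create(file.path(out, "differential"), showWarnings = FALSE)
    profile <- qc$profile
    for (cmp in config$comparisons) {
      res <- switch(cmp,
        compartment = compareCompartments(profile),
        er = do.call(rbind, lapply(c("tumor", "stroma"), function(cc)
          compareGroups(profile, clinical, "er_status", cc,
                        params = config$qc_params))),
        her2 = do.call(rbind, lapply(c("tumor", "stroma"), function(cc)
          compareGroups(profile, clinical, "her2_status", cc,
                        params = config$qc_params))),
        race = do.call(rbind, lapply(c("tumor", "stroma"), function(cc)
          ancovaRace(profile, clinical, cc))),
        `race-unadjusted` = do.call(rbind,
          lapply(c("tumor", "stroma"), function(cc)
            ancovaRace(profile, clinical, cc,
                       covariates = character(0)))))
      writeResultsTable(res, file.path(out, "differential",
                                       paste0(cmp, ".tsv")))
      .log(logcon, "differential: wrote %s (%d rows)", cmp, nrow(res))
    }

    if (length(config$endpoints)) {
      stage <- "survival"
      dir.create(file.path(out, "survival"), showWarnings = FALSE)
      for (ep in config$endpoints) {
        scr <- runSurvivalScreen(profile, clinical, ep)
        writeResultsTable(scr, file.path(out, "survival",
                                         paste0("screen_", ep, ".tsv")))
        .log(logcon, "survival: %s screen, %d rows", ep, nrow(scr))
      }
    }

    stage <- "exploratory"
    dir.create(file.path(out, "exploratory"), showWarnings = FALSE)
    mat <- t(assay(profile, "score"))
    lmat <- log2(mat)
    cl <- clusterHeatmap(lmat)
    .writeDelim(data.frame(observation = rownames(cl$matrix)[cl$row_order]),
                file.path(out, "exploratory", "row_order.tsv"))
    .writeDelim(data.frame(height = cl$row_hclust$height),
                file.path(out, "exploratory", "row_merge_heights.tsv"))
    pca <- pcaCheck(lmat, colData(profile)$compartment)
    .writeDelim(data.frame(observation = rownames(lmat),
                           compartment = colData(profile)$compartment,
                           PC1 = pca$scores[, 1],
                           PC2 = pca$scores[, 2]),
                file.path(out, "exploratory", "pca_scores.tsv"))
    .writeDelim(data.frame(component = seq_along(pca$var_explained),
                           var_explained = pca$var_explained),
                file.path(out, "exploratory", "pca_variance.tsv"))
    .log(logcon, "exploratory: PC1 compartment separation %.3f",
         pca$separation)

    stage <- "manifest"
    writeLines(c(
      sprintf("package_version: %s",
              as.character(utils::packageVersion("dspTools"))),
      sprintf("config_hash: %s", .configHash(config)),
      sprintf("seed: %d", config$seed),
      sprintf("stages: qc differential%s exploratory",
              if (length(config$endpoints)) " survival" else "")),
      file.path(out, "manifest.txt"))
    out
  }, error = function(e) {
    .log(logcon, "FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
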