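## Differential-abundance and concordance statistics on patient profiles.
## Tests run on log2 scores; medians and IQRs are always reported on the
## linear signal-to-noise scale, matching the published table conventions.
## Each Benjamini-Hochberg family is one comparison within one compartment
## (the paired compartment comparison forms a single family), and the
## family id and size are recorded in every result row.

.FLOOR_TIE_FRACTION <- 0.2

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment via \code{stats::p.adjust}; missing p-values
#' propagate as missing and are excluded from the ranking.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

.resultRow <- function(marker, comparison, g1, g2, labels, test, stat, p) {
  med <- function(v) stats::median(v, na.rm = TRUE)
  data.frame(marker = marker, comparison = comparison,
             group1 = labels[1], group2 = labels[2],
             group1_median = med(g1), group1_iqr = .iqr(g1),
             group2_median = med(g2), group2_iqr = .iqr(g2),
             n1 = sum(!is.na(g1)), n2 = sum(!is.na(g2)),
             test = test, statistic = stat, p = p,
             stringsAsFactors = FALSE)
}

#' Paired tumor-vs-stroma comparison
#'
#' Per marker, a paired t-test on log2 scores over the patients carrying
#' both compartments; markers with fewer than three complete pairs are
#' skipped with a warning. Medians and IQRs are reported per compartment on
#' the linear scale, and q-values come from one Benjamini-Hochberg family
#' across all tested markers.
#'
#' @param profile a [PatientProfile-class].
#' @param markers markers to test; default all experimental markers in the
#'   profile (all markers when no class annotation is present).
#' @return a \code{data.frame} with one row per marker: compartment
#'   medians/IQRs, t statistic, p, q.
#' @export
compareCompartments <- function(profile, markers = NULL) {
  if (is.null(markers)) {
    markers <- .analysisMarkers(profile)
  }
  tum <- profileMatrix(profile, "tumor")
  str <- profileMatrix(profile, "stroma")
  shared <- intersect(rownames(tum), rownames(str))
  rows <- list()
  for (m in markers) {
    x <- tum[shared, m]
    y <- str[shared, m]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) {
      warning(sprintf("marker '%s': <3 complete pairs; skipped", m))
      next
    }
    d <- log2(x[ok]) - log2(y[ok])
    if (all(d == 0)) {
      stat <- 0
      p <- 1
    } else if (stats::sd(d) == 0) {
      ## constant nonzero paired difference: the t statistic diverges
      stat <- sign(mean(d)) * Inf
      p <- 0
    } else {
      tt <- stats::t.test(log2(x[ok]), log2(y[ok]), paired = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    r <- .resultRow(m, "tumor_vs_stroma", x[ok], y[ok],
                    c("tumor", "stroma"), "paired_t", stat, p)
    rows[[length(rows) + 1L]] <- r
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    stop("no marker had enough complete pairs", call. = FALSE)
  }
  res$q <- bhFdr(res$p)
  res$family <- "tumor_vs_stroma"
  res$family_size <- nrow(res)
  names(res)[names(res) == "group1_median"] <- "tumor_median"
  names(res)[names(res) == "group1_iqr"] <- "tumor_iqr"
  names(res)[names(res) == "group2_median"] <- "stroma_median"
  names(res)[names(res) == "group2_iqr"] <- "stroma_iqr"
  attr(res, "file_columns") <- c("marker", "tumor_median", "tumor_iqr",
                                 "stroma_median", "stroma_iqr", "p", "q")
  res
}

.analysisMarkers <- function(profile) {
  rd <- rowData(profile)
  if ("markerClass" %in% colnames(rd)) {
    rownames(profile)[rd$markerClass == "experimental"]
  } else {
    rownames(profile)
  }
}

#' Two-group marker comparison within a compartment
#'
#' Per marker, a two-sample test on log2 scores between the levels of a
#' clinical grouping variable (ER status, HER2 status, or race without
#' adjustment), within one compartment. \code{method = "auto"} uses a
#' t-test unless more than 20\% of either group's values sit at the
#' imputation floor, in which case the Wilcoxon rank-sum test is used.
#' q-values are one Benjamini-Hochberg family per compartment.
#'
#' @param profile a [PatientProfile-class].
#' @param clinical clinical table with \code{patient_id} and the grouping
#'   column.
#' @param group_var one of \code{"er_status"}, \code{"her2_status"},
#'   \code{"race"}.
#' @param compartment \code{"tumor"} or \code{"stroma"}.
#' @param method \code{"auto"} (default), \code{"t"} or \code{"wilcoxon"}.
#' @param markers markers to test; default all experimental.
#' @param params a [qcParams()] supplying the floor constant for the tie
#'   rule.
#' @return a \code{data.frame}, one row per marker.
#' @export
compareGroups <- function(profile, clinical,
                          group_var = c("er_status", "her2_status", "race"),
                          compartment = c("tumor", "stroma"),
                          method = c("auto", "t", "wilcoxon"),
                          markers = NULL, params = qcParams()) {
  group_var <- match.arg(group_var)
  compartment <- match.arg(compartment)
  method <- match.arg(method)
  if (is.null(markers)) {
    markers <- .analysisMarkers(profile)
  }
  mat <- profileMatrix(profile, compartment)
  grp <- clinical[[group_var]][match(rownames(mat), clinical$patient_id)]
  lev <- if (group_var == "race") c("Black", "White") else c("POS", "NEG")
  keep <- !is.na(grp) & grp %in% lev
  mat <- mat[keep, , drop = FALSE]
  grp <- factor(grp[keep], levels = lev)
  if (any(table(grp) < 3L)) {
    stop(sprintf("group with <3 patients for %s in %s compartment",
                 group_var, compartment), call. = FALSE)
  }
  rows <- list()
  for (m in markers) {
    v <- mat[, m]
    g1 <- v[grp == lev[1]]
    g2 <- v[grp == lev[2]]
    at_floor <- function(g) {
      mean(abs(g - params$floor_value) < 1e-9, na.rm = TRUE)
    }
    use <- method
    if (method == "auto") {
      use <- if (max(at_floor(g1), at_floor(g2)) > .FLOOR_TIE_FRACTION) {
        "wilcoxon"
      } else {
        "t"
      }
    }
    if (use == "t") {
      if (stats::sd(c(log2(g1), log2(g2)), na.rm = TRUE) == 0) {
        stat <- 0
        p <- 1
      } else {
        tt <- tryCatch(stats::t.test(log2(g1), log2(g2)),
                       error = function(e) NULL)
        if (is.null(tt)) {
          ## essentially-constant groups: fall back to the rank test
          use <- "wilcoxon"
        } else {
          stat <- unname(tt$statistic)
          p <- tt$p.value
        }
      }
    }
    if (use == "wilcoxon") {
      wt <- suppressWarnings(stats::wilcox.test(log2(g1), log2(g2)))
      stat <- unname(wt$statistic)
      p <- wt$p.value
      if (is.nan(p)) {
        p <- 1
      }
    }
    rows[[length(rows) + 1L]] <-
      .resultRow(m, sprintf("%s_%s", group_var, compartment), g1, g2,
                 lev, use, stat, p)
  }
  res <- do.call(rbind, rows)
  res$q <- bhFdr(res$p)
  res$family <- sprintf("%s_%s", group_var, compartment)
  res$family_size <- nrow(res)
  res
}

#' Race ANCOVA adjusted for subtype, grade and BMI
#'
#' Per marker within a compartment, fits
#' \code{log2(score) ~ race + subtype + grade + bmi_category} on
#' listwise-complete cases with sum-to-zero contrasts and tests the race
#' main effect by a Type III F-test. With \code{covariates = character(0)}
#' this reduces to the unadjusted one-way ANOVA. Empty covariate levels are
#' dropped; q-values are one Benjamini-Hochberg family per compartment.
#'
#' @param profile a [PatientProfile-class].
#' @param clinical clinical table.
#' @param compartment \code{"tumor"} or \code{"stroma"}.
#' @param covariates adjustment columns, default
#'   \code{c("subtype", "grade", "bmi_category")}.
#' @param markers markers to test; default all experimental.
#' @return a \code{data.frame}, one row per marker: group medians/IQRs on
#'   the linear scale, F statistic, p, q.
#' @export
ancovaRace <- function(profile, clinical,
                       compartment = c("tumor", "stroma"),
                       covariates = c("subtype", "grade", "bmi_category"),
                       markers = NULL) {
  compartment <- match.arg(compartment)
  if (is.null(markers)) {
    markers <- .analysisMarkers(profile)
  }
  mat <- profileMatrix(profile, compartment)
  idx <- match(rownames(mat), clinical$patient_id)
  covars <- clinical[idx, c("race", covariates), drop = FALSE]
  complete <- stats::complete.cases(covars)
  mat <- mat[complete, , drop = FALSE]
  covars <- droplevels(as.data.frame(lapply(covars[complete, , drop = FALSE],
                                            factor)))
  if (nlevels(covars$race) < 2L) {
    stop("race must have two levels after listwise deletion", call. = FALSE)
  }
  contrasts_list <- lapply(covars, function(f) "contr.sum")
  rows <- list()
  for (m in markers) {
    df <- cbind(y = log2(mat[, m]), covars)
    form <- stats::reformulate(c("race", covariates), response = "y")
    fit <- stats::lm(form, data = df, contrasts = contrasts_list)
    if (any(is.na(stats::coef(fit)))) {
      stop(sprintf("rank-deficient design for marker '%s' (empty covariate cell)",
                   m), call. = FALSE)
    }
    a3 <- car::Anova(fit, type = 3)
    stat <- a3["race", "F value"]
    p <- a3["race", "Pr(>F)"]
    g1 <- mat[covars$race == "Black", m]
    g2 <- mat[covars$race == "White", m]
    rows[[length(rows) + 1L]] <-
      .resultRow(m, sprintf("race_ancova_%s", compartment), g1, g2,
                 c("Black", "White"),
                 if (length(covariates)) "ancova_typeIII_F" else "anova_F",
                 stat, p)
  }
  res <- do.call(rbind, rows)
  res$q <- bhFdr(res$p)
  res$family <- sprintf("race_ancova_%s", compartment)
  res$family_size <- nrow(res)
  res
}

#' Pearson correlation on log2 scores
#'
#' Used alike for platform-concordance analyses (spatial profiling vs
#' immunohistochemistry or gene expression) and for the continuous
#' ER-vs-immune-marker analysis. Values are log2-transformed; when a side
#' contains zeros (external platform scores), a +1 offset is applied to
#' that side only before the log. Negative values are an error.
#'
#' @param x,y paired numeric vectors (same patients, same order).
#' @param log_transform log2-transform before correlating (default TRUE).
#' @param labels length-2 character labels for the two sides.
#' @return a one-row \code{data.frame}: labels, n, Pearson R, p.
#' @export
correlateScores <- function(x, y, log_transform = TRUE,
                            labels = c("x", "y")) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  if (log_transform) {
    prep <- function(v) {
      if (any(v < 0)) {
        stop("negative values cannot be log-transformed", call. = FALSE)
      }
      if (any(v == 0)) {
        v <- v + 1
      }
      log2(v)
    }
    x <- prep(x)
    y <- prep(y)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(x = labels[1], y = labels[2], n = length(x),
             r = unname(ct$estimate), p = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Continuous ER-vs-marker correlation screen
#'
#' Correlates the tumor-compartment ER score with every other marker in
#' both compartments (log2, Pearson), the continuous analogue of the
#' ER-status group comparison.
#'
#' @param profile a [PatientProfile-class].
#' @param er_marker marker id carrying the ER signal, default \code{"ER"}.
#' @param markers markers to screen; default all experimental except the ER
#'   marker.
#' @return a \code{data.frame}: marker, compartment, n, r, p.
#' @export
erCorrelationScreen <- function(profile, er_marker = "ER",
                                markers = NULL) {
  if (is.null(markers)) {
    markers <- setdiff(.analysisMarkers(profile), er_marker)
  }
  er <- profileMatrix(profile, "tumor")[, er_marker]
  rows <- list()
  for (compartment in c("tumor", "stroma")) {
    mat <- profileMatrix(profile, compartment)
    shared <- intersect(names(er), rownames(mat))
    for (m in markers) {
      r <- correlateScores(er[shared], mat[shared, m],
                           labels = c(paste0(er_marker, "_tumor"),
                                      paste(m, compartment, sep = "_")))
      rows[[length(rows) + 1L]] <-
        data.frame(marker = m, compartment = compartment, n = r$n,
                   r = r$r, p = r$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' One-way ANOVA of scores against a categorical platform score
#'
#' Tests whether mean log2 scores are equal across the categories (e.g.
#' immunohistochemistry score levels 0/1/2/3) and returns the per-category
#' summaries used for boxplots.
#'
#' @param scores positive numeric scores.
#' @param categories factor (or coercible) of the same length.
#' @return a list with \code{F}, \code{p} and \code{groups} (per-category
#'   n, median, IQR on the linear scale).
#' @export
anovaVsCategorical <- function(scores, categories) {
  ok <- stats::complete.cases(scores, categories)
  scores <- scores[ok]
  categories <- droplevels(factor(categories[ok]))
  if (nlevels(categories) < 2L) {
    stop("need at least two non-empty categories", call. = FALSE)
  }
  fit <- stats::lm(log2(scores) ~ categories)
  a <- stats::anova(fit)
  groups <- do.call(rbind, lapply(levels(categories), function(l) {
    v <- scores[categories == l]
    data.frame(category = l, n = length(v),
               median = stats::median(v), iqr = .iqr(v),
               stringsAsFactors = FALSE)
  }))
  F_val <- a[1, "F value"]
  p <- a[1, "Pr(>F)"]
  ## all group means identical: anova returns F = 0 with p = 1 only when
  ## residual variance is positive; guard the fully degenerate case
  if (is.nan(F_val)) {
    F_val <- 0
    p <- 1
  }
  list(F = F_val, p = p, groups = groups)
}
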