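## Median-dichotomized marker groups, Kaplan-Meier estimation and log-rank
## tests for overall and breast-cancer-specific survival. Estimation is
## delegated to the survival package; this layer owns the dichotomization
## rule, endpoint construction and the marker x compartment screen.

#' Dichotomize scores at the median
#'
#' Values at or above the median go to \code{"high"}, the rest to
#' \code{"low"}; the median is computed over the supplied (analyzed)
#' values. When the median coincides with the minimum (scores saturated at
#' the detection floor) the at-or-above rule would leave the low group
#' empty, so the strictly-above rule is used instead and the floor mass
#' forms the low group. All-identical input is an error: no split exists.
#'
#' @param scores numeric vector.
#' @return factor with levels \code{low}, \code{high}, same length/names.
#' @export
dichotomizeAtMedian <- function(scores) {
  v <- scores[!is.na(scores)]
  if (length(unique(v)) < 2L) {
    stop("all values identical: no median split possible", call. = FALSE)
  }
  med <- stats::median(scores, na.rm = TRUE)
  hi <- scores >= med
  if (all(hi, na.rm = TRUE)) {
    ## floor-saturated scores: the median equals the minimum and the >=
    ## rule would leave the low group empty; the strict rule puts the
    ## floor mass low and everything above it high
    hi <- scores > med
  }
  out <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
  names(out) <- names(scores)
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimates per group and the log-rank chi-square and
#' p-value. With zero events overall the test is undefined and reported as
#' \code{NA}.
#'
#' @param time follow-up time (years).
#' @param event 0/1 or logical event indicator.
#' @param groups two-level factor.
#' @return a list of class \code{KmResult}: group sizes, per-group step
#'   functions (\code{time}, \code{n.risk}, \code{n.event},
#'   \code{survival}), \code{chisq}, \code{p}, \code{n_events}.
#' @export
kmLogrank <- function(time, event, groups) {
  event <- as.integer(event)
  groups <- droplevels(factor(groups))
  ok <- stats::complete.cases(time, event, groups)
  time <- time[ok]
  event <- event[ok]
  groups <- droplevels(groups[ok])
  if (nlevels(groups) != 2L) {
    stop("exactly two non-empty groups are required", call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata_lab <- sub("^groups=", "", rep(names(sf$strata), sf$strata))
  steps <- data.frame(group = strata_lab, time = sf$time,
                      n_risk = sf$n.risk, n_event = sf$n.event,
                      survival = sf$surv, stringsAsFactors = FALSE)
  n_events <- sum(event)
  if (n_events == 0L) {
    chisq <- NA_real_
    p <- NA_real_
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
    chisq <- sd_$chisq
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(group_sizes = table(groups), steps = steps,
                 chisq = chisq, p = p, n = length(time),
                 n_events = n_events),
            class = "KmResult")
}

#' Build survival inputs from a clinical table
#'
#' @param clinical clinical table with \code{followup_years},
#'   \code{vital_status} and (for the breast-cancer-specific endpoint)
#'   \code{breast_cancer_death}.
#' @param endpoint \code{"os"} (death from any cause) or \code{"bcss"}
#'   (death from breast cancer; other deaths censored).
#' @return \code{data.frame} with \code{patient_id}, \code{time},
#'   \code{event}, restricted to patients with follow-up available.
#' @export
survivalInputs <- function(clinical, endpoint = c("os", "bcss")) {
  endpoint <- match.arg(endpoint)
  has_fu <- !is.na(clinical$followup_years) & !is.na(clinical$vital_status)
  d <- clinical[has_fu, , drop = FALSE]
  event <- if (endpoint == "os") {
    d$vital_status == "dead"
  } else {
    !is.na(d$breast_cancer_death) & d$breast_cancer_death
  }
  data.frame(patient_id = d$patient_id, time = d$followup_years,
             event = as.integer(event), stringsAsFactors = FALSE)
}

#' Exploratory univariate survival screen
#'
#' For every marker in both compartments, dichotomizes the scores of the
#' follow-up-available patients at the median and runs the two-group
#' log-rank test. Unadjusted p-values are reported deliberately: the screen
#' is exploratory and applies no multiplicity correction.
#'
#' @param profile a [PatientProfile-class].
#' @param clinical clinical table with follow-up fields.
#' @param endpoint \code{"os"} or \code{"bcss"}.
#' @param markers markers to screen; default all experimental.
#' @return a \code{data.frame}: marker, compartment, endpoint, n, group
#'   sizes, events, chi-square, p (NA when no events), plus a list-column
#'   \code{km} of \code{KmResult} step tables.
#' @export
runSurvivalScreen <- function(profile, clinical,
                              endpoint = c("os", "bcss"),
                              markers = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(markers)) {
    markers <- .analysisMarkers(profile)
  }
  inputs <- survivalInputs(clinical, endpoint)
  rows <- list()
  km_list <- list()
  for (compartment in c("tumor", "stroma")) {
    mat <- profileMatrix(profile, compartment)
    shared <- intersect(inputs$patient_id, rownames(mat))
    d <- inputs[match(shared, inputs$patient_id), ]
    for (m in markers) {
      v <- mat[shared, m]
      res <- tryCatch({
        grp <- dichotomizeAtMedian(v)
        kmLogrank(d$time, d$event, grp)
      }, error = function(e) NULL)
      if (is.null(res)) {
        row <- data.frame(marker = m, compartment = compartment,
                          endpoint = endpoint, n = length(shared),
                          n_low = NA_integer_, n_high = NA_integer_,
                          events = sum(d$event), chisq = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE)
      } else {
        row <- data.frame(marker = m, compartment = compartment,
                          endpoint = endpoint, n = res$n,
                          n_low = unname(res$group_sizes["low"]),
                          n_high = unname(res$group_sizes["high"]),
                          events = res$n_events, chisq = res$chisq,
                          p = res$p, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
      km_list[[paste(m, compartment, sep = ".")]] <- res
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "km") <- km_list
  out
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Median of the censoring distribution (events treated as censorings and
#' vice versa), the standard summary of follow-up duration.
#'
#' @param time follow-up time.
#' @param event event indicator.
#' @return median follow-up in the time unit of the input.
#' @export
medianFollowup <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - as.integer(event)) ~ 1)
  unname(summary(sf)$table["median"])
}
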