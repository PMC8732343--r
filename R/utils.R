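## Small internal helpers shared across modules.

#' Geometric mean
#'
#' @param x numeric vector of strictly positive values.
#' @return the geometric mean of \code{x}.
#' @keywords internal
#' @noRd
.geomean <- function(x) {
  exp(mean(log(x)))
}

## Row-wise geometric means of a (features x samples) slice, columns = samples.
.colGeomeans <- function(m) {
  exp(colMeans(log(m)))
}

## IQR as printed in results tables: type-7 quantiles, same as stats::IQR default.
.iqr <- function(x) {
  stats::IQR(x, na.rm = TRUE)
}

## Sniff the field separator of a delimited text file from its header line.
.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    return("\t")
  }
  ntab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  ncom <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (ncom > ntab) "," else "\t"
}

.readDelim <- function(path) {
  sep <- .sniffSep(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    encoding = "UTF-8")
}

.writeDelim <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

## Normalize a categorical column against a canonical-level synonym map.
## `map` is a named list: canonical label -> character vector of accepted
## spellings (matched case-insensitively, exact otherwise). Unmapped non-missing
## values raise an error naming the offending value.
.normalizeLevels <- function(x, map, field = "field", allow_missing = TRUE) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  lowered <- tolower(x)
  for (canonical in names(map)) {
    hits <- lowered %in% tolower(map[[canonical]])
    out[hits] <- canonical
  }
  missing <- is.na(x) | x == "" | lowered %in% c("na", "nan", ".")
  out[missing] <- NA_character_
  bad <- !missing & is.na(out)
  if (any(bad)) {
    stop(sprintf("unrecognized value(s) for %s: %s", field,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  if (!allow_missing && anyNA(out)) {
    stop(sprintf("missing values not allowed for %s", field), call. = FALSE)
  }
  out
}

## Adjusted Rand index between two label vectors (used by clustering checks).
.adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum(choose(tab, 2))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) {
    return(1)
  }
  (sij - expected) / (maxidx - expected)
}
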