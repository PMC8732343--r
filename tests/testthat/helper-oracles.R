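# Independent brute-force oracles. These reimplement, as directly as
# possible, the statistic each pipeline operation computes, and are kept
# deliberately naive (loops, textbook formulas) so they share no code with
# the implementation under test.

# Per-cell signal-to-noise against the geometric mean of the negative
# controls in the same ROI: counts is markers x ROIs.
oracleSnr <- function(counts, experimental, negcontrols) {
  out <- matrix(NA_real_, length(experimental), ncol(counts),
                dimnames = list(experimental, colnames(counts)))
  for (m in experimental) {
    for (r in seq_len(ncol(counts))) {
      nc <- counts[negcontrols, r]
      out[m, r] <- counts[m, r] / prod(nc)^(1 / length(nc))
    }
  }
  out
}

# Group means by (patient, compartment), looped cell by cell.
oracleAggregate <- function(values, patient, compartment) {
  keys <- unique(paste(patient, compartment, sep = "."))
  out <- matrix(NA_real_, nrow(values), length(keys),
                dimnames = list(rownames(values), keys))
  for (k in keys) {
    idx <- which(paste(patient, compartment, sep = ".") == k)
    for (m in seq_len(nrow(values))) {
      out[m, k] <- mean(values[m, idx])
    }
  }
  out
}

# Benjamini-Hochberg step-up, from the definition.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  sorted <- p[o]
  for (i in seq_len(n)) {
    q[i] <- min(sorted[i:n] * n / (i:n))
  }
  pmin(1, q)[order(o)]
}

# Kaplan-Meier product-limit estimates at the event times.
oracleKM <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t_i <- ev_times[i]
    n_risk <- sum(time >= t_i)
    d_i <- sum(time == t_i & event == 1)
    s <- s * (1 - d_i / n_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, survival = surv)
}

# Two-group log-rank chi-square by observed-minus-expected tabulation.
oracleLogrank <- function(time, event, group) {
  group <- factor(group)
  lev <- levels(group)
  ev_times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t_i in ev_times) {
    at_risk <- time >= t_i
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d <- sum(time == t_i & event == 1)
    d1 <- sum(time == t_i & event == 1 & group == lev[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Naive agglomerative clustering with the Ward (ward.D2) update, returning
# the sequence of merge heights.
oracleWardHeights <- function(mat) {
  d <- as.matrix(dist(mat))
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestd)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dnew <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                      nk * d[i, j]^2) / (ni + nj + nk))
      d[i, k] <- dnew; d[k, i] <- dnew
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Pearson correlation from the textbook covariance formula.
oraclePearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
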