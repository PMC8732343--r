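test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhFdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhFdr(p), oracleBH(p), tolerance = 1e-12)
  }
  # missing p-values propagate and are excluded from the ranking
  q <- bhFdr(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracleBH(c(0.01, 0.04)))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("paired compartment comparison behaves on constructed input", {
  pats <- paste0("P", 1:10)
  tum <- matrix(c(2^(1:10), rep(8, 10)), 10,
                dimnames = list(pats, c("up", "flat")))
  str <- tum
  str[, "up"] <- tum[, "up"] * 4
  prof <- profileFromMatrices(tum, str)
  res <- compareCompartments(prof, markers = c("up", "flat"))
  # identical values: statistic 0, p = 1
  flat <- res[res$marker == "flat", ]
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # a constant 2-log2 shift with no noise is exactly significant
  up <- res[res$marker == "up", ]
  expect_lt(up$p, 1e-6)
  # medians are reported on the linear scale
  expect_equal(up$tumor_median, median(tum[, "up"]))
  expect_equal(up$stroma_median, 4 * median(tum[, "up"]))
  # q-values form a single family over the tested markers
  expect_equal(res$q, bhFdr(res$p))
  expect_true(all(res$family_size == 2))
})

test_that("compartment comparison detects embedded shifts at nominal FDR", {
  # 5 markers with a true 2.0 log2 stromal shift, 25 null markers
  set.seed(99)
  n <- 150
  pats <- paste0("P", seq_len(n))
  mk <- paste0("m", 1:30)
  base <- matrix(2^rnorm(n * 30, 4, 0.8), n, 30,
                 dimnames = list(pats, mk))
  str <- base * 2^matrix(rnorm(n * 30, 0, 0.3), n, 30)
  str[, 1:5] <- str[, 1:5] * 4
  prof <- profileFromMatrices(base, str)
  res <- compareCompartments(prof, markers = mk)
  expect_true(all(res$q[res$marker %in% paste0("m", 1:5)] < 0.05))
  null_flagged <- mean(res$q[res$marker %in% paste0("m", 6:30)] < 0.05)
  expect_lte(null_flagged, 0.1)
})

test_that("markers with too few complete pairs are skipped with warning", {
  tum <- matrix(runif(8, 1, 9), 4, 2,
                dimnames = list(paste0("P", 1:4), c("a", "b")))
  str <- matrix(runif(8, 1, 9), 4, 2,
                dimnames = list(paste0("P", 1:4), c("a", "b")))
  str[1:2, "b"] <- NA
  prof <- profileFromMatrices(tum, str)
  expect_warning(res <- compareCompartments(prof, markers = c("a", "b")),
                 "b")
  expect_equal(res$marker, "a")
})

test_that("two-group comparisons test log2 scores within a compartment", {
  set.seed(5)
  n <- 60
  pats <- paste0("P", seq_len(n))
  clin <- data.frame(patient_id = pats,
                     er_status = rep(c("POS", "NEG"), each = n / 2),
                     race = rep(c("Black", "White"), n / 2))
  tum <- matrix(2^rnorm(n * 2, 4, 0.5), n, 2,
                dimnames = list(pats, c("shift", "null")))
  tum[clin$er_status == "NEG", "shift"] <-
    tum[clin$er_status == "NEG", "shift"] * 2^1.5
  prof <- profileFromMatrices(tum)
  res <- compareGroups(prof, clin, "er_status", "tumor", method = "t",
                       markers = c("shift", "null"))
  expect_lt(res$p[res$marker == "shift"], 1e-4)
  expect_gt(res$p[res$marker == "null"], 0.001)
  # the t-statistic matches a direct computation
  tt <- t.test(log2(tum[clin$er_status == "POS", "shift"]),
               log2(tum[clin$er_status == "NEG", "shift"]))
  expect_equal(res$statistic[res$marker == "shift"],
               unname(tt$statistic), tolerance = 1e-12)
  # a group below the minimum size is fatal
  clin_small <- clin
  clin_small$er_status[clin_small$er_status == "NEG"] <- NA
  clin_small$er_status[1:2] <- "NEG"
  expect_error(compareGroups(prof, clin_small, "er_status", "tumor"),
               "<3 patients")
})

test_that("the auto rule switches to Wilcoxon under floor tie mass", {
  qp <- qcParams()
  n <- 40
  pats <- paste0("P", seq_len(n))
  clin <- data.frame(patient_id = pats,
                     er_status = rep(c("POS", "NEG"), each = n / 2))
  tum <- matrix(2^rnorm(n, 4, 0.4), n, 1, dimnames = list(pats, "m"))
  # 40% of one group at the floor
  tum[1:8, "m"] <- qp$floor_value
  prof <- profileFromMatrices(tum)
  res <- compareGroups(prof, clin, "er_status", "tumor", method = "auto",
                       markers = "m")
  expect_equal(res$test, "wilcoxon")
  # full tie saturation: both groups at the floor -> p = 1
  tumF <- matrix(qp$floor_value, n, 1, dimnames = list(pats, "m"))
  resF <- compareGroups(profileFromMatrices(tumF), clin, "er_status",
                        "tumor", method = "wilcoxon", markers = "m")
  expect_equal(resF$p, 1)
})

test_that("race ANCOVA reduces to ANOVA and flags the embedded shift", {
  # balanced two-group design with no covariates: F equals t^2
  set.seed(8)
  n <- 40
  pats <- paste0("P", seq_len(n))
  clin <- data.frame(patient_id = pats,
                     race = rep(c("Black", "White"), each = n / 2),
                     subtype = "LuminalA", grade = "LOW",
                     bmi_category = "<25")
  tum <- matrix(2^rnorm(n, 4, 0.5), n, 1, dimnames = list(pats, "m"))
  prof <- profileFromMatrices(tum)
  res0 <- ancovaRace(prof, clin, "tumor", covariates = character(0),
                     markers = "m")
  tt <- t.test(log2(tum[clin$race == "Black", "m"]),
               log2(tum[clin$race == "White", "m"]), var.equal = TRUE)
  expect_equal(res0$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res0$p, tt$p.value, tolerance = 1e-9)

  # embedded race shift on the B7-H3 analogue is recovered with adjustment
  sim <- simulateProfiles(dspSimConfig(seed = 101))
  res <- ancovaRace(sim$profile, sim$clinical, "tumor")
  expect_lt(res$q[res$marker == "B7-H3"], 0.05)
  # Black medians are lower on the linear scale
  b7 <- res[res$marker == "B7-H3", ]
  expect_lt(b7$group1_median, b7$group2_median)
})

test_that("ANCOVA race F-test agrees with a model-comparison oracle", {
  sim <- simulateProfiles(dspSimConfig(n_patients = 120, seed = 55))
  clin <- sim$clinical
  tum <- profileMatrix(sim$profile, "tumor")
  m <- "B7-H3"
  df <- data.frame(y = log2(tum[, m]),
                   race = factor(clin$race), subtype = factor(clin$subtype),
                   grade = factor(clin$grade),
                   bmi = factor(clin$bmi_category))
  full <- lm(y ~ race + subtype + grade + bmi, data = df)
  red <- lm(y ~ subtype + grade + bmi, data = df)
  F_oracle <- anova(red, full)[2, "F"]
  res <- ancovaRace(sim$profile, clin, "tumor", markers = m)
  expect_equal(res$statistic, F_oracle, tolerance = 1e-9)
})

test_that("Pearson correlation matches the closed form and handles zeros", {
  x <- c(3, 7, 2, 9, 4, 8, 1, 6, 5, 10)
  y <- 2 * x
  r <- correlateScores(x, y)
  expect_equal(r$r, 1, tolerance = 1e-12)
  set.seed(3)
  a <- runif(10, 1, 50)
  b <- runif(10, 1, 50)
  r2 <- correlateScores(a, b, log_transform = FALSE)
  expect_equal(r2$r, oraclePearson(a, b), tolerance = 1e-12)
  expect_error(correlateScores(a[1:2], b[1:2]), "3")
  # zeros on one side get the +1 offset applied to that side only
  bz <- c(0, b[-1])
  r3 <- correlateScores(a, bz)
  want <- oraclePearson(log2(a), log2(bz + 1))
  expect_equal(r3$r, want, tolerance = 1e-12)
})

test_that("ER-immune anticorrelation is embedded with consistent sign", {
  sim <- simulateProfiles(dspSimConfig(n_patients = 400, seed = 77))
  scr <- erCorrelationScreen(sim$profile)
  coupled <- sim$truth$markers$marker_id[sim$truth$markers$er_coef < 0]
  got <- scr[scr$marker %in% coupled, ]
  expect_true(all(got$r < 0))
  # and the positively coupled markers come out positive in the tumor
  pos <- sim$truth$markers$marker_id[sim$truth$markers$er_coef > 0.05]
  expect_true(all(scr$r[scr$marker %in% pos &
                          scr$compartment == "tumor"] > 0))
})

test_that("categorical ANOVA matches its oracle and the t^2 identity", {
  # constructed equal means: F = 0, p = 1
  sc <- rep(c(2, 4, 8), times = 3)
  cat3 <- rep(c("0", "1", "2"), each = 3)
  res <- anovaVsCategorical(sc, cat3)
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # two categories: F equals the pooled-variance t squared
  set.seed(11)
  sc2 <- 2^rnorm(30, 3, 0.6)
  cat2 <- rep(c("lo", "hi"), 15)
  res2 <- anovaVsCategorical(sc2, cat2)
  tt <- t.test(log2(sc2[cat2 == "lo"]), log2(sc2[cat2 == "hi"]),
               var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  # three-group instance against brute-force sums of squares
  set.seed(12)
  sc3 <- 2^rnorm(18, 3, 0.5)
  cat3b <- rep(c("0", "1", "3"), each = 6)
  y <- log2(sc3)
  grand <- mean(y)
  ssb <- sum(tapply(y, cat3b, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(y, cat3b, function(v) (v - mean(v))^2)))
  F_oracle <- (ssb / 2) / (ssw / 15)
  res3 <- anovaVsCategorical(sc3, cat3b)
  expect_equal(res3$F, F_oracle, tolerance = 1e-10)
  expect_equal(res3$groups$n, rep(6L, 3))
  expect_error(anovaVsCategorical(sc3, rep("0", 18)), "two")
})
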