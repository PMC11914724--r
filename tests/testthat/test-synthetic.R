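test_that("zero-amplitude template with no noise yields identically zero leads", {
  tpl <- waveTemplate(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  ecg <- generateEcg(tpl, heartRate = 60, fs = 500, duration = 4,
                     noiseSd = 0, seed = 1)
  expect_true(all(sampleMatrix(ecg) == 0))
})

test_that("signal length equals round(fs * duration) for every lead", {
  ecg <- generateEcg(fs = 500, duration = 10, seed = 2)
  expect_identical(dim(sampleMatrix(ecg)), c(5000L, 12L))
  expect_equal(signalDuration(ecg), 10)
  ecg2 <- generateEcg(fs = 321, duration = 7.3, seed = 2)
  expect_identical(nrow(sampleMatrix(ecg2)), as.integer(round(321 * 7.3)))
})

test_that("R peaks recur at 60/heartRate seconds", {
  for (hr in c(60, 90)) {
    ecg <- generateEcg(heartRate = hr, fs = 500, duration = 10,
                       noiseSd = 0, seed = 3)
    x <- sampleMatrix(ecg)[, "II"]
    # independent peak detection: local maxima above half the global max
    thr <- max(x) / 2
    peaks <- which(x > thr &
                   x >= c(-Inf, head(x, -1)) & x > c(tail(x, -1), Inf))
    gaps <- diff(peaks) / 500
    expect_equal(mean(gaps), 60 / hr, tolerance = 1e-3)
  }
})

test_that("invalid generation parameters error", {
  expect_error(generateEcg(duration = 0), "duration")
  expect_error(generateEcg(fs = 50), "fs")
  expect_error(generateEcg(heartRate = 10), "heartRate")
})

test_that("augmented leads follow the Einthoven/Goldberger relations", {
  expect_equal(deriveAugmentedLeads(0, 0),
               list(III = 0, aVR = 0, aVL = 0, aVF = 0))
  out <- deriveAugmentedLeads(0.5, 1.0)
  expect_equal(out$III, 0.5)
  expect_equal(out$aVR, -0.75)
  expect_equal(out$aVL, 0.0)
  expect_equal(out$aVF, 0.75)
  expect_error(deriveAugmentedLeads(1:3, 1:4), "length")
})

test_that("generated 12-lead signals satisfy the lead identities exactly", {
  set.seed(9)
  for (k in 1:3) {
    ecg <- generateEcg(heartRate = runif(1, 45, 120), seed = k, noiseSd = 0.05)
    m <- sampleMatrix(ecg)
    expect_equal(m[, "III"], m[, "II"] - m[, "I"])
    expect_equal(m[, "aVR"], -(m[, "I"] + m[, "II"]) / 2)
    expect_equal(m[, "aVL"], m[, "I"] - m[, "II"] / 2)
    expect_equal(m[, "aVF"], m[, "II"] - m[, "I"] / 2)
    expect_equal(max(abs(m[, "I"] - m[, "II"] + m[, "III"])), 0)
  }
})

test_that("cohort event fraction matches the closed-form geometric survival", {
  # flat hazard 0.1 over K = 5 intervals, no censoring:
  # P(event) = 1 - 0.9^5 = 0.40951
  g <- intervalGrid(seq(0, 500, by = 100))
  cc <- cohortConfig(nSubjects = 4000L, seed = 77L, baselineHazard = 0.1,
                     coefHr = 0, coefQrs = 0, censProb = 0,
                     fs = 100, duration = 0.2)     # minimal signals: speed
  coh <- generateCohort(cc, g)
  p <- 1 - 0.9^5
  mcSe <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(mean(coh$records$event) - p), 3 * mcSe)
})

test_that("empirical per-interval hazard matches the configured hazard", {
  g <- intervalGrid(seq(0, 500, by = 100))
  cc <- cohortConfig(nSubjects = 4000L, seed = 78L, baselineHazard = 0.1,
                     coefHr = 0, coefQrs = 0, censProb = 0,
                     fs = 100, duration = 0.2)
  coh <- generateCohort(cc, g)
  b <- intervalBoundaries(g)
  atRisk <- 4000
  for (j in 1:3) {
    died <- sum(coh$records$event == 1 & coh$records$time > b[j] &
                coh$records$time <= b[j + 1])
    hj <- died / atRisk
    expect_lt(abs(hj - 0.1), 3 * sqrt(0.1 * 0.9 / atRisk))
    atRisk <- atRisk - died
  }
})

test_that("certain early censoring leaves no events", {
  g <- intervalGrid(seq(0, 500, by = 100))
  cc <- cohortConfig(nSubjects = 50L, seed = 5L, censProb = 1, censMax = 1e-3,
                     fs = 100, duration = 0.2)
  coh <- generateCohort(cc, g)
  expect_true(all(coh$records$event == 0))
  expect_true(all(coh$records$time < 1e-3))
})

test_that("identical config and seed give identical cohorts", {
  g <- intervalGrid()
  cc <- cohortConfig(nSubjects = 5L, seed = 123L, fs = 200, duration = 10)
  a <- generateCohort(cc, g)
  b <- generateCohort(cc, g)
  expect_identical(a$records, b$records)
  expect_identical(lapply(a$signals, sampleMatrix),
                   lapply(b$signals, sampleMatrix))
})

test_that("signal CSV round trip preserves samples and rate", {
  ecg <- generateEcg(fs = 250, duration = 2, seed = 4)
  p <- tempfile(fileext = ".csv")
  writeEcgCsv(ecg, p)
  back <- readEcgCsv(p)
  expect_equal(samplingRate(back), 250)
  expect_equal(sampleMatrix(back), sampleMatrix(ecg), tolerance = 1e-12)
})
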