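## Synthetic 12-lead ECG generation with linked survival outcomes.
##
## Beats are sums of five Gaussian deflections (P, Q, R, S, T) repeated at
## the RR interval and projected per lead; only the 8 independent leads are
## simulated, the 4 augmented limb leads are always derived from I and II.

#' Construct a per-beat wave template
#'
#' Defaults give a generic adult morphology: upright P and T, dominant R
#' with small Q and S, and an rS pattern in V1. Amplitudes are in mV,
#' centres are offsets from the R peak in seconds, widths are Gaussian
#' sigmas in seconds.
#'
#' @param amplitude,center,width named numeric vectors (P, Q, R, S, T).
#' @param qrsWidth convenience scalar: scales the Q, R, S widths jointly
#'   relative to the default R sigma of 0.012 s; ignored if `width` given.
#' @param projection 5 x 12 waves-by-leads weight matrix; defaults to
#'   per-lead scalar weights with a V1-specific rS override.
#' @return a [WaveTemplate-class].
#' @examples
#' tpl <- waveTemplate(qrsWidth = 0.016)
#' @export
waveTemplate <- function(amplitude = c(P = 0.15, Q = -0.10, R = 1.20, S = -0.25, T = 0.35),
                         center = c(P = -0.170, Q = -0.030, R = 0, S = 0.035, T = 0.300),
                         width = NULL, qrsWidth = 0.012, projection = NULL) {
  wv <- c("P", "Q", "R", "S", "T")
  if (is.null(width)) {
    sc <- qrsWidth / 0.012
    width <- c(P = 0.025, Q = 0.008 * sc, R = 0.012 * sc, S = 0.010 * sc, T = 0.060)
  }
  if (is.null(projection)) {
    wts <- c(I = 0.70, II = 1.00, III = 0.30, aVR = -0.85, aVL = 0.20, aVF = 0.65,
             V1 = 0.60, V2 = 0.85, V3 = 0.95, V4 = 1.00, V5 = 0.90, V6 = 0.80)
    projection <- matrix(rep(wts, each = 5L), nrow = 5L,
                         dimnames = list(wv, .LEADS))
    ## V1 classically shows a small r and deep S
    projection["R", "V1"] <- 0.25
    projection["S", "V1"] <- 1.80
  }
  new("WaveTemplate",
      amplitude = amplitude[wv], center = center[wv], width = width[wv],
      projection = projection)
}

#' Derive the four augmented limb leads from leads I and II
#'
#' The augmented leads are fixed linear combinations (Einthoven and
#' Goldberger relations): III = II - I, aVR = -(I + II)/2,
#' aVL = I - II/2, aVF = II - I/2.
#'
#' @param leadI,leadII numeric vectors of equal length, mV.
#' @return list with numeric components `III`, `aVR`, `aVL`, `aVF`.
#' @examples
#' deriveAugmentedLeads(0.5, 1.0)
#' @export
deriveAugmentedLeads <- function(leadI, leadII) {
  .assert(length(leadI) == length(leadII),
          "lead I and II lengths differ (%d vs %d)", length(leadI), length(leadII))
  list(III = leadII - leadI,
       aVR = -(leadI + leadII) / 2,
       aVL = leadI - leadII / 2,
       aVF = leadII - leadI / 2)
}

## Sum-of-Gaussians beat train on the independent leads.
.beatTrain <- function(template, t, heartRate) {
  rr <- 60 / heartRate
  ## beat centres covering the whole record with margin for wave tails
  centers <- seq(rr / 2, max(t) + rr, by = rr)
  G <- matrix(0, length(t), 5L)
  for (w in seq_len(5L)) {
    mu <- template@center[w]
    sg <- template@width[w]
    for (cb in centers) {
      d <- t - cb - mu
      keep <- abs(d) < 6 * sg
      if (any(keep)) G[keep, w] <- G[keep, w] + exp(-d[keep]^2 / (2 * sg^2))
    }
  }
  G
}

#' Generate a synthetic 12-lead ECG
#'
#' Builds a train of Gaussian-shaped P-QRS-T complexes repeated at the RR
#' interval 60/heartRate on the 8 independent leads, adds white Gaussian
#' noise, and derives the 4 augmented limb leads from the (noisy) leads I
#' and II so the linear lead identities hold exactly. Deterministic given
#' `seed`.
#'
#' @param template a [WaveTemplate-class].
#' @param heartRate beats per minute, in (20, 300).
#' @param fs sampling frequency, Hz (>= 100).
#' @param duration record length, s (> 0).
#' @param noiseSd additive noise standard deviation, mV.
#' @param seed integer seed.
#' @return an [ECGSignal-class] with 12 leads.
#' @examples
#' ecg <- generateEcg(waveTemplate(), heartRate = 72, fs = 500,
#'                    duration = 10, noiseSd = 0.01, seed = 1)
#' @export
generateEcg <- function(template = waveTemplate(), heartRate = 72, fs = 500,
                        duration = 10, noiseSd = 0.01, seed = 1) {
  .assert(fs >= 100, "fs must be >= 100 Hz, got %g", fs)
  .assert(duration > 0, "duration must be > 0, got %g", duration)
  .assert(heartRate > 20 && heartRate < 300,
          "heartRate must be in (20, 300) bpm, got %g", heartRate)
  .assert(noiseSd >= 0, "noiseSd must be >= 0")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  G <- .beatTrain(template, t, heartRate)
  coefs <- template@projection[, .INDEP_LEADS, drop = FALSE] * template@amplitude
  s8 <- G %*% coefs                       # n x 8, mV
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    s8 <- s8 + matrix(rnorm(length(s8), sd = noiseSd), nrow = n)
  }
  aug <- deriveAugmentedLeads(s8[, "I"], s8[, "II"])
  samples <- cbind(s8[, c("I", "II"), drop = FALSE],
                   III = aug$III, aVR = aug$aVR, aVL = aug$aVL, aVF = aug$aVF,
                   s8[, c("V1", "V2", "V3", "V4", "V5", "V6"), drop = FALSE])
  samples <- samples[, .LEADS, drop = FALSE]
  new("ECGSignal", samples = samples, fs = fs)
}

#' Configuration for a synthetic survival cohort
#'
#' Per-subject heart rate and QRS width are drawn uniformly from the given
#' ranges; a constant per-interval conditional hazard is a logistic
#' function of both, standardized to their ranges, which keeps hazards in
#' (0, 1) by construction. Censoring is independent: with probability
#' `censProb` a censoring time is drawn uniformly on (0, censMax].
#'
#' @param nSubjects number of subjects (>= 1).
#' @param seed integer master seed.
#' @param hrRange heart-rate range, bpm.
#' @param qrsWidthRange QRS Gaussian-sigma range, s.
#' @param baselineHazard per-interval hazard for an average subject, in (0, 1).
#' @param coefHr,coefQrs log-odds hazard coefficients per 1 SD of heart
#'   rate and QRS width.
#' @param censProb probability a subject has a finite censoring time.
#' @param censMax upper bound of the uniform censoring time, days;
#'   defaults to the grid horizon at generation time.
#' @param fs,duration,noiseSd signal-generation settings.
#' @return a list of class `cohortConfig`.
#' @export
cohortConfig <- function(nSubjects = 100L, seed = 1L,
                         hrRange = c(50, 110), qrsWidthRange = c(0.008, 0.020),
                         baselineHazard = 0.06, coefHr = 1.2, coefQrs = 0.5,
                         censProb = 0.25, censMax = NULL,
                         fs = 400, duration = 10, noiseSd = 0.02) {
  .assert(nSubjects >= 1, "nSubjects must be >= 1")
  .assert(baselineHazard > 0 && baselineHazard < 1,
          "baselineHazard must be in (0, 1), got %g", baselineHazard)
  structure(list(nSubjects = as.integer(nSubjects), seed = as.integer(seed),
                 hrRange = hrRange, qrsWidthRange = qrsWidthRange,
                 baselineHazard = baselineHazard, coefHr = coefHr,
                 coefQrs = coefQrs, censProb = censProb, censMax = censMax,
                 fs = fs, duration = duration, noiseSd = noiseSd),
            class = "cohortConfig")
}

## standardize a uniform draw to mean 0, sd 1 given its range
.stdUnif <- function(x, rng) (x - mean(rng)) / (diff(rng) / sqrt(12))

#' Generate a synthetic cohort of ECGs with survival outcomes
#'
#' Each subject receives a signal with randomized heart rate and QRS
#' width and an event time drawn from the discrete-time hazard implied by
#' the configured coefficients, with independent uniform censoring.
#' Subjects surviving the whole grid are censored at the horizon.
#' Byte-identical output for identical (config, grid).
#'
#' @param config a [cohortConfig()].
#' @param grid an [IntervalGrid-class].
#' @return list with `signals` (list of [ECGSignal-class]) and `records`
#'   (data.frame: subjectId, time in days, event in {0,1}, plus the
#'   generator covariates heartRate, qrsWidth and the true log-odds
#'   linear predictor `trueRisk` for oracle checks).
#' @export
generateCohort <- function(config, grid) {
  stopifnot(inherits(config, "cohortConfig"), is(grid, "IntervalGrid"))
  b <- intervalBoundaries(grid)
  K <- length(b) - 1L
  n <- config$nSubjects
  censMax <- if (is.null(config$censMax)) max(b) else config$censMax
  set.seed(config$seed)
  hr <- runif(n, config$hrRange[1], config$hrRange[2])
  qw <- runif(n, config$qrsWidthRange[1], config$qrsWidthRange[2])
  lp <- config$coefHr * .stdUnif(hr, config$hrRange) +
        config$coefQrs * .stdUnif(qw, config$qrsWidthRange)
  h <- stats::plogis(stats::qlogis(config$baselineHazard) + lp)
  .assert(all(h > 0 & h < 1), "implied hazards leave (0, 1)")
  ## event interval: first Bernoulli(h) success over the K intervals
  U <- matrix(runif(n * K), n, K)
  died <- sweep(U, 1L, h, "<")
  firstDeath <- apply(died, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
  uWithin <- runif(n)
  tEvent <- ifelse(is.na(firstDeath), Inf,
                   b[firstDeath] + uWithin * (b[firstDeath + 1L] - b[firstDeath]))
  hasCens <- runif(n) < config$censProb
  tCens <- ifelse(hasCens, runif(n, 0, censMax), Inf)
  tCens <- pmin(tCens, max(b))             # horizon truncation
  time <- pmin(tEvent, tCens, max(b))
  event <- as.integer(is.finite(tEvent) & tEvent <= tCens & tEvent <= max(b))
  sigSeeds <- .childSeeds(config$seed, n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    signals[[i]] <- generateEcg(waveTemplate(qrsWidth = qw[i]), heartRate = hr[i],
                                fs = config$fs, duration = config$duration,
                                noiseSd = config$noiseSd, seed = sigSeeds[i])
  }
  ids <- sprintf("S%04d", seq_len(n))
  names(signals) <- ids
  list(signals = signals,
       records = data.frame(subjectId = ids, time = time, event = event,
                            heartRate = hr, qrsWidth = qw, trueRisk = lp,
                            stringsAsFactors = FALSE))
}

#' Write / read an ECG signal as CSV
#'
#' One CSV per record: columns are lead names, rows are samples in mV; a
#' leading comment line carries the sampling frequency.
#'
#' @param signal an [ECGSignal-class].
#' @param path output file path.
#' @export
writeEcgCsv <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", samplingRate(signal)), con)
  write.csv(as.data.frame(sampleMatrix(signal)), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEcgCsv
#' @return `readEcgCsv` returns an [ECGSignal-class].
#' @export
readEcgCsv <- function(path) {
  first <- readLines(path, n = 1L)
  .assert(grepl("^# fs=", first), "missing '# fs=' header in %s", path)
  fs <- as.numeric(sub("^# fs=", "", first))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  new("ECGSignal", samples = as.matrix(df), fs = fs)
}

#' Write / read a cohort manifest CSV
#'
#' @param records cohort records data.frame (subjectId, time, event, ...).
#' @param path file path.
#' @export
writeManifestCsv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifestCsv
#' @export
readManifestCsv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
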