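## Fidelity and performance metrics: per-lead Pearson correlation and MAE
## for digitization round trips, and Harrell's concordance index under
## censoring with bootstrap confidence intervals.

#' Per-lead fidelity of a digitized ECG against its source
#'
#' Compares the recovered signal with the reference on the aligned
#' in-window samples only (validity mask > 0), reporting per-lead Pearson
#' correlation and mean absolute error in mV. The reference should have
#' been through the same filter/resample chain so that only digitization
#' error is measured. Leads whose reference is constant (zero variance)
#' get `NA` correlation and are counted, not dropped silently.
#'
#' @param reference an [ECGSignal-class] at the digitized rate (400 Hz).
#' @param recovered a [DigitizedECG-class] (or a second ECGSignal, in
#'   which case all samples are compared).
#' @return data.frame with columns lead, r, mae, n (samples compared).
#' @export
fidelityMetrics <- function(reference, recovered) {
  stopifnot(is(reference, "ECGSignal"))
  refM <- sampleMatrix(reference)
  if (is(recovered, "DigitizedECG")) {
    recM <- sampleMatrix(recovered)
    mask <- validityMask(recovered) > 0L
  } else {
    recM <- sampleMatrix(recovered)
    mask <- matrix(TRUE, nrow(recM), ncol(recM), dimnames = dimnames(recM))
  }
  leads <- intersect(colnames(recM), colnames(refM))
  .assert(length(leads) > 0, "no shared leads to compare")
  .assert(nrow(refM) == nrow(recM),
          "frame lengths differ (%d vs %d)", nrow(refM), nrow(recM))
  res <- lapply(leads, function(ld) {
    sel <- mask[, ld]
    n <- sum(sel)
    if (n < 2L) return(data.frame(lead = ld, r = NA_real_, mae = NA_real_, n = n))
    x <- refM[sel, ld]; y <- recM[sel, ld]
    r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    data.frame(lead = ld, r = r, mae = mean(abs(x - y)), n = n)
  })
  do.call(rbind, res)
}

## O(n^2) but vectorized Harrell's C on one sample
.harrellC <- function(risk, time, event) {
  ev <- which(event == 1L)
  conc <- 0; ties <- 0; np <- 0
  for (i in ev) {
    later <- time > time[i]
    np <- np + sum(later)
    conc <- conc + sum(risk[i] > risk[later])
    ties <- ties + sum(risk[i] == risk[later])
  }
  if (np == 0) return(NA_real_)
  (conc + 0.5 * ties) / np
}

#' Harrell's concordance index with bootstrap interval
#'
#' Among comparable pairs (i, j) with `time_i < time_j` and `event_i = 1`,
#' the fraction where `risk_i > risk_j`, counting risk ties as 1/2.
#' Pairs with equal times are non-comparable. The confidence interval is
#' a seeded percentile bootstrap over records.
#'
#' @param risk numeric risk scores (higher = earlier predicted death).
#' @param time observed times.
#' @param event binary event indicators (1 = death, 0 = censored).
#' @param B bootstrap resamples (0 disables the interval).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return list of class `metricResult`: estimate, lower, upper, B, seed.
#' @examples
#' concordanceIndex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1), B = 0)
#' @export
concordanceIndex <- function(risk, time, event, B = 200L, conf = 0.95, seed = 1L) {
  n <- length(risk)
  .assert(length(time) == n && length(event) == n, "input lengths differ")
  .assert(all(event %in% c(0, 1)), "event must be binary")
  est <- .harrellC(risk, time, event)
  .assert(is.finite(est), "no comparable pairs: concordance undefined")
  lower <- upper <- NA_real_
  if (B > 0) {
    set.seed(as.integer(seed))
    bs <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      .harrellC(risk[idx], time[idx], event[idx])
    }, numeric(1))
    qs <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    lower <- unname(qs[1]); upper <- unname(qs[2])
  }
  structure(list(estimate = est, lower = lower, upper = upper,
                 B = as.integer(B), conf = conf, seed = as.integer(seed)),
            class = "metricResult")
}

#' @export
print.metricResult <- function(x, ...) {
  cat(sprintf("C-index %.4f", x$estimate))
  if (is.finite(x$lower))
    cat(sprintf(" (%.0f%% CI %.4f-%.4f, B = %d)", 100 * x$conf, x$lower, x$upper, x$B))
  cat("\n")
  invisible(x)
}

#' Render-digitize round-trip fidelity benchmark
#'
#' Generates `n` synthetic 12-lead ECGs with randomized heart rate and
#' QRS width, renders each as a paper-format page, optionally degrades
#' it, digitizes it back, and scores fidelity against the source signal
#' passed through the same filter/resample chain. Fully seeded.
#'
#' @param n number of records.
#' @param seed integer master seed.
#' @param layout a [LayoutSpec-class].
#' @param style a [RenderStyle-class].
#' @param degrade NULL for clean pages, or a list with any of `rotation`
#'   (deg), `blurSd` (px), `noiseSd` (intensity) for scan simulation.
#' @param config a [preprocessConfig()].
#' @return list of class `fidelityReport`: perLead data.frame over all
#'   records, `medianR`, `rQuantiles` (2.5/25/75/97.5%), `meanMae`,
#'   `nRecords`, `nFailed`.
#' @export
roundtripBenchmark <- function(n = 50L, seed = 7L, layout = layoutSpec(),
                               style = renderStyle(), degrade = NULL,
                               config = preprocessConfig()) {
  .assert(n >= 1, "n must be >= 1")
  set.seed(as.integer(seed))
  hr <- runif(n, 50, 110)
  qw <- runif(n, 0.008, 0.020)
  seeds <- .childSeeds(seed, 2L * n)
  perLead <- list()
  nFailed <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      ecg <- generateEcg(waveTemplate(qrsWidth = qw[i]), heartRate = hr[i],
                         fs = 500, duration = layout@columns * layout@secondsPerColumn,
                         noiseSd = 0.02, seed = seeds[i])
      page <- renderPaperEcg(ecg, layout, style)
      if (!is.null(degrade))
        page <- applyScanDegradation(page,
                  rotation = degrade$rotation %||% 0,
                  blurSd = degrade$blurSd %||% 0,
                  noiseSd = degrade$noiseSd %||% 0,
                  seed = seeds[n + i])
      dig <- digitizeEcg(page, layout, config)
      ref <- filterResample(ecg, config)
      fm <- fidelityMetrics(ref, dig)
      fm$record <- i
      fm
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nFailed <- nFailed + 1L
      warning(sprintf("record %d failed: %s", i, conditionMessage(res)))
    } else perLead[[length(perLead) + 1L]] <- res
  }
  .assert(length(perLead) > 0, "all records failed")
  perLead <- do.call(rbind, perLead)
  rs <- perLead$r[is.finite(perLead$r)]
  structure(list(perLead = perLead,
                 medianR = median(rs),
                 rQuantiles = quantile(rs, c(0.025, 0.25, 0.75, 0.975)),
                 meanMae = mean(perLead$mae, na.rm = TRUE),
                 nRecords = as.integer(n) - nFailed, nFailed = nFailed,
                 seed = as.integer(seed)),
            class = "fidelityReport")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fidelityReport <- function(x, ...) {
  cat(sprintf("Round-trip fidelity over %d records (%d failed):\n",
              x$nRecords, x$nFailed))
  cat(sprintf("  median per-lead Pearson r: %.4f (IQR %.4f-%.4f)\n",
              x$medianR, x$rQuantiles[2], x$rQuantiles[3]))
  cat(sprintf("  mean absolute error: %.4f mV\n", x$meanMae))
  invisible(x)
}
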