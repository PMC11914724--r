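## 1D preprocessing shared by the natively digital and digitized routes:
## zero-phase band-pass + notch filtering, resampling to a common rate,
## independent-lead selection, asynchronous window masking, and symmetric
## power-of-two zero padding.

#' Preprocessing configuration
#'
#' @param low,high band-pass corners, Hz (defaults 0.5 and 100).
#' @param notch powerline notch frequency, Hz (default 60); `NA` disables.
#' @param notchQ notch quality factor (default 30).
#' @param fsOut output sampling frequency, Hz (default 400).
#' @param order band-pass Butterworth order (default 3), applied
#'   forward-backward for zero phase.
#' @return a list of class `preprocessConfig`.
#' @export
preprocessConfig <- function(low = 0.5, high = 100, notch = 60, notchQ = 30,
                             fsOut = 400, order = 3L) {
  .assert(low > 0 && low < high, "need 0 < low < high")
  .assert(high < fsOut / 2, "band-pass upper edge must be below fsOut/2")
  structure(list(low = low, high = high, notch = notch, notchQ = notchQ,
                 fsOut = fsOut, order = as.integer(order)),
            class = "preprocessConfig")
}

## biquad notch (standard audio-EQ cookbook design)
.notchCoef <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

## zero-phase band-pass + notch on a matrix of lead columns at rate fs
.filterMatrix <- function(m, fs, config) {
  bp <- signal::butter(config$order, c(config$low, config$high) / (fs / 2), type = "pass")
  nc <- if (is.finite(config$notch)) .notchCoef(config$notch, fs, config$notchQ) else NULL
  for (j in seq_len(ncol(m))) {
    x <- signal::filtfilt(bp, m[, j])
    if (!is.null(nc)) x <- signal::filtfilt(nc$b, nc$a, x)
    m[, j] <- x
  }
  m
}

## cubic-spline resample of lead columns from fs to fsOut over `duration`
## seconds; tIn0 is the timestamp of the first input sample (the output
## grid always starts at 0)
.resampleMatrix <- function(m, fs, fsOut, duration, tIn0 = 0) {
  nOut <- round(fsOut * duration)
  tIn <- (seq_len(nrow(m)) - 1L) / fs + tIn0
  tOut <- (seq_len(nOut) - 1L) / fsOut
  out <- matrix(0, nOut, ncol(m), dimnames = list(NULL, colnames(m)))
  ## monotone Hermite interpolation: overshoot-free on steep QRS strokes,
  ## unlike the natural cubic spline
  for (j in seq_len(ncol(m)))
    out[, j] <- stats::splinefun(tIn, m[, j], method = "monoH.FC")(tOut)
  out
}

#' Band-pass + notch filter and resample an ECG signal
#'
#' Applies a zero-phase Butterworth band-pass (0.5-100 Hz by default) and
#' a 60 Hz notch, then resamples to `config$fsOut` (400 Hz) by cubic
#' spline interpolation of the band-limited signal; output length is
#' `round(fsOut * duration)`. When the input rate is too low to realize
#' the band-pass upper corner (fs <= 2.2 * high, as for pixel-rate traces
#' near 200 Hz), the signal is interpolated to `fsOut` first and filtered
#' there.
#'
#' @param signal an [ECGSignal-class].
#' @param config a [preprocessConfig()].
#' @param tIn0 timestamp of the first input sample, s; the output grid
#'   always starts at 0 (digitized pixel columns are centred half a
#'   pixel into their window, so the digitizer passes half a pixel here).
#' @return an [ECGSignal-class] at `fsOut`.
#' @export
filterResample <- function(signal, config = preprocessConfig(), tIn0 = 0) {
  stopifnot(is(signal, "ECGSignal"), inherits(config, "preprocessConfig"))
  m <- sampleMatrix(signal)
  .assert(all(is.finite(m)), "signal contains non-finite samples")
  fs <- samplingRate(signal)
  duration <- nrow(m) / fs
  if (fs <= 2.2 * config$high) {
    m <- .resampleMatrix(m, fs, config$fsOut, duration, tIn0)
    m <- .filterMatrix(m, config$fsOut, config)
  } else {
    m <- .filterMatrix(m, fs, config)
    m <- .resampleMatrix(m, fs, config$fsOut, duration, tIn0)
  }
  new("ECGSignal", samples = m, fs = config$fsOut)
}

#' Symmetric zero padding to the next power of two
#'
#' A 10-s lead at 400 Hz (4000 samples) becomes 4096 samples with 48
#' zeros at the start and end; a 2.5-s lead (1000 samples) becomes 1024
#' with 12 each side. Odd remainders put the extra zero at the end.
#'
#' @param signal an [ECGSignal-class] (any number of leads).
#' @return an [ECGSignal-class] padded along the sample axis.
#' @export
padPowerOfTwo <- function(signal) {
  stopifnot(is(signal, "ECGSignal"))
  m <- sampleMatrix(signal)
  n <- nrow(m)
  target <- .nextPow2(n)
  if (target == n) return(signal)
  leftN <- (target - n) %/% 2L
  rightN <- target - n - leftN
  pad <- function(k) matrix(0, k, ncol(m))
  out <- rbind(pad(leftN), m, pad(rightN))
  colnames(out) <- colnames(m)
  new("ECGSignal", samples = out, fs = samplingRate(signal))
}

#' Keep only the 8 linearly independent leads
#'
#' Drops III, aVR, aVL and aVF (linear combinations of I and II) and
#' returns the remaining leads in the order I, II, V1-V6.
#'
#' @param signal an [ECGSignal-class] carrying all 12 leads.
#' @return an [ECGSignal-class] with 8 leads.
#' @export
selectIndependentLeads <- function(signal) {
  stopifnot(is(signal, "ECGSignal"))
  present <- leadNames(signal)
  missing <- setdiff(.LEADS, present)
  .assert(length(missing) == 0L, "missing lead(s): %s", paste(missing, collapse = ", "))
  m <- sampleMatrix(signal)[, .INDEP_LEADS, drop = FALSE]
  new("ECGSignal", samples = m, fs = samplingRate(signal))
}

## panel column index of each requested lead under a layout
.leadColumns <- function(leads, layout) {
  vapply(leads, function(ld) {
    w <- which(layout@leadGrid == ld, arr.ind = TRUE)
    .assert(nrow(w) == 1L, "lead %s has no column assignment in the layout", ld)
    as.integer(w[1L, "col"])
  }, integer(1))
}

#' Mask a signal to the asynchronous paper-layout windows
#'
#' Each lead keeps only the samples inside its panel column's time window
#' [col * secondsPerColumn, (col+1) * secondsPerColumn) and is zero
#' elsewhere, emulating what a paper page actually shows. Operates on the
#' unpadded frame (e.g. 4000 samples at 400 Hz) so window arithmetic is
#' exact; apply before [padPowerOfTwo()].
#'
#' @param signal an [ECGSignal-class] spanning the full frame.
#' @param layout a [LayoutSpec-class] assigning each lead a column.
#' @return an [ECGSignal-class] with out-of-window samples zeroed.
#' @export
applyAsyncMask <- function(signal, layout = layoutSpec()) {
  stopifnot(is(signal, "ECGSignal"), is(layout, "LayoutSpec"))
  m <- sampleMatrix(signal)
  fs <- samplingRate(signal)
  nWin <- round(layout@secondsPerColumn * fs)
  cols <- .leadColumns(colnames(m), layout)
  for (j in seq_len(ncol(m))) {
    lo <- (cols[j] - 1L) * nWin + 1L
    hi <- min(cols[j] * nWin, nrow(m))
    keep <- logical(nrow(m))
    keep[lo:hi] <- TRUE
    m[!keep, j] <- 0
  }
  new("ECGSignal", samples = m, fs = fs)
}

#' Assemble the 1D model-input tensor
#'
#' Full preprocessing chain in the fixed order filter -> resample ->
#' optional asynchronous mask -> independent-lead selection -> power-of-two
#' padding, yielding the 4096 x 8 tensor (for a 10-s recording) consumed
#' by the 1D survival networks.
#'
#' @param signal a 12-lead [ECGSignal-class].
#' @param config a [preprocessConfig()].
#' @param asynchronous logical; mask leads to their 2.5-s layout windows.
#' @param layout layout used for the asynchronous mask.
#' @param prefiltered set TRUE when `signal` is already at `fsOut` and
#'   filtered (e.g. the output of [digitizeEcg()]), to skip re-filtering.
#' @return numeric matrix (padded samples x 8 leads) with attribute
#'   `format` = "synchronous" or "asynchronous".
#' @export
prepareModelInput1D <- function(signal, config = preprocessConfig(),
                                asynchronous = FALSE, layout = layoutSpec(),
                                prefiltered = FALSE) {
  s <- if (prefiltered) signal else filterResample(signal, config)
  if (asynchronous) s <- applyAsyncMask(s, layout)
  s <- selectIndependentLeads(s)
  s <- padPowerOfTwo(s)
  out <- sampleMatrix(s)
  attr(out, "format") <- if (asynchronous) "asynchronous" else "synchronous"
  out
}
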