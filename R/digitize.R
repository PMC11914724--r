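## Digitization of paper-format ECG images: colour/greyscale masks split
## trace ink from the calibration grid; the grid's small-box pitch gives
## the time/amplitude scaling (1 small box = 1 mm = 0.04 s / 0.1 mV at
## standard speed and gain); per-lead regions of interest are scanned
## column-wise (intensity-weighted centroids), label glyphs are removed by
## connected-component size filtering, missing columns are interpolated,
## and the traces are band-pass filtered, resampled to 400 Hz and placed
## at their layout time offsets in a zero-padded 12 x 10-s frame.

## luminance of an RGB array (Rec. 601 weights)
.luminance <- function(pixels) {
  if (length(dim(pixels)) == 2L) return(pixels)
  y <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  pmin(pmax(y, 0), 1)   # guard rounding at the [0, 1] borders
}

#' Split a page into trace and grid masks
#'
#' For colour pages, trace ink is dark and neutral (all channels low)
#' while the grid is reddish (red channel well above green/blue); for
#' greyscale pages the separation is by intensity band. Also returns a
#' darkness weight image used for sub-pixel centroid extraction.
#'
#' @param render a [RenderedECG-class] (or raw pixel matrix/array).
#' @return list: `trace`, `grid` (logical matrices), `darkness` (numeric
#'   matrix in [0,1]), and `blank` (TRUE with a warning for an all-white
#'   page).
#' @export
extractTraceGridMasks <- function(render) {
  pixels <- if (is(render, "RenderedECG")) pixelData(render) else render
  colour <- length(dim(pixels)) == 3L
  lum <- .luminance(pixels)
  if (colour) {
    ## the grid is reddish (red channel stays high), so dark-and-neutral
    ## can be generous: blurred thin strokes are still caught
    mx <- pmax(pixels[, , 1], pixels[, , 2], pixels[, , 3])
    trace <- mx < 0.7
    redExcess <- pixels[, , 1] - (pixels[, , 2] + pixels[, , 3]) / 2
    grid <- !trace & redExcess > 0.08 & pixels[, , 1] > 0.5
  } else {
    trace <- lum < 0.6
    grid <- lum >= 0.62 & lum < 0.93
  }
  blank <- !any(trace)
  if (blank) warning("no trace ink found: blank or unreadable page")
  list(trace = trace, grid = grid, darkness = 1 - lum, blank = blank)
}

## morphological closing bridges 1-2 px trace breaks (blur/noise thin out
## steep strokes) so the component-size filter below sees whole traces
.closeMask <- function(mask) {
  if (!any(mask)) return(mask)
  img <- EBImage::Image(t(mask) * 1)
  closed <- EBImage::erode(EBImage::dilate(img, EBImage::makeBrush(3, "box")),
                           EBImage::makeBrush(3, "box"))
  t(EBImage::imageData(closed)) > 0.5
}

## drop connected components whose bounding box fits in maxDim x maxDim
## (lead-name glyphs, specks); traces span whole column windows and stay
.removeLabelComponents <- function(mask, maxDim = 80L) {
  if (!any(mask)) return(mask)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  ij <- which(lab > 0, arr.ind = TRUE)
  id <- lab[ij]
  h <- tapply(ij[, 1], id, function(r) diff(range(r)) + 1L)
  w <- tapply(ij[, 2], id, function(c) diff(range(c)) + 1L)
  small <- as.integer(names(h))[h <= maxDim & w <= maxDim]
  if (length(small)) {
    drop <- id %in% small
    mask[ij[drop, , drop = FALSE]] <- FALSE
  }
  mask
}

## Estimate the period of a line-projection profile. Peaks are clustered
## maxima; the pitch is the least-squares spacing allowing for occasional
## missed lines. Returns NA when the periodicity is ambiguous.
.estimatePitch <- function(proj, minPeak = 0.5) {
  if (length(proj) < 8L || max(proj) <= 0) return(NA_real_)
  thr <- minPeak * max(proj)
  on <- which(proj >= thr)
  if (length(on) < 4L) return(NA_real_)
  ## cluster consecutive indices into line centres (weighted by projection)
  brk <- c(0L, which(diff(on) > 2L), length(on))
  centers <- vapply(seq_len(length(brk) - 1L), function(i) {
    idx <- on[(brk[i] + 1L):brk[i + 1L]]
    sum(idx * proj[idx]) / sum(proj[idx])
  }, numeric(1))
  if (length(centers) < 5L) return(NA_real_)
  d <- diff(centers)
  pitch0 <- median(d)
  if (!is.finite(pitch0) || pitch0 <= 1) return(NA_real_)
  k <- round(d / pitch0)
  ok <- k >= 1
  if (sum(ok) < 3L) return(NA_real_)
  pitch <- sum(d[ok]) / sum(k[ok])
  ## ambiguous if residual spacing error is large
  if (stats::sd(d[ok] / k[ok]) > 0.15 * pitch) return(NA_real_)
  pitch
}

#' Calibrate pixel-to-physical scaling from the background grid
#'
#' Estimates the small-box pitch (px per mm) from the periodicity of the
#' grid mask's row and column projections, assuming 1 small box = 1 mm
#' (0.04 s at 25 mm/s; 0.1 mV at 10 mm/mV). When no usable grid is found
#' the calibration falls back to layout-based scaling from the trace
#' panel's pixel extent, with `gridDetected = FALSE`.
#'
#' @param x a [RenderedECG-class], or a logical grid mask matrix.
#' @param layout the declared [LayoutSpec-class] (speed/gain, fallback).
#' @param traceMask optional trace mask for the layout fallback.
#' @return a [GridCalibration-class].
#' @export
calibrateGrid <- function(x, layout = layoutSpec(), traceMask = NULL) {
  if (is(x, "RenderedECG")) {
    masks <- extractTraceGridMasks(x)
    gridMask <- masks$grid
    if (is.null(traceMask)) traceMask <- .removeLabelComponents(masks$trace)
  } else gridMask <- x
  px <- .estimatePitch(colSums(gridMask))
  py <- .estimatePitch(rowSums(gridMask))
  detected <- is.finite(px) && is.finite(py) && abs(px - py) < 0.2 * max(px, py)
  if (!detected) {
    .assert(!is.null(traceMask) && any(traceMask),
            "grid calibration failed and no trace panel available for layout fallback")
    cols <- which(colSums(traceMask) > 0)
    widthMm <- layout@columns * layout@secondsPerColumn * layout@paperSpeed
    px <- py <- (max(cols) - min(cols) + 1L) / widthMm
    message("no grid detected: using layout-based scaling (",
            signif(px, 4), " px/mm)")
  }
  new("GridCalibration", pxPerMmX = px, pxPerMmY = py,
      secondsPerPx = 1 / (layout@paperSpeed * px),
      mvPerPx = 1 / (layout@gain * py),
      gridDetected = detected)
}

## Baseline rows from the trace mask: rows where flat trace segments pile
## up project strongly; clustered peaks give one centre per drawn row.
.detectBaselineRows <- function(traceMask, minFrac = 0.35) {
  proj <- rowSums(traceMask)
  if (max(proj) == 0) return(integer(0))
  on <- which(proj >= minFrac * max(proj))
  brk <- c(0L, which(diff(on) > 25L), length(on))
  centers <- vapply(seq_len(length(brk) - 1L), function(i) {
    idx <- on[(brk[i] + 1L):brk[i + 1L]]
    sum(idx * proj[idx]) / sum(proj[idx])
  }, numeric(1))
  round(centers)
}

## split sorted pixel rows into vertical runs (gap > 3 px starts a new run)
.rowRuns <- function(rows) {
  brk <- c(0L, which(diff(rows) > 3L), length(rows))
  lapply(seq_len(length(brk) - 1L), function(i) rows[(brk[i] + 1L):brk[i + 1L]])
}

#' Extract one lead's trace from a region of interest
#'
#' Scans the ROI column by column: the trace value in each pixel column
#' is the intensity-weighted centroid row of its trace pixels; when a
#' column holds several disconnected vertical runs (residual glyphs,
#' neighbouring-trace spill) the run nearest the previously accepted
#' centroid wins. Columns without trace pixels are flagged missing. Rows
#' are converted to mV around the baseline via the calibration.
#'
#' @param roi numeric matrix of trace darkness weights (0 = background),
#'   already restricted to one lead's band, or a logical mask.
#' @param calib a [GridCalibration-class].
#' @param baselineRow baseline row within the ROI; when NULL it is the
#'   median of the accepted centroid rows.
#' @return list: `samples` (mV, NA where missing), `missing` (logical),
#'   `baselineRow`, `centroids`.
#' @export
extractLeadSignal <- function(roi, calib, baselineRow = NULL) {
  w <- if (is.logical(roi)) roi * 1 else roi
  nc <- ncol(w)
  cent <- rep(NA_real_, nc)
  anyInk <- which(colSums(w) > 0)
  .assert(length(anyInk) > 0, "unreadable ROI: no trace pixels")
  prev <- if (!is.null(baselineRow)) baselineRow else {
    ij <- which(w > 0, arr.ind = TRUE)
    median(ij[, 1])
  }
  for (j in seq_len(nc)) {
    rows <- which(w[, j] > 0)
    if (!length(rows)) next
    runs <- .rowRuns(rows)
    if (length(runs) > 1L) {
      mids <- vapply(runs, function(r) sum(r * w[r, j]) / sum(w[r, j]), numeric(1))
      rows <- runs[[which.min(abs(mids - prev))]]
    }
    cent[j] <- sum(rows * w[rows, j]) / sum(w[rows, j])
    prev <- cent[j]
  }
  missing <- is.na(cent)
  .assert(mean(missing) <= 0.5, "unreadable ROI: %.0f%% of columns missing",
          100 * mean(missing))
  if (is.null(baselineRow)) baselineRow <- median(cent, na.rm = TRUE)
  list(samples = (baselineRow - cent) * calib@mvPerPx,
       missing = missing, baselineRow = baselineRow, centroids = cent)
}

#' Digitize a paper-format ECG image
#'
#' Full pipeline: trace/grid masks, label-glyph removal, grid calibration
#' (with layout fallback), per-lead ROI location from baseline-row and
#' panel-extent detection, column-wise trace extraction, linear
#' interpolation of missing columns, 0.5-100 Hz band-pass + 60 Hz notch,
#' resampling to 400 Hz, and placement of each lead's window at its
#' column's time offset in a zero-padded 10-s frame. Rhythm strips, when
#' present, are ignored.
#'
#' @param render a [RenderedECG-class].
#' @param layout the declared [LayoutSpec-class].
#' @param config a [preprocessConfig()] (filters and output rate).
#' @return a [DigitizedECG-class].
#' @examples
#' ecg <- generateEcg(seed = 3)
#' dig <- digitizeEcg(renderPaperEcg(ecg))
#' @export
digitizeEcg <- function(render, layout = layoutSpec(), config = preprocessConfig()) {
  stopifnot(is(render, "RenderedECG"), is(layout, "LayoutSpec"))
  masks <- extractTraceGridMasks(render)
  .assert(!masks$blank, "fatal: blank page")
  trace <- .removeLabelComponents(.closeMask(masks$trace))
  calib <- calibrateGrid(if (any(masks$grid)) masks$grid else matrix(FALSE, 1, 1),
                         layout = layout, traceMask = trace)
  bl <- .detectBaselineRows(trace)
  .assert(length(bl) >= layout@rows,
          "fatal: found %d trace rows, layout expects %d", length(bl), layout@rows)
  panelBl <- bl[seq_len(layout@rows)]
  pitch <- if (length(bl) > 1L) mean(diff(sort(bl))) else nrow(trace) / 2
  halfBand <- max(8L, floor(pitch / 2) - 1L)
  ## panel x-extent from the panel rows' ink
  panelRows <- max(1L, round(panelBl[1] - halfBand)):
               min(nrow(trace), round(panelBl[layout@rows] + halfBand))
  panelTrace <- trace[panelRows, , drop = FALSE]
  xs <- which(colSums(panelTrace) > 0)
  .assert(length(xs) > layout@columns, "fatal: no panel traces found")
  x0 <- min(xs); x1 <- max(xs)
  colW <- (x1 - x0 + 1L) / layout@columns

  darkness <- masks$darkness * trace
  spc <- layout@secondsPerColumn
  fsOut <- config$fsOut
  nWin <- round(spc * fsOut)
  nFrame <- nWin * layout@columns
  samplesOut <- matrix(0, nFrame, 12L, dimnames = list(NULL, .LEADS))
  maskOut <- matrix(0L, nFrame, 12L, dimnames = list(NULL, .LEADS))
  missingFrac <- setNames(numeric(12L), .LEADS)
  warningsOut <- character(0)

  ## pixel-rate window matrices, filtered jointly for efficiency
  nPx <- floor(colW)
  winPx <- matrix(0, nPx, 12L, dimnames = list(NULL, .LEADS))
  missPx <- matrix(FALSE, nPx, 12L, dimnames = list(NULL, .LEADS))
  leadOk <- setNames(rep(TRUE, 12L), .LEADS)
  for (r in seq_len(layout@rows)) for (cc in seq_len(layout@columns)) {
    lead <- layout@leadGrid[r, cc]
    rLo <- max(1L, round(panelBl[r] - halfBand))
    rHi <- min(nrow(trace), round(panelBl[r] + halfBand))
    cLo <- round(x0 + (cc - 1L) * colW)
    cCols <- cLo + seq_len(nPx) - 1L
    roi <- darkness[rLo:rHi, cCols, drop = FALSE]
    ext <- tryCatch(extractLeadSignal(roi, calib), error = function(e) e)
    if (inherits(ext, "error")) {
      leadOk[lead] <- FALSE
      missingFrac[lead] <- 1
      warningsOut <- c(warningsOut, sprintf("lead %s: %s", lead, conditionMessage(ext)))
      next
    }
    v <- ext$samples
    missingFrac[lead] <- mean(ext$missing)
    if (any(ext$missing)) {       # linear interpolation over missing columns
      idx <- seq_along(v)
      v <- approx(idx[!ext$missing], v[!ext$missing], xout = idx, rule = 2)$y
    }
    winPx[, lead] <- v
    missPx[, lead] <- ext$missing
  }

  ## band-pass + notch + resample each 2.5-s window to fsOut, then place
  ## it at the lead's column time offset
  fsPx <- nPx / spc
  filt <- filterResample(new("ECGSignal", samples = winPx, fs = fsPx), config,
                         tIn0 = 0.5 / fsPx)
  win400 <- sampleMatrix(filt)
  cols <- .leadColumns(.LEADS, layout)
  for (lead in .LEADS) {
    if (!leadOk[lead]) next
    off <- (cols[lead] - 1L) * nWin
    samplesOut[off + seq_len(nWin), lead] <- win400[seq_len(nWin), lead]
    srcCol <- pmin(nPx, pmax(1L, ceiling(seq_len(nWin) * nPx / nWin)))
    maskOut[off + seq_len(nWin), lead] <- ifelse(missPx[srcCol, lead], 2L, 1L)
  }
  new("DigitizedECG", samples = samplesOut, mask = maskOut, fs = fsOut,
      calibration = calib,
      quality = list(gridDetected = calib@gridDetected,
                     missingFraction = missingFrac,
                     leadValid = leadOk, warnings = warningsOut))
}

#' Write a digitized ECG as CSV (+ validity mask and quality JSON)
#'
#' @param dig a [DigitizedECG-class].
#' @param path CSV path for the samples; the mask goes to
#'   `<path>.mask.csv` and the quality report to `<path>.quality.json`.
#' @export
writeDigitizedCsv <- function(dig, path) {
  con <- file(path, "w")
  writeLines(sprintf("# fs=%g", dig@fs), con)
  write.csv(as.data.frame(sampleMatrix(dig)), con, row.names = FALSE)
  close(con)
  write.csv(as.data.frame(validityMask(dig)), paste0(path, ".mask.csv"),
            row.names = FALSE)
  q <- dig@quality
  jsonlite::write_json(list(gridDetected = q$gridDetected,
                            missingFraction = as.list(q$missingFraction),
                            warnings = q$warnings),
                       paste0(path, ".quality.json"), auto_unbox = TRUE)
  invisible(path)
}
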