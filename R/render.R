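## Paper-format ECG rendering: a rows x columns panel of asynchronous
## time windows plus optional full-length rhythm strips, with standard
## grid (1 mm small boxes, 5 mm major lines), at 25 mm/s and 10 mm/mV.
## Synthetic renders retain ground-truth geometry used as the oracle for
## round-trip digitization tests.

#' Construct a paper-format layout
#'
#' Defaults follow the common hospital dialect: 12 leads of 2.5 s each in
#' 4 columns and 3 rows (column-major standard order: I,II,III | aVR,aVL,
#' aVF | V1-V3 | V4-V6) with three 10-s rhythm strips below.
#'
#' @param columns,rows panel shape; `columns * rows` must be 12.
#' @param secondsPerColumn seconds shown per column (2.5).
#' @param rhythmLeads leads drawn as full-length strips (up to 3);
#'   `character(0)` for none.
#' @param paperSpeed mm/s (25).
#' @param gain mm/mV (10).
#' @param leadGrid optional rows x columns character matrix mapping cells
#'   to leads.
#' @return a [LayoutSpec-class].
#' @export
layoutSpec <- function(columns = 4L, rows = 3L, secondsPerColumn = 2.5,
                       rhythmLeads = c("II", "V1", "V5"),
                       paperSpeed = 25, gain = 10, leadGrid = NULL) {
  .assert(columns * rows == 12, "columns * rows must equal 12")
  if (is.null(leadGrid))
    leadGrid <- matrix(.LEADS, nrow = rows, ncol = columns)
  new("LayoutSpec", columns = as.integer(columns), rows = as.integer(rows),
      secondsPerColumn = secondsPerColumn, rhythmLeads = rhythmLeads,
      paperSpeed = paperSpeed, gain = gain, leadGrid = leadGrid)
}

#' Construct a render style
#'
#' @param pageWidth,pageHeight page raster size in px (2200 x 1700).
#' @param grid draw the background grid (TRUE).
#' @param colour RGB page with light-red grid (TRUE) vs greyscale page
#'   with light-grey grid.
#' @param pxPerMm pixels per millimetre (8).
#' @param labelFontPx lead-label glyph height, px; 0 disables labels.
#' @param traceHalfWidthPx trace half-thickness, px.
#' @return a [RenderStyle-class].
#' @export
renderStyle <- function(pageWidth = 2200L, pageHeight = 1700L, grid = TRUE,
                        colour = TRUE, pxPerMm = 8, labelFontPx = 15,
                        traceHalfWidthPx = 1L) {
  new("RenderStyle", pageWidth = as.integer(pageWidth),
      pageHeight = as.integer(pageHeight), grid = grid, colour = colour,
      pxPerMm = pxPerMm, labelFontPx = labelFontPx,
      traceHalfWidthPx = as.integer(traceHalfWidthPx))
}

## 5x3 bitmap glyphs for lead labels ('#' = ink)
.GLYPHS <- list(
  "I" = c("###", ".#.", ".#.", ".#.", "###"),
  "V" = c("#.#", "#.#", "#.#", "#.#", ".#."),
  "a" = c("...", ".##", "#.#", "#.#", ".##"),
  "R" = c("##.", "#.#", "##.", "#.#", "#.#"),
  "L" = c("#..", "#..", "#..", "#..", "###"),
  "F" = c("###", "#..", "##.", "#..", "#.."),
  "1" = c(".#.", "##.", ".#.", ".#.", "###"),
  "2" = c("##.", "..#", ".#.", "#..", "###"),
  "3" = c("###", "..#", ".#.", "..#", "###"),
  "4" = c("#.#", "#.#", "###", "..#", "..#"),
  "5" = c("###", "#..", "##.", "..#", "##."),
  "6" = c(".##", "#..", "###", "#.#", ".##"))

## pixel (row, col) indices of a text label with top-left at (row0, col0)
.labelPixels <- function(text, row0, col0, fontPx) {
  sc <- max(1L, round(fontPx / 5))
  out <- list()
  cx <- col0
  for (ch in strsplit(text, "")[[1]]) {
    g <- .GLYPHS[[ch]]
    if (is.null(g)) { cx <- cx + 4L * sc; next }
    bits <- do.call(rbind, lapply(g, function(s) strsplit(s, "")[[1]] == "#"))
    ij <- which(bits, arr.ind = TRUE)
    if (nrow(ij)) {
      rows <- rep((ij[, 1] - 1L) * sc + row0, each = sc * sc) +
        rep(rep(seq_len(sc) - 1L, each = sc), nrow(ij))
      cols <- rep((ij[, 2] - 1L) * sc + cx, each = sc * sc) +
        rep(rep(seq_len(sc) - 1L, times = sc), nrow(ij))
      out[[length(out) + 1L]] <- cbind(rows, cols)
    }
    cx <- cx + 4L * sc
  }
  if (length(out)) do.call(rbind, out) else matrix(0L, 0L, 2L)
}

## rasterize a polyline through points (xcont, ycont): returns (row, col)
## pixel indices, with vertical thickening by +/- halfWidth
.polylinePixels <- function(xcont, ycont, halfWidth, H, W) {
  cols <- floor(xcont) + 1
  rows <- round(ycont)
  n <- length(cols)
  if (n < 2L) return(matrix(0L, 0L, 2L))
  dx <- diff(cols); dy <- diff(rows)
  steps <- pmax(abs(dx), abs(dy)) + 1L
  seg <- rep(seq_len(n - 1L), steps)
  idx <- sequence(steps)
  frac <- (idx - 1) / pmax(steps[seg] - 1L, 1L)
  px <- round(cols[seg] + frac * dx[seg])
  py <- round(rows[seg] + frac * dy[seg])
  if (halfWidth > 0L) {
    off <- -halfWidth:halfWidth
    px <- rep(px, times = length(off))
    py <- rep(py, times = length(off)) + rep(off, each = length(py))
  }
  keep <- px >= 1 & px <= W & py >= 1 & py <= H
  cbind(py[keep], px[keep])
}

## paint (row, col) index pairs with a colour on a grey matrix or RGB array
.paint <- function(pixels, ij, value) {
  if (nrow(ij) == 0L) return(pixels)
  d <- dim(pixels)
  if (length(d) == 2L) {
    pixels[ij] <- value[1]
  } else {
    for (ch in 1:3) pixels[cbind(ij, ch)] <- value[min(ch, length(value))]
  }
  pixels
}

#' Render an ECG signal as a paper-format page
#'
#' Draws each lead's time window as a connected polyline at `gain` mm/mV
#' and `paperSpeed` mm/s over an optional calibration grid, with small
#' bitmap lead labels below-left of each baseline, and appends rhythm
#' strips when the layout configures them. The returned object retains
#' ground-truth geometry (baseline rows, column windows, px scaling) for
#' oracle use.
#'
#' @param signal an [ECGSignal-class] with all leads the layout needs.
#' @param layout a [LayoutSpec-class].
#' @param style a [RenderStyle-class].
#' @return a [RenderedECG-class].
#' @examples
#' ecg <- generateEcg(seed = 7)
#' page <- renderPaperEcg(ecg)
#' @export
renderPaperEcg <- function(signal, layout = layoutSpec(), style = renderStyle()) {
  stopifnot(is(signal, "ECGSignal"), is(layout, "LayoutSpec"), is(style, "RenderStyle"))
  dur <- signalDuration(signal)
  panelDur <- layout@columns * layout@secondsPerColumn
  .assert(dur >= panelDur - 1e-9,
          "signal duration %.3g s is shorter than the layout's %.3g s", dur, panelDur)
  fs <- samplingRate(signal)
  m <- sampleMatrix(signal)
  H <- style@pageHeight; W <- style@pageWidth
  ppm <- style@pxPerMm
  pxPerSec <- layout@paperSpeed * ppm
  colWpx <- round(layout@secondsPerColumn * pxPerSec)
  panelW <- colWpx * layout@columns
  .assert(panelW <= W, "page width %d px cannot hold a %d px panel", W, panelW)
  xLeft <- floor((W - panelW) / 2)
  nStrips <- length(layout@rhythmLeads)
  nRowsTot <- layout@rows + nStrips
  topMargin <- round(0.06 * H)
  pitch <- (H - 2 * topMargin) / nRowsTot
  .assert(pitch > 4 * ppm, "page height %d px cannot hold %d rows", H, nRowsTot)
  baseRow <- function(r) round(topMargin + (r - 0.5) * pitch)

  grey <- !style@colour
  pixels <- if (grey) matrix(1, H, W) else array(1, c(H, W, 3))

  if (style@grid) {
    minorCol <- if (grey) 0.85 else c(1, 0.82, 0.82)
    majorCol <- if (grey) 0.70 else c(1, 0.60, 0.60)
    kx <- seq(-floor(xLeft / ppm), floor((W - xLeft) / ppm))
    xs <- round(xLeft + ppm * kx)
    ky <- seq(-floor(topMargin / ppm), floor((H - topMargin) / ppm))
    ys <- round(topMargin + ppm * ky)
    vIdx <- function(x) cbind(rep(seq_len(H), length(x)), rep(x, each = H))
    hIdx <- function(y) cbind(rep(y, each = W), rep(seq_len(W), length(y)))
    inW <- function(v) v[v >= 1 & v <= W]; inH <- function(v) v[v >= 1 & v <= H]
    pixels <- .paint(pixels, rbind(vIdx(inW(xs)), hIdx(inH(ys))), minorCol)
    xm <- xs[kx %% 5L == 0L]; ym <- ys[ky %% 5L == 0L]
    pixels <- .paint(pixels, rbind(vIdx(inW(c(xm, xm + 1L))),
                                   hIdx(inH(c(ym, ym + 1L)))), majorCol)
  }

  ink <- c(0, 0, 0)
  drawTrace <- function(pixels, lead, t0, t1, xStart, y0) {
    i0 <- max(1L, floor(t0 * fs) + 1L)
    i1 <- min(nrow(m), ceiling(t1 * fs))
    tt <- (seq(i0, i1) - 1L) / fs
    sel <- tt >= t0 & tt < t1
    tt <- tt[sel]
    v <- m[seq(i0, i1)[sel], lead]
    xc <- xStart + (tt - t0) * pxPerSec
    yc <- y0 - v * layout@gain * ppm
    .paint(pixels, .polylinePixels(xc, yc, style@traceHalfWidthPx, H, W), ink)
  }
  drawLabel <- function(pixels, lead, xStart, y0) {
    if (style@labelFontPx <= 0) return(pixels)
    ij <- .labelPixels(lead, row0 = y0 + round(0.5 * layout@gain * ppm),
                       col0 = round(xStart) + 5L, fontPx = style@labelFontPx)
    keep <- ij[, 1] >= 1 & ij[, 1] <= H & ij[, 2] >= 1 & ij[, 2] <= W
    .paint(pixels, ij[keep, , drop = FALSE], ink)
  }

  leadTruth <- list()
  for (r in seq_len(layout@rows)) for (cc in seq_len(layout@columns)) {
    lead <- layout@leadGrid[r, cc]
    .assert(lead %in% leadNames(signal), "signal lacks lead %s", lead)
    t0 <- (cc - 1L) * layout@secondsPerColumn
    t1 <- cc * layout@secondsPerColumn
    xStart <- xLeft + (cc - 1L) * colWpx
    y0 <- baseRow(r)
    pixels <- drawLabel(pixels, lead, xStart, y0)
    pixels <- drawTrace(pixels, lead, t0, t1, xStart, y0)
    leadTruth[[lead]] <- list(lead = lead, row = y0, column = cc,
                              x0 = xStart + 1L, x1 = xStart + colWpx, t0 = t0)
  }
  stripTruth <- list()
  if (nStrips > 0) for (s in seq_len(nStrips)) {
    lead <- layout@rhythmLeads[s]
    .assert(lead %in% leadNames(signal), "signal lacks rhythm lead %s", lead)
    y0 <- baseRow(layout@rows + s)
    pixels <- drawLabel(pixels, lead, xLeft, y0)
    pixels <- drawTrace(pixels, lead, 0, min(dur, panelDur), xLeft, y0)
    stripTruth[[s]] <- list(lead = lead, row = y0, x0 = xLeft + 1L,
                            x1 = xLeft + panelW)
  }

  truth <- list(
    pxPerMm = ppm, pxPerSec = pxPerSec, xLeft = xLeft, colWidthPx = colWpx,
    rowPitch = pitch, gain = layout@gain, paperSpeed = layout@paperSpeed,
    secondsPerColumn = layout@secondsPerColumn,
    panelBox = c(top = baseRow(1) - round(pitch / 2), left = xLeft + 1L,
                 bottom = baseRow(layout@rows) + round(pitch / 2),
                 right = xLeft + panelW),
    leads = leadTruth, strips = stripTruth,
    grid = style@grid, colour = style@colour, degraded = FALSE)
  new("RenderedECG", pixels = pixels, truth = truth)
}

## matrix/array <-> EBImage conversion (EBImage stores x = width first)
.toEBI <- function(pixels) {
  if (length(dim(pixels)) == 2L)
    EBImage::Image(t(pixels), colormode = "Grayscale")
  else
    EBImage::Image(aperm(pixels, c(2, 1, 3)), colormode = "Color")
}
.fromEBI <- function(img, colour) {
  d <- EBImage::imageData(img)
  if (colour) aperm(d, c(2, 1, 3)) else t(d)
}

#' Apply simulated scan degradation
#'
#' Emulates print-and-scan artefacts: a small rotation (bilinear, white
#' background), Gaussian blur, and additive pixel noise, clipped to
#' [0, 1]. Output dimensions are unchanged; deterministic given `seed`.
#'
#' @param render a [RenderedECG-class].
#' @param rotation degrees (counter-clockwise).
#' @param blurSd Gaussian blur sigma, px.
#' @param noiseSd additive intensity noise sd (image units in [0, 1]).
#' @param seed integer seed for the noise.
#' @return a degraded [RenderedECG-class]; ground-truth geometry is kept
#'   but flagged `degraded` (a rotation invalidates exact pixel truth).
#' @export
applyScanDegradation <- function(render, rotation = 0, blurSd = 0, noiseSd = 0,
                                 seed = 1) {
  stopifnot(is(render, "RenderedECG"))
  .assert(blurSd >= 0 && noiseSd >= 0, "degradation parameters must be >= 0")
  pixels <- pixelData(render)
  colour <- length(dim(pixels)) == 3L
  d <- dim(pixels)
  if (rotation != 0 || blurSd > 0) {
    img <- .toEBI(pixels)
    if (rotation != 0)
      img <- EBImage::rotate(img, rotation, filter = "bilinear",
                             output.dim = c(d[2], d[1]), bg.col = "white")
    if (blurSd > 0) img <- EBImage::gblur(img, sigma = blurSd)
    pixels <- .fromEBI(img, colour)
  }
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    pixels <- pixels + array(rnorm(length(pixels), sd = noiseSd), dim = d)
  }
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  truth <- render@truth
  if (length(truth))
    truth$degraded <- (rotation != 0 || blurSd > 0 || noiseSd > 0)
  new("RenderedECG", pixels = pixels, truth = truth)
}

#' Crop away the rhythm strips, keeping the panel
#'
#' Returns only the rows x columns panel region. With truth geometry the
#' stored panel box is used; otherwise the panel/strip boundary is found
#' from trace-row projections given the layout. An image without strips
#' is returned unchanged with a message.
#'
#' @param render a [RenderedECG-class].
#' @param layout the [LayoutSpec-class] describing the page.
#' @return a cropped [RenderedECG-class] (truth geometry re-based).
#' @export
cropRhythmStrips <- function(render, layout = layoutSpec()) {
  stopifnot(is(render, "RenderedECG"))
  pixels <- pixelData(render)
  truth <- render@truth
  if (length(truth)) {
    if (length(truth$strips) == 0L) {
      message("no rhythm strips present; returning image unchanged")
      return(render)
    }
    box <- truth$panelBox
  } else {
    gm <- extractTraceGridMasks(render)
    gm$trace <- .removeLabelComponents(.closeMask(gm$trace))
    bl <- .detectBaselineRows(gm$trace)
    if (length(bl) <= layout@rows) {
      message("no rhythm strips detected; returning image unchanged")
      return(render)
    }
    panelBl <- bl[seq_len(layout@rows)]
    halfPitch <- round(mean(diff(bl)) / 2)
    cols <- which(colSums(gm$trace) > 0)
    box <- c(top = max(1L, panelBl[1] - halfPitch), left = min(cols),
             bottom = min(nrow(gm$trace), panelBl[layout@rows] + halfPitch),
             right = max(cols))
  }
  rows <- box["top"]:box["bottom"]; cols <- box["left"]:box["right"]
  pixels <- if (length(dim(pixels)) == 3L) pixels[rows, cols, , drop = FALSE]
            else pixels[rows, cols, drop = FALSE]
  if (length(truth)) {
    shiftR <- box["top"] - 1L; shiftC <- box["left"] - 1L
    truth$leads <- lapply(truth$leads, function(l) {
      l$row <- l$row - shiftR; l$x0 <- l$x0 - shiftC; l$x1 <- l$x1 - shiftC; l
    })
    truth$strips <- list()
    truth$xLeft <- truth$xLeft - shiftC
    truth$panelBox <- c(top = 1L, left = 1L, bottom = length(rows), right = length(cols))
  }
  new("RenderedECG", pixels = unname(pixels), truth = truth)
}

#' Write / read a rendered page as PNG (+ truth sidecar JSON)
#'
#' @param render a [RenderedECG-class].
#' @param path PNG file path; truth geometry, when present, is written to
#'   `truthPath` (default: `path` with a .json extension).
#' @param truthPath optional sidecar path.
#' @export
writeRenderedPng <- function(render, path, truthPath = NULL) {
  png::writePNG(pixelData(render), path)
  if (length(render@truth)) {
    if (is.null(truthPath)) truthPath <- sub("\\.png$", ".json", path)
    jsonlite::write_json(render@truth, truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeRenderedPng
#' @return `readRenderedPng` returns a [RenderedECG-class].
#' @export
readRenderedPng <- function(path, truthPath = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  truth <- list()
  if (is.null(truthPath)) {
    cand <- sub("\\.png$", ".json", path)
    if (file.exists(cand)) truthPath <- cand
  }
  if (!is.null(truthPath) && !is.na(truthPath) && file.exists(truthPath))
    truth <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
  new("RenderedECG", pixels = px, truth = as.list(truth))
}
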