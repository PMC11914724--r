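#' ECGSignal: a multi-lead ECG recording
#'
#' The central signal container: a samples-by-leads matrix in millivolts
#' together with its sampling frequency. Lead columns are named with the
#' standard identifiers (I, II, III, aVR, aVL, aVF, V1-V6); a signal may
#' carry all 12 leads or the 8 linearly independent ones.
#'
#' @slot samples numeric matrix, rows = samples (mV), columns = leads.
#' @slot fs sampling frequency in Hz.
#' @export
setClass("ECGSignal",
  representation(samples = "matrix", fs = "numeric"),
  validity = function(object) {
    s <- object@samples
    if (!is.numeric(s)) return("samples must be numeric")
    if (is.null(colnames(s))) return("samples must have lead names as colnames")
    bad <- setdiff(colnames(s), .LEADS)
    if (length(bad)) return(paste("unknown lead name(s):", paste(bad, collapse = ", ")))
    if (anyDuplicated(colnames(s))) return("duplicated lead names")
    if (!all(is.finite(s))) return("amplitudes must be finite")
    if (!.isScalarNum(object@fs) || object@fs <= 0) return("fs must be a positive scalar")
    TRUE
  })

#' WaveTemplate: per-beat P-QRS-T morphology
#'
#' Each beat is a sum of five Gaussian deflections (P, Q, R, S, T), each
#' with an amplitude (mV), a centre offset within the beat (s) and a
#' width (s, the Gaussian sigma). A 5 x 12 projection matrix scales each
#' wave per lead; only the 8 independent-lead columns are used by the
#' generator (the 4 augmented leads are always derived).
#'
#' @slot amplitude named numeric (P,Q,R,S,T), mV.
#' @slot center named numeric, offset of each wave centre within the beat, s.
#' @slot width named numeric, Gaussian sigma per wave, s (> 0).
#' @slot projection 5 x 12 numeric matrix (waves x leads), dimensionless.
#' @export
setClass("WaveTemplate",
  representation(amplitude = "numeric", center = "numeric",
                 width = "numeric", projection = "matrix"),
  validity = function(object) {
    wv <- c("P", "Q", "R", "S", "T")
    for (sl in c("amplitude", "center", "width")) {
      v <- slot(object, sl)
      if (!identical(names(v), wv)) return(sprintf("%s must be named P,Q,R,S,T", sl))
      if (!all(is.finite(v))) return(sprintf("%s must be finite", sl))
    }
    if (any(object@width <= 0)) return("wave widths must be > 0")
    p <- object@projection
    if (!all(dim(p) == c(5L, 12L))) return("projection must be 5 x 12")
    if (!identical(colnames(p), .LEADS))
      return("projection columns must be the standard 12 leads")
    if (!all(is.finite(p))) return("projection weights must be finite")
    TRUE
  })

#' LayoutSpec: paper-format page geometry
#'
#' Describes how 12 leads are arranged on a paper-format page: a
#' rows x columns panel where each column shows a consecutive time
#' window, plus optional full-duration rhythm strips below.
#'
#' @slot columns,rows integer panel shape (columns * rows == 12).
#' @slot secondsPerColumn seconds of signal per column (default 2.5).
#' @slot rhythmLeads character, 0-3 leads drawn as full-length strips.
#' @slot paperSpeed mm/s (default 25).
#' @slot gain mm/mV (default 10).
#' @slot leadGrid rows x columns character matrix mapping panel cells to leads.
#' @export
setClass("LayoutSpec",
  representation(columns = "integer", rows = "integer",
                 secondsPerColumn = "numeric", rhythmLeads = "character",
                 paperSpeed = "numeric", gain = "numeric", leadGrid = "matrix"),
  validity = function(object) {
    if (object@columns * object@rows != 12L) return("columns * rows must equal 12")
    if (object@secondsPerColumn <= 0) return("secondsPerColumn must be > 0")
    if (object@paperSpeed <= 0 || object@gain <= 0) return("paperSpeed and gain must be > 0")
    g <- object@leadGrid
    if (!all(dim(g) == c(object@rows, object@columns))) return("leadGrid shape mismatch")
    if (!setequal(as.vector(g), .LEADS)) return("leadGrid must contain each of the 12 leads once")
    if (length(object@rhythmLeads) > 3L) return("at most 3 rhythm leads")
    if (!all(object@rhythmLeads %in% .LEADS)) return("rhythmLeads must be standard leads")
    TRUE
  })

#' RenderStyle: raster appearance of a rendered page
#'
#' @slot pageWidth,pageHeight page size in px (default 2200 x 1700).
#' @slot grid logical; draw the background grid.
#' @slot colour logical; RGB page (red grid) vs greyscale page (grey grid).
#' @slot pxPerMm pixels per millimetre (default 8).
#' @slot labelFontPx lead-label glyph height in px (0 disables labels).
#' @slot traceHalfWidthPx half-thickness of the trace polyline in px.
#' @export
setClass("RenderStyle",
  representation(pageWidth = "integer", pageHeight = "integer",
                 grid = "logical", colour = "logical", pxPerMm = "numeric",
                 labelFontPx = "numeric", traceHalfWidthPx = "integer"),
  validity = function(object) {
    if (object@pxPerMm <= 0) return("pxPerMm must be > 0")
    if (object@pageWidth < 1L || object@pageHeight < 1L) return("page size must be positive")
    if (object@traceHalfWidthPx < 0L) return("traceHalfWidthPx must be >= 0")
    TRUE
  })

#' RenderedECG: a rasterized ECG page
#'
#' Pixel values are in [0, 1]; `pixels` is H x W (greyscale) or
#' H x W x 3 (colour), origin top-left, y increasing downward. For
#' synthetic renders, `truth` retains the ground-truth geometry
#' (per-lead baseline rows, column windows, px scaling) used as the
#' oracle in round-trip tests; it is absent for foreign images.
#'
#' @slot pixels numeric matrix or 3-d array in [0, 1].
#' @slot truth list of ground-truth geometry, or empty list.
#' @export
setClass("RenderedECG",
  representation(pixels = "array", truth = "list"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (!(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
      return("pixels must be H x W or H x W x 3")
    r <- range(object@pixels)
    if (!all(is.finite(r)) || r[1] < 0 || r[2] > 1)
      return("pixel values must be finite and in [0, 1]")
    TRUE
  })

#' GridCalibration: pixel-to-physical scaling of a paper ECG
#'
#' One small grid box is 1 mm: 0.04 s at 25 mm/s paper speed and 0.1 mV
#' at 10 mm/mV gain. `secondsPerPx = 1 / (paperSpeed * pxPerMmX)` and
#' `mvPerPx = 1 / (gain * pxPerMmY)`. When no grid is detected the
#' calibration is derived from the declared layout instead and
#' `gridDetected` is FALSE.
#'
#' @slot pxPerMmX,pxPerMmY estimated pixels per mm along x and y.
#' @slot secondsPerPx,mvPerPx physical scale per pixel.
#' @slot gridDetected logical.
#' @export
setClass("GridCalibration",
  representation(pxPerMmX = "numeric", pxPerMmY = "numeric",
                 secondsPerPx = "numeric", mvPerPx = "numeric",
                 gridDetected = "logical"),
  validity = function(object) {
    v <- c(object@pxPerMmX, object@pxPerMmY, object@secondsPerPx, object@mvPerPx)
    if (!all(is.finite(v)) || any(v <= 0)) return("all scale factors must be > 0")
    TRUE
  })

#' DigitizedECG: signals recovered from a paper-format image
#'
#' 12 leads at 400 Hz spanning the full 10-s frame. The validity mask
#' distinguishes, per sample, how the value arose: 0 = zero-padded
#' (outside the lead's panel window), 1 = extracted from trace pixels,
#' 2 = interpolated across missing pixel columns.
#'
#' @slot samples numeric matrix (frame samples x 12 leads), mV.
#' @slot mask integer matrix, same shape, values in {0, 1, 2}.
#' @slot fs sampling frequency, Hz (400).
#' @slot calibration the [GridCalibration] used.
#' @slot quality list: gridDetected flag, per-lead missing fraction, warnings.
#' @export
setClass("DigitizedECG",
  representation(samples = "matrix", mask = "matrix", fs = "numeric",
                 calibration = "GridCalibration", quality = "list"),
  validity = function(object) {
    if (!identical(dim(object@samples), dim(object@mask)))
      return("samples and mask shapes differ")
    if (!identical(colnames(object@samples), .LEADS))
      return("samples must carry the 12 standard leads")
    if (!all(object@mask %in% 0:2)) return("mask values must be 0, 1 or 2")
    if (!all(is.finite(object@samples))) return("samples must be finite")
    TRUE
  })

#' IntervalGrid: discrete-time survival intervals
#'
#' Ordered boundaries 0 = t0 < t1 < ... < tK in days define K intervals
#' (t_{j-1}, t_j] over which the survival networks output conditional
#' hazards.
#'
#' @slot boundaries numeric vector of K + 1 boundaries, first element 0.
#' @export
setClass("IntervalGrid",
  representation(boundaries = "numeric"),
  validity = function(object) {
    b <- object@boundaries
    if (length(b) < 2L) return("need at least one interval")
    if (b[1] != 0) return("first boundary must be 0")
    if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
    TRUE
  })

#' SurvivalModel: a discrete-time survival convolutional network
#'
#' A small convolutional network (1D residual over a 4096 x 8 signal
#' tensor, or 2D over a normalized image raster) whose K-unit sigmoid
#' head emits per-interval conditional hazards. Weights live in
#' `layers`; `config` records architecture, input shape and seed;
#' `history` records training curves when fitted.
#'
#' @slot layers list of layer parameter lists.
#' @slot config list (architecture tag, input shape, K, seed, optimizer).
#' @slot grid the [IntervalGrid] the head is trained against.
#' @slot history list with per-epoch train/validation loss when trained.
#' @export
setClass("SurvivalModel",
  representation(layers = "list", config = "list",
                 grid = "IntervalGrid", history = "list"),
  validity = function(object) {
    if (is.null(object@config$K) || object@config$K < 1L) return("config$K must be >= 1")
    if (object@config$K != length(object@grid@boundaries) - 1L)
      return("head size K must match the interval grid")
    TRUE
  })
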