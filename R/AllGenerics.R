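#' @rdname ECGSignal-class
#' @param object,x an object.
#' @export
setGeneric("sampleMatrix", function(x) standardGeneric("sampleMatrix"))
#' @rdname ECGSignal-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname ECGSignal-class
#' @export
setGeneric("leadNames", function(x) standardGeneric("leadNames"))
#' @rdname ECGSignal-class
#' @export
setGeneric("signalDuration", function(x) standardGeneric("signalDuration"))

#' @rdname ECGSignal-class
#' @export
setMethod("sampleMatrix", "ECGSignal", function(x) x@samples)
#' @rdname ECGSignal-class
#' @export
setMethod("samplingRate", "ECGSignal", function(x) x@fs)
#' @rdname ECGSignal-class
#' @export
setMethod("leadNames", "ECGSignal", function(x) colnames(x@samples))
#' @rdname ECGSignal-class
#' @export
setMethod("signalDuration", "ECGSignal", function(x) nrow(x@samples) / x@fs)

setMethod("show", "ECGSignal", function(object) {
  cat(sprintf("ECGSignal: %d leads x %d samples @ %g Hz (%.3g s)\n",
              ncol(object@samples), nrow(object@samples), object@fs,
              signalDuration(object)))
  cat("  leads:", paste(leadNames(object), collapse = " "), "\n")
})

#' @rdname DigitizedECG-class
#' @export
setMethod("sampleMatrix", "DigitizedECG", function(x) x@samples)
#' @rdname DigitizedECG-class
#' @export
setMethod("samplingRate", "DigitizedECG", function(x) x@fs)
#' @rdname DigitizedECG-class
#' @export
setMethod("leadNames", "DigitizedECG", function(x) colnames(x@samples))

#' Per-sample validity mask of a digitized ECG
#'
#' @param x a [DigitizedECG-class].
#' @return integer matrix: 0 = zero-padded, 1 = extracted, 2 = interpolated.
#' @export
setGeneric("validityMask", function(x) standardGeneric("validityMask"))
#' @rdname validityMask
#' @export
setMethod("validityMask", "DigitizedECG", function(x) x@mask)

#' Calibration of a digitized ECG
#' @param x a [DigitizedECG-class].
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname calibration
#' @export
setMethod("calibration", "DigitizedECG", function(x) x@calibration)

setMethod("show", "DigitizedECG", function(object) {
  miss <- signif(object@quality$missingFraction, 2)
  cat(sprintf("DigitizedECG: 12 leads x %d samples @ %g Hz; grid %s\n",
              nrow(object@samples), object@fs,
              if (isTRUE(object@calibration@gridDetected)) "detected" else "not detected"))
  cat("  mean missing-column fraction:", signif(mean(miss), 3), "\n")
})

#' Pixel raster of a rendered page
#' @param x a [RenderedECG-class].
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname pixelData
#' @export
setMethod("pixelData", "RenderedECG", function(x) x@pixels)

#' Ground-truth geometry of a synthetic render
#'
#' @param x a [RenderedECG-class].
#' @return list of geometry (baseline rows, column windows, px scaling),
#'   or an empty list for images without retained truth.
#' @export
setGeneric("renderTruth", function(x) standardGeneric("renderTruth"))
#' @rdname renderTruth
#' @export
setMethod("renderTruth", "RenderedECG", function(x) x@truth)

setMethod("show", "RenderedECG", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RenderedECG: %d x %d px (%s)%s\n", d[1], d[2],
              if (length(d) == 3L) "colour" else "greyscale",
              if (length(object@truth)) ", with truth geometry" else ""))
})

#' Interval boundaries of a discrete-time grid
#' @param x an [IntervalGrid-class].
#' @export
setGeneric("intervalBoundaries", function(x) standardGeneric("intervalBoundaries"))
#' @rdname intervalBoundaries
#' @export
setMethod("intervalBoundaries", "IntervalGrid", function(x) x@boundaries)

#' Number of intervals
#' @param x an [IntervalGrid-class].
#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))
#' @rdname nIntervals
#' @export
setMethod("nIntervals", "IntervalGrid", function(x) length(x@boundaries) - 1L)

setMethod("show", "IntervalGrid", function(object) {
  b <- object@boundaries
  cat(sprintf("IntervalGrid: %d intervals over (0, %g] days\n", length(b) - 1L, max(b)))
})

setMethod("show", "SurvivalModel", function(object) {
  cf <- object@config
  np <- sum(vapply(object@layers, function(l) {
    sum(vapply(l[names(l) %in% c("W", "b", "W1", "b1", "W2", "b2", "Ws", "bs")],
               length, integer(1)))
  }, numeric(1)))
  cat(sprintf("SurvivalModel <%s>: K = %d hazards, %d parameters%s\n",
              cf$architecture, cf$K, as.integer(np),
              if (length(object@history)) sprintf(", trained %d epochs",
                                                  length(object@history$valLoss)) else " (untrained)"))
})
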