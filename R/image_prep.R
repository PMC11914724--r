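## Image-side preprocessing for the 2D route: black-and-white conversion,
## exact-dimension area-interpolated resizing over an 11-step resolution
## ladder, and normalized model-input assembly (ink bright on dark).

#' Convert a rendered page to greyscale
#'
#' Luminance conversion (Rec. 601). A red calibration grid maps to a
#' light grey, well above the near-black trace, so the trace remains the
#' darkest structure. Already-greyscale input is returned unchanged.
#'
#' @param render a [RenderedECG-class] (or pixel matrix/array).
#' @return a greyscale [RenderedECG-class] (or matrix, matching input).
#' @export
toBlackWhite <- function(render) {
  if (is(render, "RenderedECG")) {
    if (length(dim(render@pixels)) == 2L) return(render)
    truth <- render@truth
    if (length(truth)) truth$colour <- FALSE
    return(new("RenderedECG", pixels = .luminance(render@pixels), truth = truth))
  }
  .luminance(render)
}

## separable area-interpolation weight matrix mapping nIn pixels to nOut:
## output pixel i averages input over [ (i-1)*nIn/nOut, i*nIn/nOut )
.areaWeights <- function(nOut, nIn) {
  Wm <- matrix(0, nOut, nIn)
  scale <- nIn / nOut
  for (i in seq_len(nOut)) {
    a <- (i - 1) * scale; b <- i * scale
    j0 <- floor(a) + 1L; j1 <- ceiling(b)
    for (j in j0:min(j1, nIn)) {
      lo <- max(a, j - 1); hi <- min(b, j)
      if (hi > lo) Wm[i, j] <- hi - lo
    }
  }
  Wm / scale
}

#' Resize an image to exact target dimensions
#'
#' Area interpolation: each output pixel is the average of the input
#' region it covers (computed separably), so downsizing is anti-aliased
#' and resizing to 1 x 1 yields the mean intensity.
#'
#' @param image numeric matrix (greyscale), 3-channel array, or a
#'   [RenderedECG-class].
#' @param target integer c(height, width), both >= 1.
#' @return the resized image, same type as the input (a RenderedECG
#'   loses its truth geometry, which no longer applies).
#' @export
resizeImage <- function(image, target) {
  .assert(length(target) == 2L && all(target >= 1), "target must be c(height, width) >= 1")
  if (is(image, "RenderedECG"))
    return(new("RenderedECG", pixels = resizeImage(pixelData(image), target),
               truth = list()))
  d <- dim(image)
  if (d[1] == target[1] && d[2] == target[2]) return(image)
  Wr <- .areaWeights(target[1], d[1])
  Wc <- .areaWeights(target[2], d[2])
  if (length(d) == 2L) return(Wr %*% image %*% t(Wc))
  out <- array(0, c(target, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Wr %*% image[, , ch] %*% t(Wc)
  out
}

#' The 11-step input-resolution ladder
#'
#' Eleven (height, width) pairs from 1 x 1 up to 310 x 868, passing
#' through 27 x 76, with intermediate entries geometrically interpolated
#' between those anchors. Pixel counts are strictly increasing.
#'
#' @return integer matrix, 11 rows x 2 columns (height, width).
#' @export
resolutionLadder <- function() {
  geomSeq <- function(from, to, n)
    round(exp(seq(log(from), log(to), length.out = n)))
  h <- c(geomSeq(1, 27, 6), geomSeq(27, 310, 6)[-1])
  w <- c(geomSeq(1, 76, 6), geomSeq(76, 868, 6)[-1])
  out <- cbind(height = as.integer(h), width = as.integer(w))
  stopifnot(nrow(out) == 11L, all(diff(out[, 1] * out[, 2]) > 0))
  out
}

#' Assemble a normalized 2D model input
#'
#' Greyscale conversion, optional rhythm-strip cropping, resizing to the
#' target resolution, then inversion and scaling to [0, 1] so ink is
#' bright (~1) on a dark background -- small networks train more stably
#' when the informative pixels carry the large activations.
#'
#' @param render a [RenderedECG-class].
#' @param target c(height, width); default 310 x 868.
#' @param layout layout used to locate rhythm strips when cropping.
#' @param cropStrips drop the rhythm strips before resizing.
#' @return numeric matrix (height x width) in [0, 1].
#' @export
prepareModelInput2D <- function(render, target = c(310L, 868L),
                                layout = layoutSpec(), cropStrips = TRUE) {
  stopifnot(is(render, "RenderedECG"))
  if (cropStrips) render <- suppressMessages(cropRhythmStrips(render, layout))
  bw <- pixelData(toBlackWhite(render))
  img <- resizeImage(bw, target)
  img <- 1 - img
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  img
}
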