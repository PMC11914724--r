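#' @import methods
#' @importFrom stats approx spline median quantile rbinom rnorm runif rexp sd cor setNames
#' @importFrom utils head tail read.csv write.csv
NULL

## Standard 12-lead order used throughout the package.
.LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
            "V1", "V2", "V3", "V4", "V5", "V6")

## The 8 linearly independent leads; III, aVR, aVL, aVF are linear
## combinations of I and II (Einthoven/Goldberger) and are always derived.
.INDEP_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Standard lead names
#'
#' @return Character vector of the 12 standard lead names, or the 8
#'   linearly independent leads (I, II, V1-V6) when `independent = TRUE`.
#' @param independent logical; return only the independent leads.
#' @export
ecgLeadNames <- function(independent = FALSE) {
  if (independent) .INDEP_LEADS else .LEADS
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

## next power of two >= n
.nextPow2 <- function(n) {
  .assert(n >= 1, "need a positive length, got %s", n)
  2L^ceiling(log2(n))
}

## Deterministic child seeds: derive k sub-seeds from one master seed so
## independent stages don't share streams. Kept below 2^31.
.childSeeds <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * seq_len(k) %% 2147483629L
}

.isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
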