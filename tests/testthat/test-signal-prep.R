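makeSine <- function(freq, fs = 500, duration = 20) {
  t <- (seq_len(fs * duration) - 1) / fs
  m <- matrix(sin(2 * pi * freq * t), ncol = 1, dimnames = list(NULL, "I"))
  new("ECGSignal", samples = m, fs = fs)
}

rmsMid <- function(x) {           # RMS away from filter edges
  n <- length(x)
  sqrt(mean(x[round(n * 0.25):round(n * 0.75)]^2))
}

test_that("10-s input at 500 Hz resamples to 4000 samples at 400 Hz", {
  out <- filterResample(generateEcg(fs = 500, duration = 10, seed = 1))
  expect_identical(nrow(sampleMatrix(out)), 4000L)
  expect_equal(samplingRate(out), 400)
})

test_that("a 0.05 Hz drift is attenuated by at least 20 dB", {
  out <- filterResample(makeSine(0.05))
  att <- 20 * log10(rmsMid(sampleMatrix(out)[, 1]) / (1 / sqrt(2)))
  expect_lt(att, -20)
})

test_that("a 10 Hz sinusoid passes within 1 dB", {
  out <- filterResample(makeSine(10))
  att <- 20 * log10(rmsMid(sampleMatrix(out)[, 1]) / (1 / sqrt(2)))
  expect_lt(abs(att), 1)
})

test_that("the 60 Hz notch removes powerline interference", {
  out <- filterResample(makeSine(60))
  att <- 20 * log10(rmsMid(sampleMatrix(out)[, 1]) / (1 / sqrt(2)))
  expect_lt(att, -20)
})

test_that("non-finite samples are rejected", {
  s <- makeSine(10, duration = 1)
  s@samples[5, 1] <- NA
  expect_error(filterResample(s), "finite")
})

test_that("filterResample is linear within numeric tolerance", {
  a <- makeSine(7, duration = 5)
  b <- makeSine(23, duration = 5)
  combo <- new("ECGSignal", samples = 2 * a@samples - 3 * b@samples, fs = 500)
  fa <- sampleMatrix(filterResample(a))
  fb <- sampleMatrix(filterResample(b))
  fc <- sampleMatrix(filterResample(combo))
  expect_equal(fc, 2 * fa - 3 * fb, tolerance = 1e-8)
})

test_that("power-of-two padding is symmetric: 4000 -> 4096 with 48 each side", {
  sig <- filterResample(generateEcg(fs = 500, duration = 10, seed = 2))
  padded <- padPowerOfTwo(sig)
  m <- sampleMatrix(padded)
  expect_identical(nrow(m), 4096L)
  expect_true(all(m[1:48, ] == 0))
  expect_true(all(m[4049:4096, ] == 0))
  expect_equal(m[49:4048, ], sampleMatrix(sig), ignore_attr = TRUE)
})

test_that("padding edge cases: power-of-two input unchanged, 1000 -> 1024", {
  m <- matrix(rnorm(4096), ncol = 1, dimnames = list(NULL, "I"))
  s <- new("ECGSignal", samples = m, fs = 400)
  expect_identical(sampleMatrix(padPowerOfTwo(s)), m)
  m2 <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "II"))
  p2 <- sampleMatrix(padPowerOfTwo(new("ECGSignal", samples = m2, fs = 400)))
  expect_identical(nrow(p2), 1024L)
  expect_true(all(p2[1:12, ] == 0) && all(p2[1013:1024, ] == 0))
})

test_that("independent-lead selection drops the derived leads in order", {
  ecg <- generateEcg(seed = 3)
  s8 <- selectIndependentLeads(ecg)
  expect_identical(leadNames(s8), c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
  expect_error(selectIndependentLeads(s8), "III")
  # the dropped leads are recoverable exactly from I and II
  aug <- deriveAugmentedLeads(sampleMatrix(s8)[, "I"], sampleMatrix(s8)[, "II"])
  expect_equal(aug$aVF, sampleMatrix(ecg)[, "aVF"])
  expect_equal(aug$III, sampleMatrix(ecg)[, "III"])
})

test_that("asynchronous masking keeps each lead only in its column window", {
  sig <- filterResample(generateEcg(seed = 4))
  masked <- applyAsyncMask(sig, layoutSpec())
  m <- sampleMatrix(masked)
  # lead I: column 1 -> samples 1..1000; V6: column 4 -> samples 3001..4000
  expect_true(all(m[1001:4000, "I"] == 0))
  expect_true(any(m[1:1000, "I"] != 0))
  expect_true(all(m[1:3000, "V6"] == 0))
  expect_true(any(m[3001:4000, "V6"] != 0))
  # column windows partition the frame: each lead non-zero in one quarter
  lay <- layoutSpec()
  for (r in 1:3) {
    leads <- lay@leadGrid[r, ]
    nz <- lapply(leads, function(ld) which(m[, ld] != 0))
    expect_identical(sort(unique(unlist(nz))), 1:4000)
    expect_true(all(diff(sapply(nz, min)) == 1000))
  }
})

test_that("model-input assembly yields the 4096 x 8 tensor", {
  x <- prepareModelInput1D(generateEcg(seed = 5))
  expect_identical(dim(x), c(4096L, 8L))
  expect_identical(attr(x, "format"), "synchronous")
  xa <- prepareModelInput1D(generateEcg(seed = 5), asynchronous = TRUE)
  expect_identical(attr(xa, "format"), "asynchronous")
  # async: lead V6 energy confined to its shifted window (offset 48 by padding)
  expect_true(all(xa[1:(3000 + 48), "V6"] == 0))
})
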