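test_that("trace mask recovers the drawn trace with few errors", {
  page <- fixturePage()
  masks <- extractTraceGridMasks(page)
  # reference trace mask: re-render the same signal without grid; its dark
  # pixels are exactly the drawn trace + labels
  truthInk <- pixelData(fixturePageNoGrid())[, , 1] < 0.5
  expect_gt(sum(masks$trace & truthInk) / sum(truthInk), 0.95)
  expect_lt(sum(masks$trace & !truthInk) / sum(masks$trace), 0.05)
})

test_that("grid-off pages yield an empty grid mask and fallback calibration", {
  masks <- extractTraceGridMasks(fixturePageNoGrid())
  expect_false(any(masks$grid))
  dig <- digitizeEcg(fixturePageNoGrid(), smallLayout())
  expect_false(calibration(dig)@gridDetected)
  # layout fallback still recovers the px/mm scale from the panel extent
  expect_equal(calibration(dig)@pxPerMmX, 6, tolerance = 0.02)
})

test_that("an all-white page gives empty masks and a warning", {
  blank <- new("RenderedECG", pixels = matrix(1, 200, 300), truth = list())
  expect_warning(masks <- extractTraceGridMasks(blank), "blank")
  expect_false(any(masks$trace))
  expect_false(any(masks$grid))
  expect_error(suppressWarnings(digitizeEcg(blank)), "blank")
})

test_that("grid calibration estimates px/mm within 2%, integer or not", {
  ecg <- fixtureEcg()
  for (ppm in c(10, 6.5)) {
    st <- renderStyle(pageWidth = as.integer(ceiling(250 * ppm) + 120),
                      pageHeight = 1100L, grid = TRUE, colour = TRUE,
                      pxPerMm = ppm)
    page <- renderPaperEcg(ecg, smallLayout(), st)
    cal <- calibrateGrid(page, smallLayout())
    expect_true(cal@gridDetected)
    expect_lt(abs(cal@pxPerMmX - ppm) / ppm, 0.02)
    expect_lt(abs(cal@pxPerMmY - ppm) / ppm, 0.02)
    expect_equal(cal@secondsPerPx, 1 / (25 * cal@pxPerMmX))
    expect_equal(cal@mvPerPx, 1 / (10 * cal@pxPerMmY))
  }
})

test_that("flat-line extraction returns zeros within half a pixel", {
  tpl <- waveTemplate(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  flat <- generateEcg(tpl, fs = 500, duration = 10, noiseSd = 0, seed = 2)
  page <- renderPaperEcg(flat, smallLayout(), smallStyle())
  masks <- extractTraceGridMasks(page)
  trace <- ecgrisk:::.removeLabelComponents(masks$trace)
  cal <- calibrateGrid(masks$grid, smallLayout(), trace)
  lt <- renderTruth(page)$leads[["V3"]]
  roi <- (masks$darkness * trace)[(lt$row - 40):(lt$row + 40), lt$x0:lt$x1]
  ext <- extractLeadSignal(roi, cal)
  expect_true(all(abs(ext$samples) <= 0.5 * cal@mvPerPx))
  expect_false(any(ext$missing))
})

test_that("a rendered 1 mV step is recovered within 0.05 mV", {
  # half the window at 0 mV, half at 1 mV
  n <- 5000
  m <- matrix(0, n, 12, dimnames = list(NULL, ecgLeadNames()))
  m[, ] <- rep(c(0, 1), each = n / 2)
  sig <- new("ECGSignal", samples = m, fs = 500)
  page <- renderPaperEcg(sig, smallLayout(), smallStyle())
  masks <- extractTraceGridMasks(page)
  trace <- ecgrisk:::.removeLabelComponents(masks$trace)
  cal <- calibrateGrid(masks$grid, smallLayout(), trace)
  lt <- renderTruth(page)$leads[["V1"]]   # column 3: fully at 1 mV
  roi <- (masks$darkness * trace)[(lt$row - 80):(lt$row + 80), lt$x0:lt$x1]
  ext <- extractLeadSignal(roi, cal, baselineRow = 81)
  expect_lt(abs(median(ext$samples, na.rm = TRUE) - 1), 0.05)
})

test_that("occluded columns are flagged missing and interpolated", {
  page <- fixturePage()
  px <- pixelData(page)
  lt <- renderTruth(page)$leads[["II"]]
  holeCols <- lt$x0 + 200:204
  px[(lt$row - 60):(lt$row + 60), holeCols, ] <- 1   # punch a 5-column gap
  holed <- new("RenderedECG", pixels = px, truth = page@truth)
  masks <- extractTraceGridMasks(holed)
  trace <- ecgrisk:::.removeLabelComponents(masks$trace)
  cal <- calibrateGrid(masks$grid, smallLayout(), trace)
  roi <- (masks$darkness * trace)[(lt$row - 100):(lt$row + 100), lt$x0:lt$x1]
  ext <- extractLeadSignal(roi, cal)
  expect_identical(which(ext$missing), as.integer(201:205))
  dig <- digitizeEcg(holed, smallLayout())
  expect_true(any(validityMask(dig)[, "II"] == 2L))
  expect_gt(dig@quality$missingFraction[["II"]], 0)
})

test_that("a mostly-empty ROI raises an unreadable-ROI error", {
  roi <- matrix(0, 50, 100)
  roi[25, 1:30] <- 1
  cal <- new("GridCalibration", pxPerMmX = 6, pxPerMmY = 6,
             secondsPerPx = 1 / 150, mvPerPx = 1 / 60, gridDetected = TRUE)
  expect_error(extractLeadSignal(roi, cal), "unreadable")
})

test_that("digitized leads occupy exactly their column windows", {
  dig <- fixtureDigitized()
  msk <- validityMask(dig)
  lay <- smallLayout()
  for (lead in c("I", "aVL", "V2", "V6")) {
    col <- which(lay@leadGrid == lead, arr.ind = TRUE)[1, "col"]
    win <- ((col - 1) * 1000 + 1):(col * 1000)
    expect_true(all(msk[win, lead] > 0))
    expect_true(all(msk[-win, lead] == 0L))
    expect_true(all(sampleMatrix(dig)[-win, lead] == 0))
  }
})

test_that("round-trip fidelity holds on the small-page fixture", {
  fm <- fidelityMetrics(fixtureReference(), fixtureDigitized())
  expect_gt(median(fm$r), 0.98)
  expect_lt(mean(fm$mae), 0.02)   # reduced 6 px/mm page; full page is finer
})

test_that("digitization tolerates mild scan degradation", {
  page <- applyScanDegradation(fixturePage(), rotation = 0, blurSd = 0.8,
                               noiseSd = 0.01, seed = 4)
  dig <- digitizeEcg(page, smallLayout())
  fm <- fidelityMetrics(fixtureReference(), dig)
  clean <- fidelityMetrics(fixtureReference(), fixtureDigitized())
  expect_gt(median(fm$r), median(clean$r) - 0.05)
})

test_that("digitized CSV export writes samples, mask and quality report", {
  dig <- fixtureDigitized()
  p <- file.path(tempdir(), "dig.csv")
  writeDigitizedCsv(dig, p)
  expect_true(file.exists(p))
  expect_true(file.exists(paste0(p, ".mask.csv")))
  q <- jsonlite::read_json(paste0(p, ".quality.json"))
  expect_true(q$gridDetected)
})
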