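test_that("default style renders a 2200 x 1700 px page", {
  ecg <- generateEcg(seed = 11, duration = 10)
  page <- renderPaperEcg(ecg)   # default layout + style
  expect_identical(dim(pixelData(page))[1:2], c(1700L, 2200L))
})

test_that("a flat-line signal renders at the truth baseline rows", {
  tpl <- waveTemplate(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  flat <- generateEcg(tpl, fs = 500, duration = 10, noiseSd = 0, seed = 1)
  page <- renderPaperEcg(flat, smallLayout(), smallStyle(grid = FALSE))
  px <- pixelData(page)
  for (lt in renderTruth(page)$leads) {
    seg <- px[lt$row, lt$x0:lt$x1, 1]
    expect_true(all(seg == 0))   # ink along the whole baseline
  }
})

test_that("a 1 mV offset sits gain * pxPerMm pixels above the baseline", {
  tpl <- waveTemplate(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  flat <- generateEcg(tpl, fs = 500, duration = 10, noiseSd = 0, seed = 1)
  m <- sampleMatrix(flat) + 1   # constant 1 mV on every lead
  shifted <- new("ECGSignal", samples = m, fs = 500)
  st <- smallStyle(grid = FALSE)
  page <- renderPaperEcg(shifted, smallLayout(), st)
  px <- pixelData(page)
  lt <- renderTruth(page)$leads[["II"]]
  expected <- lt$row - smallLayout()@gain * st@pxPerMm
  expect_true(all(px[expected, lt$x0:lt$x1, 1] == 0))
  expect_true(all(px[lt$row, lt$x0:lt$x1, 1] == 1))  # baseline now blank
})

test_that("the grid changes only background pixels, never trace pixels", {
  on <- pixelData(fixturePage())
  off <- pixelData(fixturePageNoGrid())
  traceOn <- on[, , 1] < 0.5 & on[, , 2] < 0.5 & on[, , 3] < 0.5
  traceOff <- off[, , 1] < 0.5 & off[, , 2] < 0.5 & off[, , 3] < 0.5
  expect_identical(traceOn, traceOff)
})

test_that("scan degradation is the identity at zero parameters and seeded", {
  page <- fixturePage()
  same <- applyScanDegradation(page, 0, 0, 0)
  expect_identical(pixelData(same), pixelData(page))
  d1 <- applyScanDegradation(page, rotation = 0.5, blurSd = 1, noiseSd = 0.02,
                             seed = 9)
  d2 <- applyScanDegradation(page, rotation = 0.5, blurSd = 1, noiseSd = 0.02,
                             seed = 9)
  expect_identical(pixelData(d1), pixelData(d2))
  expect_false(identical(pixelData(d1), pixelData(page)))
  expect_identical(dim(pixelData(d1)), dim(pixelData(page)))
  expect_true(all(pixelData(d1) >= 0 & pixelData(d1) <= 1))
})

test_that("rhythm-strip cropping keeps exactly the panel box", {
  ecg <- fixtureEcg()
  lay <- smallLayout(rhythmLeads = c("II", "V1", "V5"))
  page <- renderPaperEcg(ecg, lay, smallStyle())
  cropped <- cropRhythmStrips(page, lay)
  expect_lt(nrow(pixelData(cropped)), nrow(pixelData(page)))
  box <- renderTruth(page)$panelBox
  expect_equal(nrow(pixelData(cropped)), unname(box["bottom"] - box["top"] + 1L),
               tolerance = 2)
  # no strip baseline survives inside the crop
  stripRows <- sapply(renderTruth(page)$strips, `[[`, "row")
  expect_true(all(stripRows > box["bottom"]))
  # strip-free image is a no-op
  noStrips <- fixturePage()
  expect_message(out <- cropRhythmStrips(noStrips, smallLayout()), "unchanged")
  expect_identical(pixelData(out), pixelData(noStrips))
})

test_that("PNG round trip preserves pixels and truth geometry", {
  page <- fixturePage()
  p <- file.path(tempdir(), "page.png")
  writeRenderedPng(page, p)
  back <- readRenderedPng(p)
  expect_equal(pixelData(back), pixelData(page), tolerance = 1 / 255)
  expect_equal(renderTruth(back)$pxPerMm, renderTruth(page)$pxPerMm)
  expect_equal(renderTruth(back)$leads$II$row, renderTruth(page)$leads$II$row)
})

test_that("layout and style constructors validate their geometry", {
  expect_error(layoutSpec(columns = 5L, rows = 3L), "equal 12")
  expect_error(renderPaperEcg(generateEcg(duration = 5, seed = 1)), "duration")
  expect_error(renderStyle(pxPerMm = -1), "pxPerMm")
})
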