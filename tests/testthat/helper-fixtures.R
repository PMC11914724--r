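# Shared fixtures, built once per test run. Renders use a reduced page
# (6 px/mm, no rhythm strips) so unit tests stay fast; full-page
# (2200 x 1700, 8 px/mm) geometry is exercised in the acceptance suite.

smallLayout <- function(rhythmLeads = character(0))
  layoutSpec(rhythmLeads = rhythmLeads)

smallStyle <- function(grid = TRUE, colour = TRUE, pxPerMm = 6)
  renderStyle(pageWidth = 1650L, pageHeight = 1000L, grid = grid,
              colour = colour, pxPerMm = pxPerMm)

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

fixtureEcg <- function() cached("ecg", generateEcg(heartRate = 72, fs = 500,
                                                   duration = 10, noiseSd = 0.02,
                                                   seed = 101))

fixturePage <- function() cached("page",
  renderPaperEcg(fixtureEcg(), smallLayout(), smallStyle()))

fixturePageNoGrid <- function() cached("pageNoGrid",
  renderPaperEcg(fixtureEcg(), smallLayout(), smallStyle(grid = FALSE)))

fixtureDigitized <- function() cached("dig",
  digitizeEcg(fixturePage(), smallLayout()))

fixtureReference <- function() cached("ref", filterResample(fixtureEcg()))

# brute-force O(n^2) pair-enumeration concordance oracle (kept deliberately
# independent of the package's vectorized implementation)
bruteForceC <- function(risk, time, event) {
  conc <- 0; ties <- 0; np <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      np <- np + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) ties <- ties + 1
    }
  }
  (conc + 0.5 * ties) / np
}
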