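# ecgrisk

Mortality risk from 12-lead ECGs along three routes: natively digital 1D
signals, digitized signals recovered from paper-format ECG images, and
direct 2D image input.

Most of the world's stored ECGs exist only as paper printouts or page
rasters, while most AI-ECG models consume calibrated digital waveforms.
`ecgrisk` is a desk-scale toolkit for studying that gap. It provides:

- a **synthetic ECG generator**: sum-of-Gaussians P-QRS-T beats on the 8
  independent leads (the augmented limb leads III, aVR, aVL, aVF are the
  exact linear combinations III = II − I, aVR = −(I+II)/2, aVL = I − II/2,
  aVF = II − I/2), with survival outcomes linked to the waveform through a
  discrete-time hazard;
- a **paper-format renderer**: the standard 4×3 layout (2.5 s per column,
  25 mm/s, 10 mm/mV, 1 mm grid boxes), optional 10-s rhythm strips,
  colour or greyscale pages at 2200 × 1700 px, plus scan-degradation
  transforms (rotation, blur, noise). Synthetic renders carry ground-truth
  geometry, making the renderer the oracle for digitization tests;
- a **digitization pipeline**: colour/greyscale masks separate trace ink
  from the calibration grid; the grid's small-box pitch gives the
  time/amplitude scale (1 box = 1 mm = 0.04 s / 0.1 mV); lead-name glyphs
  are removed by connected-component filtering; traces are read column by
  column as intensity-weighted centroids, interpolated over gaps,
  band-pass filtered (0.5–100 Hz, 60 Hz notch), resampled to 400 Hz and
  placed at their layout time offsets in a zero-padded 12 × 10-s frame;
- **shared 1D preprocessing**: the same filters, resampling to 400 Hz,
  symmetric power-of-two padding (4000 → 4096 samples, 48 zeros each
  side), independent-lead selection (4096 × 8 input tensor), and the
  asynchronous 2.5-s-per-lead masking that mirrors what a paper page
  actually shows;
- **discrete-time survival networks**: K per-interval conditional hazards
  `h_j` from a sigmoid head, trained with the censoring-aware likelihood
  `−Σ_j m_j [y_j log h_j + (1−y_j) log(1−h_j)]`; survival is
  `S_k = Π_{j≤k}(1−h_j)` and the risk score is the cumulative hazard
  `−Σ_j log(1−h_j)`. A small residual 1D CNN (stem + 3 residual blocks
  over the 4096-sample axis) and a small strided 2D CNN are included,
  with vanilla-gradient saliency maps;
- **evaluation**: per-lead Pearson r and MAE for digitization fidelity,
  Harrell's C-index under censoring with a bootstrap interval, and a
  packaged render→digitize round-trip benchmark.

## Worked example

```r
library(ecgrisk)

## one synthetic 12-lead ECG, rendered and digitized back
ecg  <- generateEcg(heartRate = 72, fs = 500, duration = 10,
                    noiseSd = 0.02, seed = 101)
page <- renderPaperEcg(ecg)                 # 2200 x 1700 px, grid on
dig  <- digitizeEcg(page)
fm   <- fidelityMetrics(filterResample(ecg), dig)
median(fm$r); mean(fm$mae)
#> [1] 0.9935625
#> [1] 0.01152263
```

The source trace is recovered from the page raster with a median per-lead
correlation above 0.99 and a mean absolute error near 0.01 mV — about a
tenth of one small grid box.

```r
## survival discrimination on a synthetic cohort driven by heart rate
grid   <- intervalGrid()                    # 10 half-year intervals
cohort <- generateCohort(cohortConfig(nSubjects = 500, seed = 11), grid)
X      <- sapply(cohort$signals, prepareModelInput1D, simplify = "array")
tgt    <- encodeTargets(cohort$records$time, cohort$records$event, grid)
splits <- prepareCohort(cohort$records, grid, seed = 5)   # 50/10/40
model  <- trainModel(buildModel(netConfig("residual1d", K = 10, seed = 42),
                                grid), X, tgt, splits)
h      <- predictHazards(model, X[, , splits$test])
concordanceIndex(hazardsToSurvival(h)$risk,
                 cohort$records$time[splits$test],
                 cohort$records$event[splits$test], B = 0)
#> C-index 0.7385
```

The held-out C-index of ~0.74 approaches the generator's own oracle
ranking (~0.79), i.e. the network recovers most of the discrimination the
cohort contains.

## Command line

```sh
Rscript inst/scripts/ecgrisk-cli.R simulate  --seed 3 --out run/
Rscript inst/scripts/ecgrisk-cli.R render    --seed 3 --out run/
Rscript inst/scripts/ecgrisk-cli.R digitize  --seed 3 --out run/
Rscript inst/scripts/ecgrisk-cli.R roundtrip --seed 7 --out run/
```

Subcommands share one flat YAML config (`--config run.yaml`) and a global
seed; every run is reproducible from its logged config + seed.

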