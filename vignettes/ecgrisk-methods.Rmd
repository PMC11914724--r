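---
title: "ecgrisk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecgrisk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, numerical choices and open design
decisions behind `ecgrisk`: what the synthetic generator emulates, how
the renderer and digitizer are coupled, how the discrete-time survival
networks are specified and trained, and what the desk-scale tests do and
do not demonstrate about real hospital data.

## The problem

Paper is still the dominant storage format for ECGs, while AI-ECG models
consume calibrated digital waveforms. Three routes connect an ECG to a
mortality-risk estimate: use the natively digital signal; recover
("digitize") the signal from the page raster and feed a 1D model; or
feed the page raster itself to a 2D model. `ecgrisk` implements all
three around a synthetic data source, so the whole
render→digitize→model chain is verifiable end to end on one desk-scale
machine, with the renderer's ground-truth geometry as the oracle.

## Synthetic ECGs and linked survival

Each beat is a sum of five Gaussian deflections (P, Q, R, S, T) with
amplitudes in mV, centre offsets and widths in seconds, repeated at the
RR interval 60/heart-rate and projected per lead by a 5 × 12 weight
matrix (V1 gets an rS override). Only the 8 independent leads are
simulated; III, aVR, aVL, aVF are always derived from the (noisy) leads
I and II, so the Einthoven/Goldberger identities hold exactly by
construction — a property the tests assert at machine precision. A
sum-of-Gaussians model was chosen over a dynamical-system (ODE) model
because the downstream tasks only require that heart rate and QRS width
be controllable and carried into risk; it is also orders of magnitude
faster.

Survival outcomes come from a discrete-time hazard, constant across the
grid's intervals for a given subject:
`h = plogis(qlogis(h0) + bHR·zHR + bQRS·zQRS)`, with covariates
standardized to their uniform sampling ranges. The logistic link keeps
every hazard in (0, 1) by construction. Generator defaults, chosen once
as the package's study conditions: heart rate uniform on 50–110 bpm, QRS
sigma uniform on 8–20 ms, baseline per-interval hazard 0.06 over 10
half-year intervals (≈ 46% five-year event fraction for an average
subject), coefficients 1.2 (heart rate) and 0.5 (QRS width) per SD,
independent uniform censoring with probability 0.25. Under these
conditions the generator's own linear predictor ranks held-out subjects
at a C-index of ≈ 0.79 — the ceiling any model can reach. Subjects
surviving the whole grid are censored at the horizon. The empirical
per-interval hazard of a large cohort is tested against the configured
value within Monte-Carlo error; the event fraction against the
closed-form geometric survival.

The censoring mechanism of real hospital cohorts is unknown to us; the
uniform model here is a stand-in that exercises the likelihood
machinery, not a claim about any clinical data set.

## Rendering

The page model follows the common hospital dialect: a 3 × 4 panel of
2.5-s windows (columns in the standard order I,II,III | aVR,aVL,aVF |
V1–V3 | V4–V6), optional full-length rhythm strips below (defaults II,
V1, V5 — the set is not standardized, so it is configurable), paper
speed 25 mm/s, gain 10 mm/mV, 1 mm minor / 5 mm major grid, default
2200 × 1700 px at 8 px/mm. Image origin is top-left with y increasing
downward; positive millivolts deflect toward smaller row indices. Traces
are drawn as connected polylines with ±1 px vertical thickening; lead
labels are tiny 5 × 3 bitmap glyphs placed below-left of each baseline
(below rather than the vendor-typical above, so tall R waves at window
starts cannot fuse with the glyphs and defeat their removal). Colour
pages use a light-red grid, greyscale pages light grey; the grid is
drawn first and ink last, so grid on/off changes background pixels only
— asserted in the tests. Every synthetic render retains its geometry
(baseline rows, column windows, px/mm) for oracle use; scan degradation
(rotation via bilinear resampling on white, Gaussian blur, additive
noise) flags the retained truth as degraded.

## Digitization

The pipeline is masks → calibration → regions of interest → per-lead
extraction → interpolation → filtering → resampling → frame placement.

* **Masks.** On colour pages trace ink is dark and neutral (all channels
  below 0.7 — generous because the reddish grid keeps a high red channel
  regardless), the grid is "red excess" above background. On greyscale
  pages the split is by intensity band. A 3 × 3 morphological closing
  bridges 1–2 px breaks that blur introduces on steep strokes before
  connected components whose bounding box fits in 80 × 80 px (label
  glyphs, specks) are removed; trace components span whole 2.5-s windows
  and survive.
* **Calibration.** The small-box pitch is estimated from the periodicity
  of the grid mask's row/column projections: clustered peak centres,
  least-squares spacing tolerant of occasional missed lines, ambiguity
  (large residual) reported as failure. One box = 1 mm = 0.04 s at
  25 mm/s and 0.1 mV at 10 mm/mV. Without a usable grid the scale falls
  back to the declared layout: panel pixel extent over its physical
  width, with `gridDetected = FALSE`.
* **Extraction.** Baseline rows are peaks of the trace-mask row
  projection; ROI bands split at midpoints between adjacent baselines,
  which implements "pixels go to the nearer baseline, ties to the upper
  lead" deterministically. Within a column the value is the
  intensity-weighted centroid of trace pixels; when several disconnected
  vertical runs exist the run nearest the previously accepted centroid
  wins. Columns without ink are flagged missing and linearly
  interpolated; a lead with > 50% missing columns is marked invalid.
  The per-lead baseline is the median of accepted centroid rows —
  robust because baseline segments dominate a beat.
* **Time base.** Each window's pixel columns are mapped to
  [0, 2.5 s) through the window width itself (the ROI is by definition
  one column span), with sample times at column centres — the half-pixel
  offset is passed to the resampler, which removed a consistent
  one-sample lag in round trips. Amplitude scaling uses the grid
  calibration.
* **Output.** A 12 × 4000 frame at 400 Hz with a per-sample validity
  mask (0 zero-padded, 1 extracted, 2 interpolated); quality report with
  grid flag and per-lead missing fractions.

## Shared 1D preprocessing

Filtering is a 3rd-order Butterworth band-pass 0.5–100 Hz plus a biquad
notch at 60 Hz (Q = 30), both applied forward-backward for zero phase;
the corner frequencies are the published ones, the order/Q are this
package's choices. Resampling to 400 Hz interpolates the band-limited
signal with a monotone Hermite spline onto the exact output grid: the
natural cubic spline was measured to overshoot on steep QRS strokes of
pixel-rate traces (Runge ringing that the zero-phase filters then smear
over ±60 ms), while the monotone interpolant is overshoot-free; the
band-pass supplies the anti-aliasing a polyphase design would otherwise
provide, and the operator stays linear — a tested property. When the
input rate cannot realize a 100 Hz corner (pixel-rate traces near
200 Hz), interpolation to 400 Hz precedes filtering. Asynchronous
masking zeroes each lead outside its column's [c·2.5, (c+1)·2.5) s
window on the unpadded 4000-sample frame so the window arithmetic is
exact; symmetric zero padding to the next power of two (48 + 4000 + 48)
comes last, and the fixed order filter → resample → mask → lead
selection → pad is itself asserted by the shape tests.

## Discrete-time survival networks

The grid defaults to 10 half-year intervals over 5 years, aligning the
horizon with the 5-year life-status stratification used in cohort
splitting; it is fully configurable. Targets: an event in interval k
sets y_k = 1 with mask m_1..k = 1; censoring in interval k credits only
the k − 1 completed intervals (no half-interval credit — the simplest
likelihood consistent with the encoding; a half-credit variant would be
a one-line change). Events beyond the horizon count as censored at the
last boundary. The loss is the masked Bernoulli likelihood averaged over
records; with one interval and full observation it is exactly binary
cross-entropy. The risk score for ranking is the cumulative hazard
−Σ log(1 − h_j), which orders records identically to 1 − S_K.

Architectures are deliberately desk-scale: the 1D network is a strided
stem convolution (kernel 16, stride 4) and three residual blocks
(kernel 8, stride 4 each; 16→24→32→48 channels, ~57k parameters) over
the 4096 × 8 tensor, global average pooling, and a K-unit sigmoid head;
the 2D network stacks strided residual stages (3 × 3 kernels,
8→16→24→32 channels) over the image. Full-size replicas are a matter of
widening the configuration, not a different code path. All layers are
implemented in base R (im2col + BLAS matrix products) with
backpropagation verified against finite differences in the test suite.

Training: Adam (lr 5 × 10⁻⁴, batch 32) with decoupled weight decay
10⁻³ on weight matrices, head bias initialized at qlogis(0.1) so early
epochs refine discrimination rather than the output scale, up to 60
epochs. Model selection and early stopping (patience 20) use the
validation C-index computed on the interval ranks implied by the
targets, falling back to validation loss when no pairs are comparable;
with a 50-subject validation split, loss-based selection was measurably
noisier across initialization seeds. The label-shuffled control in the
acceptance suite confirms the pipeline cannot manufacture discrimination
from nothing.

Cohort utilities drop records censored before day 30 (no 30-day life
status), then split subjects 50/10/40 into train/validation/test,
stratified by availability of 5-year status (an event at any time or
follow-up reaching the grid horizon), with every subject confined to one
split. With the default grid the horizon is 5 × 365.25 days, and
"reaching the horizon" is evaluated against that boundary.

Saliency is the vanilla gradient of the cumulative-hazard risk score
with respect to the input (for the sigmoid head this gradient at the
pre-activation is simply h), max-reduced over channels.

## Evaluation

Digitization fidelity compares, per lead, the recovered signal against
the source passed through the same filter/resample chain, over the
in-window (extracted or interpolated) samples only — this isolates
digitization error from filter transients and from the zero-padded
frame regions; whether published fidelity figures were computed this way
is not stated anywhere we could check, so the convention is documented
here. Zero-variance leads yield NA correlation and are counted rather
than silently dropped. Harrell's C counts pairs (i, j) with
t_i < t_j and event_i = 1; risk ties count one half; pairs with equal
times are non-comparable. The implementation is vectorized but is
checked in the tests against an independent O(n²) double-loop oracle
(exact agreement) and against `survival::concordance` on tie-free data.
Confidence intervals are seeded percentile bootstraps over records.
Model comparison by a partial likelihood ratio test is out of scope
(the procedure is not specified in enough detail to reimplement); paired
bootstrap C-index differences serve instead.

## Problem sizes and determinism

The round-trip benchmark runs 50 records at full page size (2200 × 1700
px, grid on) in a few minutes on one CPU; the discrimination experiment
trains on a 500-subject cohort (250 train / 50 validation / 200 test)
in a few minutes more. All randomness flows from explicit integer
seeds: the generator, cohort sampler, degradation noise, training
shuffles and bootstrap are each seeded, and identical config + seed
reproduces byte-identical artifacts (a tested contract).

## What passing tests do and do not show

The synthetic generator produces clean, stationary, single-morphology
beats: no baseline wander, no arrhythmia, no pathological morphologies
(infarction patterns, bundle-branch blocks), no electrode artefacts, no
vendor typography or header blocks on the page. Passing round trips
therefore demonstrate the geometric and numerical correctness of the
render→digitize→model chain — calibration, alignment, scaling,
likelihood, ranking — not clinical-grade digitization of arbitrary
scanned paper. Likewise the discrimination experiment shows the survival
networks can recover a known waveform→hazard link at realistic sample
sizes, not that mortality is predictable at any particular C-index in
real cohorts. Layouts other than 3 × 4 (plus optional strips) and
multi-page or vector-format (PDF) inputs are out of scope; pages must be
pre-rasterized.
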