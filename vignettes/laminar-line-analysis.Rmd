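---
title: "Depth-resolved analysis of line-scanning fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved analysis of line-scanning fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamline)
```

## The scientific problem

Neuronal populations in early visual cortex combine stimulus-driven
(feedforward) input with contextual input arriving through lateral and
descending connections. These input streams terminate in different cortical
layers: ascending thalamic projections target the middle depths, while
descending connections from higher-order areas terminate in superficial and
deep layers. Line-scanning fMRI trades spatial coverage for resolution,
sampling a single cortical patch at 0.25 mm along the laminar axis and
105 ms temporal resolution, which yields 6–10 data points across gray
matter — enough to resolve laminar response profiles non-invasively.

`lamline` implements the full analysis chain for such experiments:

1. a divisive-normalization (DN) population receptive field (pRF) forward
   model used to design participant-specific stimuli that weight responses
   toward stimulus-driven or contextual processing;
2. a seeded synthetic-session generator with known laminar ground truth,
   so that every downstream stage is testable without access to scanner
   data;
3. preprocessing: multi-echo combination, Savitzky–Golay smoothing,
   percent-signal scaling, event-related epoching, and re-gridding to a
   standard 20-point depth axis;
4. template-weighted depth profiles; and
5. a descriptive laminar model summarised by a contextual coefficient sum,
   `beta_context`.

## The DN-pRF forward model and stimulus design

The response of the target patch to a binary stimulus raster $S$ is

$$R(S) = \frac{a_{act}\,\langle S, G_1\rangle + b}
              {a_{norm}\,\langle S, G_2\rangle + d} - \frac{b}{d},$$

with $G_1, G_2$ unit-amplitude isotropic Gaussians at the pRF position with
widths $\sigma_1$ (activation pool) and $\sigma_2 \ge \sigma_1$
(normalization pool). Subtracting $b/d$ anchors the empty stimulus at zero.
The inner products are raster sums at a configurable resolution (default
20 px/dva — doubling the resolution changes disc responses by well under
1%, which is ample for selecting stimulus sizes on a 0.1-dva grid).

Passing centred discs of increasing radius (101 radii on 0–10 dva) through
the model traces a size-tuning curve; the centre stimulus takes the radius
at its maximum (ties resolved toward the smaller radius — the smallest
maximally effective stimulus). The large annulus is a 2-dva-wide ring whose
outer radius is the smallest distance from the pRF to any screen edge, and
the medium annulus sits halfway between the two, with a warning when the
halfway ring spatially overlaps its neighbours (on ordinary screen
geometries some overlap is unavoidable). Checkerboards carry 2 radial and
1 angular cycle per degree of stimulus size; we interpret "per degree of
stimulus size" as scaling with the outer radius, so the radial frequency is
fixed at 2 cycles/dva regardless of ring width (the alternative — scaling
with ring width — would make annulus texture depend on width, which the
rendering keeps configurable through `stimulus_spec`).

The DN amplitude parameters ($a_{act}, a_{norm}, b, d$) are configurable
with defaults (1, 0.05, 50, 500 at 20 px/dva) chosen to produce a
physiologically typical size-tuning curve: peak near 1.5–2 dva for a
$\sigma_1 = 0.7$ dva pRF, roughly one-third response suppression at
full-field, and an inhibitory surround with a zero crossing near 2.4 dva.
They are illustrative defaults, not estimates of any measured population.

## The synthetic session generator

The generator defines the study conditions the rest of the package is
tested against:

* **Timing.** 7-min runs; ~42 s dummy plus 30 s baseline before the first
  event; 5 events per condition per run, 2 s each, in a pseudorandom order;
  two timing variants per session. ISIs follow a truncated negative
  exponential on [14, 24] s whose scale is solved numerically so the mean
  is 18 s. We read the ISI as the offset-to-onset gap; the sampler's bounds
  hold either way.
* **Geometry.** A 24-voxel line at 0.25 mm spacing with a 6–10-sample
  gray-matter ribbon inside it; signal outside the ribbon is scaled to 5%
  of the gray-matter level, emulating outer-volume suppression.
* **Response.** Condition regressors are event boxcars convolved with a
  canonical double-gamma HRF built from gamma-variates with modes at
  exactly 6 s (peak) and 16 s (undershoot, ratio 1/6), normalised so one
  2-s event peaks at 1. Each ribbon depth scales the regressor by the
  condition's ground-truth amplitude at that normalized depth.
* **Ground truth.** Depth runs from 0 (pial) to 1 (white matter)
  everywhere in the package. The centre (feedforward) profile is a ramp
  increasing toward the surface plus a small middle-depth bump,
  $1.5\,(1-d) + 0.3\,N(d; 0.5, 0.1)$ (% signal). The large-annulus
  (contextual) profile has unit-max Gaussian peaks at $d = 0.25$ and
  $0.75$ (amplitudes 1.0 and 0.8) and a negative middle lobe
  ($-1.2\,N(d; 0.5, 0.12)$); the medium profile is a 50/50 mixture. The
  amplitudes were fixed once so that (a) depth-averaged peak responses
  order centre > medium > large, and (b) the laminar model assigns the
  centre profile a negative and the large profile a positive
  `beta_context` — the qualitative pattern the model is meant to detect.
  Note the composite large profile's maxima sit a little outside
  25%/75% because the negative middle Gaussian pushes them outward; the
  generative peaks are at exactly 25%/75%.
* **Noise.** Per-voxel AR(1) noise (ρ = 0.3, marginal SD 2% signal per
  sample — tSNR ≈ 50, typical for sub-millimetre line data) plus slow
  cosine drifts (periods 140–420 s, 1% amplitude). All randomness is
  seeded; generation is bit-reproducible.
* **Options.** A unidirectional drainage operator can mix deeper ribbon
  signal into superficial bins (fraction λ per
  depth step toward the pial surface), and a multi-echo mode emits echo
  images scaled by $e^{-TE/T_2^*}$ (TE 6–38 ms, $T_2^*$ 33 ms in gray
  matter).

What the generator does *not* emulate: physiological noise spectra
(cardiac/respiratory), motion, $T_2^*$ changes as the actual BOLD
mechanism (activation enters as a percent-signal modulation), partial
voluming at the ribbon borders, or between-depth noise correlations.
Passing tests therefore demonstrate correctness of the analysis chain
under a linear signal model with realistic amplitudes and timing — not
robustness to every artefact of real line data.

## Preprocessing

Runs are smoothed with a Savitzky–Golay filter (31 samples ≈ 3.3 s, 3rd
order, mirrored edges), scaled to percent signal change about the temporal
median per depth (sparse designs leave the median at rest level; the
choice between median and mean is immaterial for baseline-corrected
epochs), epoched from 2 s before to 14 s after onset (fixed length
`round(16 s / tr)` = 152 samples, onsets aligned to the nearest earlier
sample — no temporal interpolation), baseline-corrected by the pre-onset
mean, and averaged first across runs sharing a timing variant, then across
events. Condition means are restricted to the gray-matter ribbon and
linearly interpolated onto 20 evenly spaced normalized depths (linear
interpolation preserves constants and endpoints; nearest-neighbour is
available for sensitivity checks).

Quality assessment regresses every line position on an HRF-convolved
centre-event regressor and inspects variance explained along the line. A
session is included when the centre response (depth-averaged, 5–7 s
window) exceeds every other condition and the centre profile shows the
draining-vein signature (superficial third above the deep third). The
ribbon may be shifted by up to ±2 samples toward higher mean r²; a nonzero
shift is accepted only when it improves mean ribbon r² by at least 0.01 —
on a noise-flat r² landscape an unconditional argmax frequently selected
spurious ±2 shifts that dragged suppressed out-of-ribbon voxels into the
profile, which is exactly what the shift is meant to prevent.

## Template-weighted depth profiles

Evoked depth-by-time responses are collapsed over time by projecting each
depth's time course onto a template — the centre-stimulus response
averaged over participants and depths:

$$\mathrm{profile}_d = \frac{\sum_t h_d(t)\, h_T(t)}{\sum_t h_T(t)}.$$

The denominator sums the raw (not absolute) template, as the expression is
written; a near-zero template sum raises an error rather than returning
unstable ratios. Profiles are de-offset across participants (subtract each
participant's depth mean, add back the grand mean; idempotent and
mean-preserving). A 5–7 s window average is provided as the simpler
alternative; the template is preferred because response latency varies
across participants.

## The laminar model and `beta_context`

Profiles on the 20-point grid are fit by OLS against six regressors:
intercept; a zero-meaned drain term (linear $1-d$, or negative exponential
$e^{-d/\tau}$, $\tau = 0.25$, both largest at the pial surface where
venous carry-over accumulates); unit-max Gaussians at 25% and 75% depth
(width $\sigma_g = 0.12$ normalized depth, i.e. FWHM ≈ 28% — wide enough
to be smooth on 20 points, narrow enough to keep the peaks separable and
the design full-rank, which holds numerically across
$\sigma_g \in (0.05, 0.3)$); and their analytic depth-derivatives scaled
to unit maximum absolute value, which let each peak shift slightly to
absorb anatomical variability. The derivative convention is with respect
to depth: a positive derivative coefficient shifts the fitted peak toward
the white matter. `beta_context` sums the last four coefficients; the
intercept and drain term are excluded so that a flat or purely
drain-shaped profile scores zero (verified to OLS precision in the tests).

Draining-vein sensitivity is assessed two ways: swapping the linear drain
for the exponential, and deconvolving profiles through a unidirectional
leakage operator before fitting. The default leakage operator is the
single-parameter carry model ($L_{ij} = \lambda^{j-i}$ for $j \ge i$,
pial-first ordering, λ = 0.3 per 0.05 normalized-depth step);
`read_leakage_matrix()` accepts published vascular-model coefficient
tables in their place. Deconvolution is exact triangular back-substitution;
the forward/inverse round trip is accurate to $10^{-10}$.

Group statistics (one-way ANOVA with partial η², Holm-corrected pairwise
paired t-tests, Cohen's d) are thin calls to the standard routines — they
are plumbing around `beta_context`, not part of the contribution.

## Numerical choices and degenerate inputs

* Epoch length is fixed at 152 samples; epochs extending past the run are
  dropped with a warning and counted.
* Zero-variance line positions (fully suppressed) get r² = 0 rather than
  NaN.
* `percent_signal_change` errors on non-positive medians; raw generator
  output is strictly positive.
* Paradigm construction retries ISI draws (bounded) when a schedule would
  overflow the 7-min run, then errors.
* Ties in the size-tuning argmax go to the smaller radius; flat curves are
  an error.
* T2* estimation falls back to the global median with a warning when a
  depth's mean echo signal is non-positive.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the test suite run: single
sessions of two 7-min runs (24 × 4000 samples); an 11-participant cohort
through the full pipeline (~2 s); and 200-cohort Monte-Carlo checks of the
`beta_context` direction at the profile level (ground truth + participant
gain variability + per-depth noise of 0.2% signal, matching the empirical
profile noise of the full pipeline at default settings). Running the
direction check through 2,200 fully generated sessions would exercise the
same fitting-stage property at vastly higher cost; the end-to-end path is
instead covered by the noiseless round-trip and pipeline tests.

## Known limitations

* The recoverable ground truth of a session is its profile at the sampled
  ribbon depths: a 7-depth session regridded to 20 points is compared
  against the equally regridded 7-point truth, not against the continuous
  profile (they correlate at ≈ 0.999 but differ at interpolation scale).
* The generator's noise model is stationary and depth-independent.
* The inclusion criteria and ribbon-shift rule are qualitative
  reconstructions of manual quality control; their thresholds (0.01 r²
  margin, superficial/deep thirds) are design choices documented above.
* Group inference on synthetic cohorts uses participant-level paired
  tests; a full mixed-effects treatment of multi-run data is deliberately
  out of scope.
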