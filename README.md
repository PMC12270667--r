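# lamline

Depth-resolved analysis of line-scanning fMRI responses in human visual
cortex.

Stimulus-driven and contextual visual processing arrive in different
cortical layers: ascending (feedforward) projections terminate in the
middle depths of V1, while lateral and descending (contextual) connections
terminate superficially and deep. Line-scanning fMRI samples a single
cortical patch at 0.25 mm along the laminar axis and 105 ms temporal
resolution — 6–10 points across gray matter — making those laminar
signatures measurable in humans. `lamline` is for researchers running (or
simulating) such experiments: it covers stimulus design from population
receptive field (pRF) estimates, synthetic session generation with known
laminar ground truth, preprocessing, depth-profile extraction, and the
descriptive laminar model that separates feedforward from contextual
response patterns.

## What it computes

**DN-pRF forward model and stimulus design.** A divisive-normalization pRF
responds to a stimulus raster *S* as

    R(S) = (a_act <S, G1> + b) / (a_norm <S, G2> + d) − b/d,

with G1, G2 Gaussians of widths σ1 (activation pool) and σ2 ≥ σ1
(normalization pool). Size-tuning curves from this model set the centre
stimulus radius; screen geometry sets the large annulus; the medium
annulus sits halfway.

**Synthetic sessions.** Seeded generator of 7-min line-scanning runs
(TR 0.105 s, jittered ISIs 14–24 s with mean 18 s, 5 events per condition
per run, two timing variants), with condition-specific ground-truth
laminar profiles, AR(1) noise, drift, optional multi-echo images and an
optional draining-vein (leakage) forward model.

**Preprocessing.** Multi-echo combination (sum-of-squares or T2*-weighted),
Savitzky–Golay smoothing (31 samples, 3rd order), percent-signal scaling,
epoching (−2…14 s, baseline-corrected), GLM quality control along the
line, and re-gridding of gray-matter responses to a standard 20-point
normalized-depth grid (0 = pial, 1 = white matter).

**Depth profiles and the laminar model.** Depth-by-time responses collapse
onto a per-depth scaling factor via template weighting,

    profile_d = Σ_t h_d(t) · h_T(t) / Σ_t h_T(t),

where h_T is the group-average centre response. Profiles are then fit by
OLS against six depth regressors — intercept, a draining-vein term, two
Gaussians peaking at 25% and 75% cortical depth, and their derivatives —
and summarised by **β_context**, the sum of the last four coefficients.
Feedforward-like profiles (monotone toward the surface) score β_context
near or below zero; contextual profiles (bimodal superficial/deep) score
positive. Drainage can additionally be removed by deconvolution through a
unidirectional leakage matrix.

## Worked example

The numbered scripts under `analysis/` run the complete workflow on
synthetic data. The cohort analysis:

```sh
Rscript analysis/04_cohort_profiles.R
Rscript analysis/05_laminar_model.R
```

prints

```
simulated 11 participants; 10 pass the inclusion criteria
peak-window response magnitudes (% signal): center 0.80, large 0.18, medium 0.49

[linear drain]
  center: beta_context -0.18 +/- 0.11
  large: beta_context 1.58 +/- 0.17
  medium: beta_context 0.73 +/- 0.13
  one-way ANOVA: F(2,30) = 40.37, p = 3.1e-09, eta2p = 0.73
  centre vs large: t(10) = -8.42, p_holm = 2.2e-05, d = -2.54
```

Reading: the centre stimulus drives the largest overall response (0.80%
signal around the response peak), as designed; but after collapsing to
depth profiles, the *large annulus* carries the strongly positive
contextual coefficient (β_context 1.58 vs −0.18 for the centre stimulus) —
its response concentrates at superficial and deep depths, where descending
connections terminate, while the centre response rises monotonically
toward the surface. The direction of that contrast is unchanged with an
exponential drain term or with drainage deconvolution
(`analysis/05_laminar_model.R`, `analysis/06_direction_property.R`).

The same stages are available programmatically:

```r
library(lamline)
res <- run_pipeline(pipeline_config(seed = 20))
res$group$descriptives      # per-condition beta_context mean +/- SEM
res$group$pairwise          # Holm-corrected paired contrasts
```

## Layout

- `R/` — package code: pRF model and stimulus design, paradigm and session
  generator, preprocessing, depth profiles, laminar model, pipeline.
- `analysis/01…06_*.R` — narrative drivers writing tables under `results/`.
- `vignettes/laminar-line-analysis.Rmd` — models, assumptions, parameter
  choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests.
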