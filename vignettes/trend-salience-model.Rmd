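---
title: "The trend-salience tension model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The trend-salience tension model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiontrend)
```

## Overview

Continuous tension ratings are among the most robust behavioral probes of
musical experience: listeners move a slider while the music plays, and the
averaged trace is highly reliable across panels. `tensiontrend` models such
traces from audio alone, on the hypothesis that tension tracks the recent
*direction of change* of a handful of perceptual features rather than their
levels — rising loudness is tense at any absolute loudness — and that a
trend which confirms an already-established direction is more salient than
a fresh one.

This vignette derives the model, explains every default, documents the
numerical choices, and states the limitations. All quantitative statements
below about synthetic data are computed by the package's test suite or by
`scripts/acceptance.R`; the package makes no claims about behavioral data,
which it does not ship.

## The model

Let $x_f(t)$ be feature $f$ sampled at 10 Hz and z-scored per piece. On a
lattice with step $h = 250$ ms, three stages produce the per-feature trend
signal:

**1. Attentional slope.** $s_f(t)$ is the OLS slope of $x_f$ over the
trailing window $(t - d,\, t]$, regressed on time in seconds. Windows are
stamped at their end time, so the model is causal; lattice points whose
window does not fit entirely inside the piece carry no slope.

**2. Memory gating.** A second slope over the preceding memory window
$(t - d - m,\, t - d]$ sets the context. The gated slope is

$$\tilde s_f(t) = \begin{cases}
\beta\, s_f(t) & \text{if } \operatorname{sign} s_f(t) =
  \operatorname{sign} s^{mem}_f(t) \neq 0,\\
s_f(t) & \text{otherwise,}
\end{cases}$$

with gain $\beta = 5$. Slopes with magnitude below $10^{-12}$ are treated
as zero so that a constant passage can never be amplified through
floating-point residue.

**3. Decaying integration.** The trend signal is a decaying average of the
last $n = 3\,\mathrm{s} / h = 12$ gated slopes,

$$S_f(t) = \frac{\sum_{\tau=0}^{n-1} \lambda^{\tau}\,
  \tilde s_f(t - \tau h)}{\sum_{\tau=0}^{n-1} \lambda^{\tau}},$$

with decay $\lambda \in (0, 1]$ (default 0.8; $\lambda = 1$ is the plain
12-step mean, and a constant slope is a fixed point for every $\lambda$ —
both limits are pinned by tests). At the start of a piece the kernel is
renormalized over the available taps.

The predicted tension is the weighted sum $S(t) = \sum_f w_f S_f(t)$.
Because each stage is linear in the feature values apart from the gate,
$S$ is exactly linear in the weights; the test suite checks this to
$10^{-12}$.

## Estimation

Ratings lag the music; the package reads the (z-scored, panel-mean) rating
4.5 s after each prediction time and works at 2 Hz for estimation and
evaluation. Per-piece baseline differences are handled as intercepts:
penalized steps center target and regressors within piece (the
Frisch–Waugh projection of piece fixed effects), and the final weight fit
estimates one intercept per piece explicitly. With the pooled, nearly
balanced design this fixed-intercept least-squares fit coincides with a
random-intercept likelihood fit; `fit_weights(method = "lmer")` provides
the latter when `lme4` is installed. The reported marginal $R^2$ is the
slope-term variance over slope + intercept + residual variance.

**Window selection, weighted variant.** All $(d, m)$ pairs with
$d \in 1{:}10$ s, $m \in 0{:}10$ s enter a grouped penalty: the six feature
columns of one pair form a group, and the first group to activate along a
descending geometric penalty schedule (50 points over 4 decades from the
analytic $\lambda_{max}$) is selected. The group lasso is solved by block
coordinate descent after within-group orthonormalization, which leaves
group selection unchanged while making each block update closed-form.
Selection stops at the first active group, since nothing later on the path
is used. A selection whose unpenalized refit explains less than 5% of the
centered target variance is flagged weak.

**Window selection, timescale variant.** Each feature may keep its own
pair from $d \in 1{:}20$, $m \in 0{:}20$ s. Grouping is dropped (the 2,520
columns are highly collinear across neighboring windows) in favor of a
plain L1 path (`glmnet`), tuned by AIC with degrees of freedom counted as
nonzero coefficients plus per-piece intercepts; each feature takes the pair
of its largest-magnitude surviving coefficient, with a flagged fallback to
the most common pair when a feature keeps no column.

Since the target is z-scored, weights are identified up to a positive
scale; comparisons against generating weights are made after unit-norm
scaling.

## Features

No psychoacoustics toolbox is assumed; the extractors are self-contained
approximations chosen so that the *ordering and trend* information the
model consumes is faithful:

- **Loudness**: STFT-frame RMS to SPL ($94 + 20\log_{10}$), then the sone
  power law $2^{(SPL - 40)/10}$ — monotone in level with the conventional
  10 dB doubling.
- **Roughness**: the signal is squared and low-passed to obtain its
  envelope; modulation-spectrum energy in 20–300 Hz is weighted by
  $(f_m/70)\,e^{1 - f_m/70}$, peaking at 70 Hz where roughness is maximal.
- **Onset frequency**: positive spectral flux on a log-mel spectrogram with
  local-max/local-mean peak picking; the piece is split at its midpoint and
  each half's inter-onset durations are converted to a step function
  (each event scored as that half's maximum duration minus its own), which
  is robust to a mid-piece change of instrumentation.
- **Tempo**: windowed autocorrelation of the onset-strength envelope;
  among near-maximal autocorrelation peaks the shortest lag is taken (so
  multiples of the period cannot masquerade as slower tempi), and the BPM
  value is folded octave-wise into [90, 180).
- **Pitch height**: mean MIDI number of spectral-peak multi-pitch
  estimates, held through unpitched frames.
- **Tonal tension**: notes are transcribed from the multi-pitch frames,
  placed on a line-of-fifths helix (quarter turn and constant rise per
  fifth), and each 1 s window's duration-weighted center of effect is
  scored by its distance from the piece's global center — a simplified
  spiral-array tensile strain using pitch classes only, without separate
  chord and key representations.

Every feature ends with the same postprocessing: 1 s moving-average
smoothing, block-mean downsampling to 10 Hz, z-scoring with the population
(divisor-$n$) standard deviation.

## Synthetic data

The synthetic module is the package's study design, and its defaults were
fixed before any recovery experiments: 10 pieces × 90 s at 10 Hz, six
band-limited (0.05–0.5 Hz) Gaussian features per piece regenerated until
all pairwise correlations stay below 0.7, forward-model tension plus
Gaussian noise of sd 0.2 on the z scale, and 24 simulated raters (slider
start at 0.30, nominal maximum 0.70, log-normal gain sd 0.15, response lag
4.5 ± 0.5 s, smoothed noise, floor clipping at 0, 60 Hz). The feature band
is chosen so that 1–20 s windows see distinguishable trends: much faster
signals alias into the slope noise, much slower ones make neighboring
window lengths indistinguishable. These problem sizes are the package's
own choice for desk-scale reproducibility, not a claim about any
particular behavioral corpus.

## Numerical choices

- **Windowed slopes** are computed as a zero-sum FIR filter: with uniform
  sampling, every full window of length $d$ holds exactly $d \cdot$ rate
  samples, so the OLS slope is a fixed centered-ramp convolution. This
  avoids the catastrophic cancellation of the textbook
  $m S_{xy} - S_x S_y$ prefix-sum formulas at large absolute times; the
  test suite holds the result to within $10^{-10}$ relative error of a
  direct per-window fit, and typical errors are near $10^{-12}$.
- **Block-mean resampling** (not interpolation) maps between rates, so
  downsampling commutes with the piecewise-constant reading of the design
  lattice and is idempotent at the coarser rate.
- **Population-sd z-scoring** everywhere, so a z-scored series has mean
  exactly 0 and root-mean-square exactly 1 regardless of length.
- The **group-lasso path** terminates at the first active group, and raw
  slopes are computed once per window length and shared across all
  $(d, m)$ pairs, which keeps full-grid optimization at a few seconds
  (weighted) to tens of seconds (timescale) per corpus.

## Limitations

- The loudness, roughness, and transcription front ends are deliberate
  approximations of their psychoacoustic references (no excitation-pattern
  loudness, no Plomp–Levelt partial-pair roughness, no trained
  polyphonic-transcription model). They preserve monotonicity and trend
  structure on the synthetic fixtures they are tested on; absolute values
  are not comparable to toolbox outputs.
- The tonal-tension feature uses pitch classes only; major/minor context
  and voice leading are outside its reach, and transcription from dense
  polyphonic audio will be noisy.
- Recovery results quoted anywhere in the package are for the synthetic
  generator's conditions. They bound what the pipeline can do when its own
  forward model generated the data and say nothing about human ratings.
- The rating lag (4.5 s) and evaluation rate (2 Hz) are fixed conventions
  of the pipeline; data collected under different slider dynamics may need
  different values, which all entry points expose as arguments.
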