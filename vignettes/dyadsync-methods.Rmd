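---
title: "Measuring dyadic human-canine psychophysiology: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dyadic human-canine psychophysiology: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

Canine-assisted interaction (CAI) research typically measures outcomes with
pre/post surveys. `dyadsync` implements a finer-grained approach: a human and
a dog each wear synchronized sensors — ECG, a tri-axial accelerometer,
electrodermal activity (EDA) and skin temperature (ST, human wrist only) —
across an experimental day structured as baseline (BASE), two 10-minute
interaction subsessions (INT1, INT2) couched in neutral subsessions
(NEU; the dog is out of the room) and a post-line (POST). All modalities are
reduced onto one shared grid of non-overlapping 10-second epochs, chosen as
the fastest timescale at which the slowest-reacting metrics still carry
signal. Three raters additionally assign each interactant a
psychophysiological state per second (-1 negative, 0 neutral, +1 positive),
and SAM/PANAS-SF surveys are collected between subsessions.

Two extraction forms coexist:

* **ME** (metric by epoch): one value per 10-s epoch — the basis of the
  summary tables, the directional heatmap and the correlation matrix.
* **RE** (rolling extraction): the same metric from a centered 60-s window
  evaluated at 10 Hz — the basis of the synchrony analyses, which use an
  18-epoch (3-minute) slice from the middle of each interaction subsession,
  torso devices only (human chest, canine harness).

## Metrics

From detected R peaks, interbeat intervals (IBI, ms) give HR
(`60000 / mean(IBI)` per window — one documented convention, rather than a
mean of instantaneous rates), SDNN (sample SD, n−1), RMSSD (root mean
square of successive differences over adjacent valid pairs) and their
quotient. IBIs outside species bounds (human 300–2000 ms, canine
250–1500 ms) or deviating >30% from the median of the five surrounding
IBIs are rejected as artifacts — a timing-only proxy for "normal sinus
beats", since no beat morphology typing is attempted.

From the gravity-removed (band-passed) accelerometer: per-axis mean
amplitude deviation `MAD = mean(|a - mean(a)|)` and the integral modulus of
acceleration `IMA = sum(|ax|+|ay|+|az|) * dt / T`, time-normalized so that
10-s epochs and 60-s windows are comparable (units m/s²). Raw-signal
per-axis mean/min/max are taken with gravity included.

EDA is split into a tonic level (8-s running median) and a phasic residual;
a skin-conductance response (SCR) is a local phasic maximum with an
onset-to-peak rise of at least 0.03 µS within 5 s — declared substitutes
for an external tool's unpublished thresholds. Epoch features are the mean
and max of the full signal plus the SCR count.

## Synchrony

For each interaction subsession and each of HR, SDNN, RMSSD and IMA, the
mid-subsession RE slice pair is compared with (i) Pearson correlation and
(ii) dynamic time warping — classic full-matrix dynamic programming, L1
local cost, steps (1,0)/(0,1)/(1,1), boundary-anchored, no warping window.
DTW runs on raw metric units by default, which makes heart-rate distances
dominate (the canine baseline sits ~20 beats/min above the human's); a
z-scored mode removes level offsets and is what the coupling-recovery
analysis uses. Behavior synchrony is the XNOR measure: the percentage of
jointly determinate epochs carrying the identical code.

## PPSA behavior coding

An epoch's code is the strict majority of its seconds; any non-strict
majority codes neutral (5 s neutral + 5 s positive is neutral, and a
positive/negative 5/5 tie also resolves to neutral — the schema's
deliberate conservative bias). Epochs with ≥5 off-screen seconds are
indeterminate and excluded from percentages, XNOR and kappa; fewer
off-screen seconds are dropped from the majority count. Inter-rater
reliability is plain (unweighted) Cohen's kappa on the 3-category scale,
averaged pairwise for three raters.

## Statistics

Session-type contrasts (neutral vs interaction) pair observations within a
session — one mean per type per session — and use the Wilcoxon signed-rank
test: zero differences dropped, ties mid-ranked, and for n ≤ 12 the
two-sided p computed by full enumeration of all 2^n sign assignments
(tie-aware); larger n uses the normal approximation with continuity
correction and tie-corrected variance. Significance is two-sided 0.05. The
suite verifies the exact branch against an independent enumeration oracle
and calibrates the type-I error at the null (0.05 ± 0.02 over 1000
replicate studies).

The pairing question (per session vs per subject) is resolved
here per *session*: each experimental day contributes one NEU/INT pair,
which matches how `compare_session_types` aggregates; pairing by subject
can be obtained by passing subject ids as the `session` column.

## The synthetic dyad generator

No CAI pilot dataset is public, so the package ships a simulator whose
defaults define the study conditions and whose ground truth makes every
stage testable:

* **IBI**: `simulate_ibi_series` is AR(1) in IBI space around
  `60000/mean_hr`; the lag-1 coefficient comes from the identity
  `RMSSD² = 2·Var·(1−φ)`, so one (SDNN, RMSSD) pair is targeted exactly in
  expectation. Feasibility requires φ ∈ (−1, 1), i.e. `rmssd < 2·sdnn`.
  Defaults: human 75 beats/min, SDNN 50 ms, RMSSD 40 ms; canine
  95 beats/min, SDNN 60 ms, RMSSD 40 ms. The canine HRV targets are
  placeholders chosen in a physiologically plausible range, not claims
  about dogs.
* **Coupling**: within a session the two subjects beat at different rates,
  so a shared beat-indexed innovation stream would drift out of temporal
  alignment. Instead a latent continuous-time AR(1) (Ornstein-Uhlenbeck)
  driver is sampled on a common 4 Hz clock; during interaction subsessions
  each subject's IBI fluctuation loads on it with weight `sqrt(rho)` and on
  a private driver of the same correlation-time scale with weight
  `sqrt(1−rho)`, making the expected Pearson correlation of the smoothed
  heart-rate series equal `rho`. Because a 60-s rolling window leaves only
  a handful of effectively independent values inside a 3-minute slice, a
  single slice's sample correlation is noisy; recovery is therefore
  assessed as a mean over 20 seeds × 2 interaction slices per coupling
  level, which lands within 0.1 of the target across the grid
  {0, 0.3, 0.6, 0.9} and is strictly monotone.
* **ECG**: three Gaussian bumps per beat (P, R, T; R = 1 mV, 10 ms width)
  plus Gaussian noise (default 0.02 mV) — the minimal shape that exercises
  a real Pan-Tompkins-style detector. The canine uses the same template at
  its faster rate; no breed morphology is modeled because only R-peak
  timing is consumed.
* **EDA/ST/ACC**: tonic ramp + Bateman-kernel SCRs + noise (tonic shifted
  +0.5 µS during interactions, SCR rate doubled); linear ST drift
  (0.05 °C/min); gravity + band-limited dynamic noise with scheduled
  movement bouts, modulated by the subject's coupled driver so activity
  synchrony mirrors physiological coupling.
* **Behavior**: the human state stream is a sticky 3-state Markov chain;
  each second the canine copies the human's state with probability κ, else
  follows its own chain, so the same-state fraction is at least κ. Humans
  are neutral by instruction outside interactions; the dog is off-scene
  during NEU. Three simulated raters observe the truth with misread
  probabilities 3/5/7% plus shared off-camera segments.
* **Surveys**: session-level latent arousal feeds both the SAM arousal
  item and PANAS positive affect (so their across-session correlation is
  recoverable); interactions shift the arousal and valence constructs by
  one and 0.8 points and the PANAS item means by +0.5/−0.2. SAM stores the
  source convention (larger value = more unhappiness / more calmness), on
  a 1–5 scale. MDORS is a pair-level total, lower = stronger bond,
  generated from the bond strength.
* **Reproducibility**: one master seed; every channel draws from its own
  deterministically derived stream, so identical configs are byte-identical
  and adding a channel never perturbs the others.

What the simulator does **not** emulate — and hence what green tests do not
show about real data: motion artifacts that correlate across channels,
electrode drift and contact loss, breed- and posture-dependent ECG
morphology, respiratory sinus arrhythmia structure beyond AR(1), rater
drift over a session, or any causal link from behavior states to the
physiological channels.

## Numerical and design choices

* Half-open 10-s epochs, 0-based indices; partial trailing epochs are
  dropped so every epoch has identical support; epochs never straddle
  subsession boundaries.
* Resampling to uniform clocks is linear; raw gaps longer than 2 s are
  masked as missing, never interpolated (shorter than any metric window,
  longer than timing jitter).
* Outlier handling masks, never imputes: physiological plausibility bounds
  per channel kind, plus a Hampel test (1 s window, 5·MAD) for the slow
  channels (EDA, ST) only — R waves and movement bursts are legitimate
  spikes. A channel whose artifact fraction among usable samples exceeds
  50% raises a quality error.
* Filter bands (standard physiological choices, all configurable): ECG
  0.5–40 Hz order 4; accelerometer dynamic component 0.1–0.4·fs order 4;
  EDA 1 Hz low-pass order 2; ST 0.01 Hz low-pass. The EDA/ST filters are
  true low-passes because epoch means are reported in physical units and a
  near-zero high-pass edge is numerically fragile at 4 Hz sampling; epoch
  means and maxima are taken from masked raw samples for the same reason.
  All filtering is zero-phase (forward-backward) so epochs stay aligned.
* Delta ties (`v_t = v_{t-1}`) in the heatmap render as "decrease" — the
  visual contract is binary solid/off — with the tie count reported
  separately. The SDNN/RMSSD quotient carries no agreed direction and is
  excluded from the heatmap unless explicitly mapped.
* RE ticks with truncated windows are computed but edge-flagged; synchrony
  slices refuse edge ticks and interpolate at most 5% missing ticks.
* Exact Wilcoxon enumeration caps at n = 12 (4096 sign vectors), the
  crossover to the continuity-corrected normal approximation.

## Problem sizes

The shipped test-suite and acceptance runs use: 5-minute records at 250 Hz
for beat-recovery checks (20 seeds, both species); two 10-minute
interaction subsessions per simulated dyad on the coupling grid (20 seeds
per level); and a full 22-session study at the standard protocol
(5 subsessions, 35 minutes per session) for the end-to-end report. These
sizes were chosen so each property is measured with comfortable
Monte-Carlo margin.
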