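---
title: "Circadian gating of differentiation commitment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian gating of differentiation commitment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockgate)
```

## The scientific problem

Preadipocytes differentiate into fat cells over several days, yet the
irreversible step — commitment, marked by the PPARG level crossing a
threshold beyond which positive feedback locks it high — completes within
roughly four hours. Because commitment is fast relative to the ~26-h
cell-intrinsic circadian clock, the clock can gate it: commitment events
concentrate in the rising half of the Rev-Erbα reporter cycle (phases π to
2π, with peaks defined as phase 0/2π and troughs as π), producing daily
bursts of differentiation at the population level. `clockgate` implements
both halves of the computational story: the single-cell trace pipeline that
measures commitment times and phases from dual-reporter imaging data, and a
stochastic ODE model that explains when and why bursts appear.

## The trace pipeline

**Smoothing and slopes.** Trajectories are smoothed with a centered 6-h
moving average; the local synthesis-rate proxy is the OLS slope over ±4-h
windows. At trace ends the smoothing window shrinks symmetrically and the
slope window is truncated — no padding is invented, because commitment
calls near the ends of the movie matter. Both operators are linear and the
slope matches a per-point `lm()` oracle to 1e-9 (tested).

**Commitment calibration.** The ground-truth fate cutoff is the smallest
control-cell terminal PPARG value leaving strictly fewer than 3% of control
cells above it. A ROC scan over candidate thresholds then asks how well
"the trace ever exceeded the threshold" predicts terminal fate; the optimal
threshold is the ROC point closest to the corner (0, 1), ties broken toward
the lower threshold so commitment is detected earlier. The scan evaluates
the union of 200 quantile thresholds and every observed per-cell maximum,
which makes the trapezoidal AUC exactly the Mann–Whitney statistic.
Commitment time is the first crossing of the optimal threshold, linearly
interpolated between samples (12-min sampling would otherwise quantize
phase estimates).

**Anchors and phase.** Peaks and troughs of the smoothed reporter are
detected by topographic prominence (≥ 10% of the trace range, ≥ 12 h
apart), forced to alternate by inserting the extremum between same-kind
anchors. Two refinements matter in practice:

* *Boundary-aware prominence.* A flank that reaches the trace end without
  a higher point and without descending by the prominence threshold is
  censored by the observation window; such one-sided candidates are kept
  only if they lie near the top of the trace range. Without this, first
  peaks within ~3 h of the movie start are systematically lost, which
  biases condition comparisons of first-peak times.
* *A rhythmicity gate.* The trace must let a cosine at the median peak
  spacing explain ≥ 50% of its variance, otherwise no anchors are
  returned. The gate is affine-invariant (so is the whole detector) and is
  what makes Bmal1-knockdown-like flat traces yield zero anchors instead
  of noise peaks.

Phase maps interpolate linearly from each peak (0 mod 2π) to the next
trough (π) and on to the next peak (2π). Commitments before the first
detected peak or after the last anchor are excluded and counted, not
extrapolated — extrapolated phase would be unanchored. Commitment-time
distributions are summarized with a univariate Gaussian mixture (EM, BIC
selection over k = 1..5 via mclust, deterministic initialization);
commitment-phase distributions with a one-term Fourier fit to a 24-bin
phase density. Phase-folded slope curves resample each complete
peak-to-peak period onto a 48-point phase grid; bootstrap confidence bands
resample cells (periods within a cell are correlated).

**Division calling.** A division is called when both nearest-future
candidates carry 45–55% of the parent's total H2B. Parent and candidate
totals are averaged over 1 h before/after the frame; with 5% per-frame
intensity noise, frame-level ratios would leave the band ~30% of the time,
while the averaged ratios give recall and precision above 0.95 on
generator ground truth.

**Rhythmicity utility.** `rhythmicity_test()` is a deliberately simple
cosinor-amplitude permutation test (shuffling time labels), with an
optional one-period moving-average detrend. It is plumbing, not a
reimplementation of JTK_Cycle.

## The synthetic data generator

Every pipeline stage is tested against `generate_population()`, which
produces dual-reporter populations with full ground truth. What it
emulates: raised-cosine reporter oscillations with per-cell periods drawn
around 26 h (5% CV); a 12-h delayed first reporter peak under a DMI-like
condition and a ×1.25 period lengthening under a LH846-like condition; a
flat reporter under Bmal1 knockdown; a gradual multi-day PPARG rise whose
slope is modulated (depth 0.3) peaking at reporter phase 1.4π; a logistic
commitment switch with a 4-h 10–90% rise, built so the noise-free trace
first crosses the true threshold exactly at the drawn commitment time;
commitment phases uniform in the gating window [π, 2π], with the
commitment cycle drawn from a truncated geometric (p = 0.35) so bursts
spread over sequential cycles; bimodal terminal fates that do not overlap
noise-free; at most one exact H2B halving per cell, within the first 24 h,
probability 0.05; and multiplicative 5% lognormal measurement noise.
Identical seeds reproduce populations bit for bit, and each cell uses its
own substream, so cell *i* is unchanged when `n_cells` grows.

What it does **not** emulate: segmentation/tracking errors, photobleaching
and focus drift, reporter amplitude damping, cell crowding, or any
correlation between clock phase and fate probability beyond the gating
window itself. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under the stated statistical
structure, not robustness to imaging artifacts.

Free choices the source material does not constrain, fixed once: the
first-peak time distribution U(2, 8) h; reporter amplitude = baseline = 1;
undifferentiated noise-free endpoints drawn in [low + 0.5·(thr − low),
low + 0.85·(thr − low)]; Bmal1-knockdown commitment times from a single
Gaussian 48 ± 6 h (one commitment wave when no clock phases exist); the
LH846 factor 1.25.

## The seven-species model

States (relative units, time in minutes): PPARG mRNA, PPARG protein,
agonist-activated PPARG*, CEBPA mRNA and protein (fast feedback, protein
half-life ln 2/0.0033 ≈ 3.5 h), slow-partner mRNA and protein (FABP4-like,
mRNA half-life ≈ 34 h). All twenty printed rate constants are defaults of
`model_params()`. PPARG mRNA is induced by (CEBPA + SlowFBP)⁴/(1⁴ + ·);
both feedback mRNAs by (w·PPARG + PPARG*)⁴ Hill terms with constants 2 and
3 raised to the 4th power; the adipogenic stimulus (stim = 1 from t = 0)
drives PPARG activation through stim/(1.2 + stim). Everything starts at
zero. Cell-to-cell variability enters through static lognormal factors ε₁,
ε₂ (underlying SD 0.30, or 0.03 for the low-noise scenario) multiplying the
two feedback mRNA synthesis terms; a third factor on PPARG mRNA synthesis
is available behind `noise_on_mpparg` but off by default.

**Forcing calibration.** The circadian input multiplies CEBPA mRNA
synthesis with `mean + a·cos(2π(t − θ₀)/T)`, T = 1560 min.
`circadian_forcing()` defaults to mean 1 (so the multiplier averages to 1),
but the *model* default is a rest-phase boost: mean = 1 + a, a = 1.3, so
the forcing rests at 1 in its trough and peaks at 3.6. The reason is
structural: with any mean-1 cosine of amplitude ≤ 1, the noise-free cell
stays in the low-PPARG basin indefinitely (verified by 40-day
integrations), so a 3%-noise ensemble would contain no committed cells at
all — incompatible with the typical S-shaped committing trajectory and
with the low-variation scenario producing a single commitment wave. A
boost with a ≥ ~1.1 places the commitment boundary below ε = 1; a = 1.3
with stimulus onset at the forcing trough (θ₀ = T/2) was fixed after a
coarse scan because it reproduces all four architecture behaviors at once
(multimodal gated bursts, single low-noise wave, first-cycle-only
fast-only commitment, arrhythmic slow architectures). Amplitude, mean and
θ₀ all remain configurable.

**Integration.** Ensembles use a vectorized fixed-step RK4 (6-min steps;
the fastest rate constant is 0.025 min⁻¹, so λh ≈ 0.15) over all cells at
once — 2000 cells × 6 days in ~2 s. Single cells use deSolve's adaptive
`lsoda` with rtol 1e-8. The two routes agree to relative 1e-4 on random
parameterizations (tested); states are clamped at zero and asserted
nonnegative.

**Fate scoring.** The fate cutoff comes from the bimodal terminal
total-PPARG distribution: a 2-means split of log endpoints
(deterministic quantile initialization), cutoff at the midpoint of the
cluster centers in log space. A kernel-density antimode was tried first
and rejected: cells still in transit at day 6 fill the valley, making the
antimode location unstable across seeds (it wandered between 2.0 and 3.6),
whereas the 2-means cutoff is stable to ±0.05. If the split is not
genuinely bimodal (center ratio < 3 or a cluster under 2% of cells) the
ensemble is declared unimodal, all cells get one fate with a warning, and
no commitment times are assigned. Architecture variants are scored against
the full model's cutoff — the comparisons share one threshold line.

**Variants.** `apply_variant()` derives low-noise (SD 3%), slow-slow,
fast-fast, clock-on-slow and no-clock architectures. The timescale swaps
replace the printed degradation rates of the swapped branch *and* rescale
that branch's synthesis rates by the same factors, preserving its
steady-state output. Replacing degradation alone would change the branch's
steady state ~27-fold and with it the whole operating point — the slowed
CEBPA branch would then dominate the feedback and make every cell commit
immediately, while the accelerated slow branch would vanish and almost no
cell would differentiate; the steady-state-preserving swap isolates the
timescale question the variants are meant to ask.

**Phase conventions.** Commitment phases are recorded relative to the
forcing (`2π(t − θ₀)/T mod 2π`) and in the reporter convention, which maps
the forcing maximum — where CEBPA synthesis peaks — to reporter phase
1.4π, the phase where the measured CEBPA slope peaks. In that convention
the model's commitments concentrate around 1.8π (where the measured PPARG
slope peaks) and ~88% fall inside the π–2π gating window, without either
number being imposed.

**Rhythmicity of the mean synthesis rate.** `ensemble_rhythmicity()`
detrends the ensemble-mean total-PPARG slope with a one-period moving
average, subsamples to 4 h, and combines the permutation cosinor p-value
with an effect-size floor: rhythmic only if p < 0.05 *and* the circadian
amplitude is at least as large as the mean absolute secular trend. The
floor is needed because the ensemble mean of thousands of noiseless
trajectories is itself noiseless: the slow architectures retain a genuine
but ~7×-attenuated rhythm (the 30-h branch filters the forcing) that any
pure significance test detects. Measured relative amplitudes: full ≈ 2.5,
slow-slow ≈ 0.6, clock-on-slow ≈ 0.4, no-clock ≈ 0.01; the threshold 1
("modulation at least as large as the trend") sits in the gap.

## Problem sizes and determinism

The test suite runs generator populations of 80–2000 cells and model
ensembles of 1000–2000 cells (the published simulations used 20,000; all
ensemble statistics here are fractions or component locations that are
stable at n = 1000–2000, which keeps the whole suite under a minute).
Every stochastic step takes an explicit seed: generator populations derive
per-cell substreams from the master seed, ensembles seed the noise draw,
bootstraps and permutation tests seed their resampling. The Gaussian
mixture fit is deterministic by construction (model-based hierarchical
initialization).

## Known limitations

* The generator's waveform is a raised cosine; real reporter traces damp
  and deform, so period-recovery accuracy on real data will be worse than
  the ±0.4 h seen here.
* The forcing calibration (amplitude, mean, θ₀) is constrained only by
  qualitative behavior; quantitative statements that depend on absolute
  forcing strength (e.g. the exact differentiated fraction) should be read
  as illustrative.
* `rhythmicity_test()` assumes exchangeable residuals under the null; for
  strongly autocorrelated series use the detrend option and coarse
  sampling, as `ensemble_rhythmicity()` does, and interpret significance
  together with effect size.
* Commitment phases cannot be assigned before the first detected reporter
  peak; early-committing cells are excluded and counted rather than
  extrapolated, which slightly under-samples the first burst.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(generator_config(n_cells = 1000, condition = "rosi",
                                   seed = 7))
res <- run_pipeline(cfg)
print(res)
res$gmm          # commitment-time mixture: components ~26 h apart
res$fourier      # commitment-phase preference inside (pi, 2*pi)

p <- model_params()
ens <- simulate_ensemble(p, 2000, seed = 11)
fit_commitment_time_gmm(ens$commit_time[!is.na(ens$commit_time)] / 60)
ensemble_rhythmicity(ens)$rhythmic
```
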