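---
title: "Methods: aperiodic/periodic decomposition of STN input-output activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aperiodic/periodic decomposition of STN input-output activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stnio)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic validation can show. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## The signal model

Each recording site yields two streams. The LFP stream is the 3–200 Hz
band of the wide-band signal (zero-phase 4th-order Butterworth). The SPK
stream is the 300–6000 Hz band, full-wave rectified and mean-subtracted;
rectification is a demodulation step — a band-passed spike train carries no
power below its band, but the envelope of the rectified signal recovers the
discharge-rate modulation. Both streams' power spectra are modeled in
log-log coordinates as

`log10 P(f) = offset − α · log10 f + Σ_k h_k exp(−(f − c_k)² / (2 w_k²))`

an aperiodic 1/f^α trend plus Gaussian periodic peaks. The aperiodic
exponent α separates the streams: LFP behaves like Brown noise (α ≈ 2),
the rectified rate signal like white noise (α ≈ 0). Periodic beta activity
is compared *after* removing the trend ("whitening"):
`P_w(f) = P(f) · f^α` per bin over 3–70 Hz, or equivalently on spectral
magnitudes in the time domain (Hann window → FFT → scale magnitudes by
f^α with the exponent fitted to the magnitude spectrum → inverse FFT →
Welch re-estimate). Outside 3–70 Hz the time-domain path zeros the
magnitudes so both paths share one frequency support; the Hann window's
amplitude distortion is not compensated before the Welch re-estimate (the
paths are compared through peak locations, which windowing does not move).

## Spectral estimation

Welch PSDs use 2-s Hamming windows with 50% overlap, giving an exact 0.5 Hz
grid; sites shorter than 1.5 windows (< 3 s) are excluded, not erred.
Segments are not detrended by default (constant detrending is available as
an option). Mains bins (±2 Hz around 50 Hz and harmonics) are replaced by
the mean of the nearest clean bin on each side; the repair is idempotent
and single-sided at grid edges. Spectra are normalized by total 3–200 Hz
power (NPSD, scale-free) and optionally z-scored per frequency bin against
the mean and SD of the first ten pre-STN sites ("frequency and distance"
normalization). The per-bin SD uses the ten baseline sites only — with so
few baseline samples the z-maps are noisy for single trajectories and only
stabilize in population averages, which is why trajectory-level beta
statistics default to the frequency-normalized (not z-scored) variant.

## The spectral parameterization

The fitter implements the standard iterative procedure: a robust aperiodic
fit (fit, flatten, clip negative residuals, refit on the ≤ 2.5th-percentile
points), iterative peak extraction on the flattened spectrum (tallest
point; width guessed from the half-height crossing; subtract) until six
peaks or until no point exceeds 2·SD of the residual and the 0.05
log10-power floor, a joint bounded least-squares refinement of all
Gaussians (centers bounded within 1.5 guess-SD, heights non-negative,
widths within limits; Levenberg–Marquardt with deterministic,
data-derived initials so fits are reproducible), and a final aperiodic
refit on the peak-removed spectrum. R² and the mean absolute error are
computed in log10-power over the 3–70 Hz fit range; a zero-variance
spectrum yields an undefined R² reported as missing, never as 1.

Two settings deserve comment:

- `peak_width_limits = c(0.8, 12)` bounds the reported bandwidth (2·SD) of
  each peak.
- `peak_width_limits_per = c(0.02, 0)` is a frequency-proportional bound
  read as: the effective lower bandwidth limit at center frequency `cf` is
  `max(0.8, 0.02·cf)`; the zero second element disables a proportional
  upper bound. Its exact semantics are not fixed by any published
  definition; the interpretation is isolated in `effective_width_limits()`
  so it can be swapped.

One identifiability caveat: the three broad test-spectrum peaks
((18, 5, 1.5), (25, 8, 3), (35, 5, 2) as center/SD/height) sum to a curve
with only *two* local maxima, and the middle component's 16 Hz bandwidth
exceeds the 12 Hz cap. No fitter can return those three components from the
composite spectrum; the tests therefore assert fit fidelity (R², MAE) on
the composite and exact center recovery only for separated peaks.

## Beta features

The beta center frequency is the highest *local* maximum (strictly greater
than both neighbors) of a whitened/normalized PSD within 13–33 Hz; a
monotone spectrum yields a no-peak result that is excluded from paired
analyses. Bandwidths use topographic (findpeaks-style) prominence computed
within the full 3–70 Hz spectrum so shoulders are handled; the reference
height is the peak minus half (or 3/4, or 1/4) its prominence, flank
crossings are linearly interpolated between bracketing bins, and a flank
that never crosses is censored at the range edge and flagged. Pairs with
|Δ βCF| < 0.5 Hz (one bin) count as "equal" in the downshift summary; the
paired test is the two-tailed Wilcoxon signed-rank.

## Trajectory assembly

A trajectory is analyzable when pre-STN, motor, and non-motor subregions
are all present and each spans strictly more than 1 mm. Subregion borders
come from an upstream classifier and are treated as inputs; because they
are imprecise, sites within 0.5 mm of a border are dropped from subregion
averages ("safe boundaries"): motor and non-motor lose 0.5 mm at entry and
exit, pre-STN only its final 0.5 mm. The retained interval is inclusive of
its endpoints; a subregion no longer than 1 mm after trimming retains
nothing and is flagged. Sites are points, not intervals, and belong to the
subregion containing their depth. RMS outliers (beyond 3 interquartile
ranges outside the quartiles, type-7 quantiles, per trajectory per stream)
are excluded everywhere; when an outlier falls among the first ten sites,
the NRMS baseline is the mean of the remaining non-outlier baseline sites.

## The synthetic study generator

The generator is the package's stand-in for the clinical cohort and
defines the study conditions rather than adapting to tests:

- exponents per trajectory: LFP ~ N(2.20, 0.40), SPK ~ N(0.11, 0.22);
- βCFs per trajectory: LFP truncated-N(26, 3) on [14, 32] Hz (HiBeta),
  SPK truncated-N(17, 2) on [13.5, 20] Hz (LoBeta, downshifted);
- beta sine amplitude 0.5× the noise SD in both streams, SPK beta present
  only in the motor subregion;
- depth structure: ≥10 pre-STN sites at 400 µm, then 100 µm STN steps;
  4-s sites at 4096 Hz; default subregion lengths 4/3/3 mm;
- clinical responses: linear in the z-normalized aperiodic family with
  coefficients (0.5, −0.3, 0.4, 0.2) plus N(0, 0.3) noise; the DBS
  evaluation score is discretized to the −2…+2 ordinal scale.

Colored noise is synthesized spectrally (white Gaussian FFT scaled by
f^(−α/2)), so the in-band power law is exact; LFP components below 2.5 Hz
are zeroed because the emulated acquisition chain band-limits the LFP at
3 Hz and, for steep spectra, sub-band power would otherwise leak across
the Hamming window's sidelobes and bias the fitted exponent low. Brown
noise for the signal-level simulations is instead a cumulative sum of unit
Gaussian increments — the simplest exact-α=2 process — causally high-passed
at 0.1 Hz (the hardware filter it imitates is causal) with the first and
last quarters discarded, so only the settled middle half is analyzed. The
beta sine is generated at full pre-trim length and trimmed with the noise,
keeping phases aligned.

Spike placement: the membrane signal is Brown noise plus a 1.2·SD beta
sine; the threshold is the 60th percentile of that sine. Supra-threshold
samples are grouped *per beta cycle* and each cycle receives one
Poisson(6) draw placed uniformly without replacement on its
supra-threshold samples. Grouping per contiguous run was rejected: noise
jitter fragments a single beta peak's crossing into several runs (a third
of runs are 1–2 samples long), which would multiply the draws and truncate
the counts, breaking the "mean 6 spikes per beta peak" contract that the
cycle-level grouping satisfies to within 5%.

Noise for the simulated test spectra is calibrated by rescaling the drawn
Gaussian vector so its realized mean absolute value equals the target MAE
exactly; an iterative search over the noise SD would only approximate what
the rescaling achieves in closed form. R² values are averaged on the atanh
scale and back-transformed (values of exactly 1 are clipped to 1 − 1e−12).

What the generator does **not** emulate: volume conduction geometry and
its pre-STN beta leakage, electrode impedance, the 44 kHz hardware chain,
non-sinusoidal/bursting beta, spatial correlation between neighboring
sites, and phenotype-dependent signal differences. Passing tests therefore
show the *pipeline* is correct and calibrated under the stated statistical
structure — not that real STN recordings satisfy that structure.

One known simulation-level discrepancy is documented by the tests: adding
Poisson spikes of amplitude 3×max(beta) to the membrane signal raises a
broadband floor that exceeds the Brown-noise PSD near the top of the 3–70
Hz fit range, so the fitted exponent of the spiked signal drops by ~0.3
relative to the spike-free membrane even though the spectrum below ~30 Hz
is unchanged. The tests assert the low-frequency invariance, not
full-range exponent equality.

## GLM layer

Predictors and responses are z-normalized before fitting; interaction
designs are products of z-scored members (4 terms at zeroth order, 6
pairwise products at first order, 4 triple products plus the quadruple at
higher order — the higher-order design follows the five-term single-model
reading; separate three- and four-way models are available by fitting the
terms individually). AIC is `n·ln(RSS/n) + 2k` with `k` counting the
intercept and the residual variance, so comparisons are internally
consistent; rank-deficient fits are flagged and report no AIC. The model
p-value is the F-test against the intercept-only model — also for the
interaction-only designs, which contain no main effects. The two-factor
ANOVA of aperiodic parameters uses Type II sums of squares (main effects
unconfounded by interaction ordering on unbalanced data; this can diverge
from tools whose default is Type I), with Bonferroni-corrected pairwise
cell comparisons. The ordinal DBS evaluation score is fitted with the same
Gaussian identity link as the other responses; an ordinal model is out of
scope.

## Problem sizes and determinism

The test suite and the analysis scripts choose desk-scale problem sizes:
1000 realizations for the averaged simulation spectra (estimator SD of the
averaged log-PSD ~0.02, well inside the ±0.1/±0.05 exponent tolerances);
20 repeats per goodness-of-fit cell over the full exponent grid at three
representative noise levels (0.005, 0.065, 0.145 — the ends and middle of
the 0.005–0.145 range); synthetic studies of 6–8 patients with 2 mm motor
and non-motor subregions for parameter recovery (≈15 retained sites per
subregion after safe-boundary trimming); 40 signal-free patients for
coefficient recovery; 500 replicates for the 5% type-I-error calibration
of the Wilcoxon, ANOVA, and permutation suites. All generators consume the
R RNG only, so every result is bit-reproducible given (config, seed), and
the pipeline itself is deterministic.

## Known limitations

- The container is a plain-text directory layout; very large cohorts would
  want a binary store.
- The z-normalized (frequency + distance) beta statistics are unstable for
  single trajectories (10-site baseline); interpret them at population
  level.
- Coherence estimates from 4-s sites average only 3 segments and carry the
  corresponding positive bias (~1/3 under independence); they are reported,
  not bias-corrected.
- The spectral parameterization supports only the fixed (knee-free)
  aperiodic mode, and power-law vs log-normal behavior cannot be
  distinguished over 1.5 decades of frequency.
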