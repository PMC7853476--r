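---
title: "Methods: GAW/acoustic parameter extraction and correlation screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAW/acoustic parameter extraction and correlation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gawscreen)
```

## The problem and the model

During phonation the vocal folds chop the airstream from the lungs into a
train of flow pulses; the vocal tract then shapes these pulses into the
radiated acoustic signal. High-speed videoendoscopy observes the folds
directly, and the segmented glottal area waveform (GAW) — the area between
the folds over time, together with its left and right halves — is the
standard one-dimensional summary of their oscillation. `gawscreen` quantifies
both signals of a sustained-vowel recording with a battery of 49 parameters
and screens every GAW × acoustic parameter pair for linear (Pearson) and
general (distance-correlation) dependence under false-discovery-rate control.

Because clinical recordings are rarely shareable, the package carries a
synthetic-cohort generator whose recordings have known ground truth. All
tests of the extraction chain are recovery tests against that ground truth.

## The synthetic glottal pulse

One cycle of the unit pulse consists of, in phase order: a flat closed
plateau (fraction `plateau_frac` of the cycle, at the residual-gap level
`gap_rel`), a half-cosine opening ramp, a half-cosine closing ramp (the open
phase occupies `open_quotient` of the cycle, of which `closing_fraction` is
the closing ramp), and a closed remainder. The shape was chosen for its
closed-form landmarks: the peak position, ramp durations, plateau length and
residual gap are all elementary functions of the configuration, so the
glottal-dynamic measures (CQ, SQ, PQ, GGI, GAI) can be checked against exact
expectations.

Per-cycle periods are `round(fs_gaw/f0)/fs_gaw · (1 + δ_i)` with δ_i i.i.d.
Gaussian of standard deviation `jitter_rel`, truncated at ±3σ (multiplicative
period noise matches the cycle-to-cycle semantics of jitter measures);
quantizing the base period to the sample grid makes zero-jitter configs
exactly periodic, which pins down many oracle values. Per-cycle amplitudes
carry the analogous `shimmer_rel` perturbation. The left half is scaled by
`lr_amp_ratio/(1+lr_amp_ratio)` and delayed by `lr_phase_delay_rel` periods;
the right half is the complement, and the total GAW is their exact sample-wise
sum. The acoustic track evaluates the same pulse train at 40 kHz, takes the
first difference (the source derivative as radiation surrogate), passes it
through two-pole resonators at /i/-like formants (defaults 300/2300/3000 Hz
with 80/120/150 Hz bandwidths), and adds white noise at `acoustic_snr_db`.

Defaults mirror a typical clinical setup: 250 ms segments, GAW at 4000
samples/s, audio at 40 kHz, f0 within the 80–400 Hz phonation band. The
cohort samplers draw female f0 from 160–300 Hz and male f0 from 80–160 Hz;
disordered-group samplers shift jitter (1–3 %), shimmer (4–10 %), residual
gap (5–30 %) and left–right asymmetry upward relative to healthy ranges.
These shifts are illustrative: functional dysphonia is an umbrella diagnosis
with no published distributional parameters, so the disordered groups emulate
"more perturbed voices", not a calibrated clinical population.

### Ground truth is observable ground truth

A peak picker marks cycles at successive pulse maxima. When the period
jitters, the peak of a cycle moves *within* the cycle, so peak-to-peak
intervals are not identical to onset-to-onset periods. The generator
therefore recomputes its ground truth from the emitted pulse train at the
observable landmarks: realized periods are the continuous-time peak-to-peak
intervals of the composite (left + right) pulse, and realized amplitudes are
the peak-to-trough excursions of the peak-delimited cycles. Recovery tests
compare measurements against these observable quantities; remaining
disagreement is sample quantization (the sampled cycle-end peak, which the
half-open cycle interval excludes, can carry a deficit of a percent or two).

## What the generator does not emulate

Real GAWs carry segmentation errors, camera-motion artefacts, amplitude
drift, diplophonia and aperiodic breaks; real acoustics carry room noise,
reverberation and time-varying vocal-tract filtering. The generator's noise
is white and stationary, its pulse shape is fixed within a recording, and the
left/right halves differ only by scale and delay. Passing recovery tests
therefore demonstrate that the estimators are correct for well-behaved
quasi-periodic input, not that they are robust to every pathology of clinical
material. The resonator bank also delays the acoustic energy by its group
delay (~0.5 ms), so cross-modal alignment checks allow a few GAW samples of
lag rather than exact coincidence.

## Cycle detection

The dominant period is the argmax of the normalized autocorrelation over lags
in the 80–400 Hz band; a peak below 0.2 raises an unvoiced-signal error.
Cycle boundaries are local maxima (minima for the minimum-based variant on
the negated signal) with topographic prominence ≥ 20 % of the signal's
peak-to-peak range and spacing ≥ 0.5 × the dominant period; both thresholds
are arguments. Partial cycles at the segment edges are discarded, and cycles
are half-open sample intervals `[b_i, b_{i+1})` anchored at the maximum
sample itself. For the acoustic track the battery tightens the spacing to
0.7 × the dominant period: vocal-tract resonances ring between glottal pulses
and can create a prominent mid-cycle peak that the looser GAW criterion would
mistake for a cycle boundary (observed as period-halving on low-f0 male
configurations).

All GAW-based parameters use cycles detected on the total GAW; the left and
right halves inherit those boundaries unchanged. Acoustic cycles are detected
independently on the acoustic signal. Phase-asymmetry parameters use
minimum-based cycles, so that each cycle contains one full open phase and
both halves peak inside it.

## Parameter definitions and conventions

* Periods, amplitudes, energies: `T_i` from boundary differences; `A_i` =
  within-cycle max − min (robust to the residual-gap offset); `E_i` = sum of
  squared mean-removed samples.
* `F0[Mean]`/`F0[Std]`: mean and sample SD of the inverse cycle lengths.
* `MJit` = mean |ΔT| (ms); `Jit(%)` = 100·MJit/mean(T); `PVI` =
  100·sd(T)/mean(T); `MShim` = mean |20·log10(A_{i+1}/A_i)| dB; `AVI` = sd of
  20·log10(A_i/mean A) dB (acoustic only); `EPF` = 100·mean|ΔE|/mean(E) (GAW
  only). PVI, AVI and EPF use coefficient-of-variation forms, each behind its
  own function so an alternative convention is a one-line change. Sample
  (n−1) standard deviations are used throughout, so all `[Std]` parameters
  are bit-reproducible.
* Landmarks within a maximum-based cycle: closing = peak → earliest minimum
  (ties break to the earliest sample), opening = minimum → next peak, plateau
  = total time within 5 % (configurable `plateau_eps`) of the cycle minimum.
  `CQ` = closing/T, `SQ` = opening/closing, `PQ` = plateau/T, `GGI` =
  A_min/A_max (clamped at 0 when noise pushes the minimum below zero), `GAI`
  = (mean − min)/(max − min). Note the cosine ramps dwell near the minimum,
  so even a plateau-free pulse has a small positive PQ; the tests account for
  this analytically.
* Symmetry (left vs right): signed measures are positive when the right half
  leads (phase) or is larger (amplitude/area); indices are min/max ratios in
  (0, 1]; `WaSI` is the mean per-cycle Pearson correlation of the two halves.
  The three `*Index` parameters carry `[Std]`, which together with the seven
  `[Mean]`s yields the 10 symmetry parameters of the 25 + 10 + 14 split.
* `CPP`: dB-magnitude cepstrum of the dB spectrum of the single Hann-windowed
  segment (zero-padded to a power of two, dynamic range clamped 300 dB below
  the spectral peak), peak searched in the 2.5–12.5 ms quefrency band,
  baseline from a least-squares line over 1–12.5 ms. A 3-bin moving average
  of the cepstrum magnitude before peak picking tames the extreme-value noise
  floor a single-segment cepstrum otherwise exhibits; at SNRs below ~10 dB
  the estimator still saturates toward that floor, which is a known property
  of single-segment cepstral prominence rather than a defect. No frame
  averaging (no CPPS variant).
* `HNR`: cycles resampled to the rounded mean length, HNR = 10·log10 of mean
  waveform energy × N over residual energy, capped at +60 dB. `SNR_Q` uses a
  per-cycle least-squares amplitude match to the mean waveform before taking
  the same ratio; on stationary input both agree within ~1 dB. `WMC` is the
  Pearson correlation of adjacent cycles after resampling to a common length.
* `NNE`: Hann spectrum of the whole segment, harmonic bands of full width
  f0/4 around each harmonic, analysis band up to Nyquist (GAW) or 5 kHz
  (acoustic); NNE = 10·log10(E_inter/E_total). `SNR_K` applies the same split
  framewise (4 cycles per frame, rectangular window, no padding — a frame
  spans an exact number of cycles, so harmonics fall on DFT bins and the
  split is leakage-free up to jitter), reporting mean and SD over frames,
  frames capped at +60 dB.

The battery emits exactly 35 GAW-based (25 + 10 symmetry) and 14 acoustic
parameters in a frozen schema (`parameter_schema()`); failed sub-computations
leave explicit `NA` markers, and failure of one track never blanks the other.

## The correlation screen

Per gender, healthy and disordered subjects are merged (parameters are
expected to scatter across both). All 35 × 14 pairs get a Pearson coefficient
with the t-distribution p-value and a distance correlation with a seeded
permutation p-value, `p = (1 + #{dcor_perm ≥ dcor_obs})/(1 + n_perm)`,
default 1000 permutations (the permutation count is an argument; 200 is the
floor). The double-centered distance matrices of x are reused across
permutations, and the distance variance of y is permutation-invariant, so a
permutation costs one Hadamard product. Benjamini–Yekutieli adjustment is
applied within each (gender × coefficient-type) family of 490 tests —
separate families for PCC and DCC, since the two coefficient types answer
different questions and merging them would couple their corrections. A pair
is *relevant* when its adjusted p < 0.05 and |coefficient| ≥ 0.3, and is
binned by the Mukaka rule of thumb (negligible/low/moderate/high/very high at
0.3/0.5/0.7/0.9). Missing values are handled by pairwise-complete deletion,
preserving n per test. Norm tables report n, min, max, mean, median, sample
SD, moment skewness g1 = m3/m2^{3/2} and excess kurtosis m4/m2² − 3 (1/n
central moments), with NA below the minimal n (2/3/4 for SD/skewness/
kurtosis) and for constant columns.

## Numerical and design choices

* Degenerate inputs error early with specific messages (constant signals,
  unvoiced signals, too few cycles, zero amplitudes, flat cycles); the
  battery converts these errors into NA markers per parameter.
* Ties: earliest minimum within a cycle; peak picking keeps the higher peak
  when two candidates are closer than the spacing threshold.
* The +60 dB caps keep noise-free synthetic input finite without affecting
  any realistic operating point.
* Seeding: one master seed; cohort subjects derive per-subject seeds by fixed
  affine offsets, so cohorts are reproducible element-wise regardless of
  group sizes; permutation p-values derive per-pair seeds the same way.
* Problem sizes in the test-suite and acceptance computations (cohorts of
  tens of subjects, 200 null replicates, 200–1000 permutations) were chosen
  as the smallest sizes at which the checked quantities are stable; all
  scale linearly if larger studies are needed.

## Known limitations

Cycle detection assumes one dominant peak per cycle; strongly diplophonic or
subharmonic material would need a dedicated voicing model (only an unvoiced
error is provided). The acoustic model has fixed formants — no vowel
variation, no radiation model beyond differentiation. Jit(%) and PVI carry a
sampling floor at 4000 samples/s that grows with f0 (a one-sample boundary
shift is 10 % of a 400 Hz cycle); this is a property of the sampling grid,
demonstrated analytically in the tests, and norm values at high f0 should be
read with it in mind. The disordered-group simulation is not clinically
calibrated, so group-level norm tables from synthetic cohorts demonstrate the
machinery, not clinical reference ranges.
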