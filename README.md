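# gawscreen

Voice research links the oscillation of the vocal folds — observed through
high-speed videoendoscopy as the **glottal area waveform** (GAW, the segmented
area between the folds over time, split into left and right halves) — to the
acoustic signal a listener actually hears. `gawscreen` implements the full
analysis chain for synchronized GAW/acoustic recordings of sustained
phonation:

* **cycle detection** — maximum- and minimum-based oscillation cycles on GAW
  and acoustic tracks (each cycle starts at a sufficiently distinct local
  maximum, operationalized as topographic prominence ≥ 20 % of peak-to-peak
  with spacing ≥ 0.5 × the dominant period; left/right halves inherit the
  total-GAW cycle grid);
* **a 49-parameter battery** per recording — 14 acoustic and 35 GAW-based
  parameters (25 ordinary + 10 left–right symmetry): fundamental frequency
  F0 [Mean]/[Std] from inverse cycle lengths; perturbation measures MJit,
  Jit(%), PVI, MShim, AVI, EPF; glottal-dynamic quotients CQ, SQ, PQ, GGI,
  GAI; symmetry measures PhA(I), AmS(I), SpS(I), WaSI; and noise measures
  CPP, HNR, WMC, NNE, SNR_K, SNR_Q;
* **a correlation screen** — for each gender (healthy and disordered merged),
  Pearson (PCC) and distance correlation (DCC, with seeded permutation
  p-values) for all 35 × 14 GAW × acoustic pairs, Benjamini–Yekutieli FDR
  control at 5 % per (gender × coefficient) family, and relevance flags
  (adjusted p < 0.05 **and** |coefficient| ≥ 0.3) with Mukaka magnitude
  categories;
* **norm tables** — per group (healthy/disordered × female/male) minimum,
  maximum, mean, median, standard deviation, skewness and kurtosis of every
  parameter;
* **a synthetic-cohort generator** — seeded, ground-truth-carrying emulation
  of sustained /i/ phonation: quasi-periodic glottal pulses (80–400 Hz,
  half-cosine opening/closing ramps, flat closed plateau) with controllable
  jitter, shimmer, residual glottal gap, left–right amplitude ratio and phase
  delay, GAW measurement noise, and an acoustic counterpart rendered from the
  same pulse train through a source–filter model (differentiated glottal area
  through /i/-like formant resonators, plus white noise at a configurable
  SNR). GAW tracks are sampled at 4000 samples/s and 250 ms, the acoustic
  track at 40 kHz, matching typical clinical recording setups.

The distance correlation of two samples is estimated from the double-centered
pairwise distance matrices *A*, *B*:

    dCov² = mean(A ∘ B),   dCor = dCov / sqrt(dVar_x · dVar_y)

and lies in [0, 1]; it is 0 (in the population) only under independence, so
the screen captures non-linear as well as linear dependence. The
Benjamini–Yekutieli step-up procedure (`p.adjust(..., "BY")`) controls the
false discovery rate under arbitrary dependence between the 490 tests of a
family.

## Worked example

```r
library(gawscreen)

cfg <- synth_config(f0_hz = 220, jitter_rel = 0.01, shimmer_rel = 0.04,
                    gap_rel = 0.1, lr_amp_ratio = 0.85, seed = 42)
sim <- simulate_recording(cfg)
pv <- extract_parameters(sim$recording)
round(unlist(pv[c("gaw_f0_mean", "gaw_jit_pct", "gaw_ggi_mean",
                  "gaw_amsi_mean", "gaw_cpp", "ac_f0_mean", "ac_hnr")]), 3)
#>   gaw_f0_mean   gaw_jit_pct  gaw_ggi_mean gaw_amsi_mean       gaw_cpp
#>       222.324         1.677         0.095         0.853        14.008
#>    ac_f0_mean        ac_hnr
#>       222.336        19.066
```

The battery recovers the injected configuration: GAW and acoustic mean F0
agree (both tracks share the pulse train), the measured residual-gap index
GGI ≈ 0.095 matches the configured `gap_rel = 0.1`, and the amplitude
symmetry index ≈ 0.85 matches `lr_amp_ratio = 0.85`. Jit(%) of 1.68 reflects
the injected 1 % jitter plus the sample-quantization floor of an 18-sample
cycle at 4000 samples/s.

A cohort-level screen:

```r
co <- simulate_cohort(c(NF = 12, FDF = 6, NM = 8, FDM = 4), seed = 1)
params <- extract_cohort(co)
scr <- run_screen(params, coefficients = "pcc")
scr[scr$gaw_param == "gaw_f0_mean" & scr$acoustic_param == "ac_f0_mean",
    c("gender", "n", "pcc", "pcc_p_adj", "relevant_pcc", "category_pcc")]
#>  gender  n    pcc pcc_p_adj relevant_pcc category_pcc
#>  female 18 0.9997 4.452e-24         TRUE    very high
#>    male 12 0.9954 5.405e-08         TRUE    very high
```

The GAW-F0 × acoustic-F0 pair is flagged relevant at the "very high"
magnitude in both genders — the expected signature of a shared oscillation
source. `norm_table(params)` tabulates the per-group descriptive statistics
of all 49 parameters.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "gaw_pipeline.R", package = "gawscreen")`) with
subcommands `simulate`, `extract`, `screen`, `norms` and `all`.

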