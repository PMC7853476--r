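# Noise-free, perturbation-free base configuration used across tests.
clean_cfg <- function(...) {
  synth_config(jitter_rel = 0, shimmer_rel = 0, gaw_noise_rel = 0,
               acoustic_snr_db = Inf, ...)
}

# Strictly periodic pulse-train GAW (total track) with its detected cycles.
clean_gaw <- function(f0 = 160, seed = 3, ...) {
  rec <- simulate_recording(clean_cfg(f0_hz = f0, seed = seed, ...))$recording
  list(rec = rec, cycles = detect_cycles(rec$gaw_total, rec$fs_gaw))
}

# A sampled sine at the GAW rate, 250 ms by default.
test_sine <- function(f0 = 100, fs = 4000, duration = 0.25) {
  sin(2 * pi * f0 * seq(0, duration - 1 / fs, by = 1 / fs))
}
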