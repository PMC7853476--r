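test_that("cycle table reports exact periods, amplitudes and energies", {
  s <- test_sine(100)
  cyc <- detect_cycles(s, 4000)
  tab <- cycle_table(s, cyc)
  expect_equal(nrow(tab), cyc$n_cycles)
  expect_true(all(tab$period_s == 0.010))
  expect_equal(max(abs(tab$amplitude - tab$amplitude[1])), 0, tolerance = 1e-9)
  expect_true(all(tab$energy > 0))
})

test_that("f0 statistics follow the inverse-period definition", {
  tab <- data.frame(period_s = c(0.010, 0.010, 0.010), amplitude = 1, energy = 1)
  expect_equal(f0_stats(tab), c(f0_mean = 100, f0_std = 0))
  tab2 <- data.frame(period_s = c(0.009, 0.010, 0.011), amplitude = 1, energy = 1)
  # hand arithmetic: (1000/9 + 100 + 1000/11) / 3
  expect_equal(f0_stats(tab2)[["f0_mean"]], (1000 / 9 + 100 + 1000 / 11) / 3)
  expect_error(f0_stats(tab2[1, ]), "std")
})

test_that("jitter measures match hand-computed values and scale laws", {
  tab <- data.frame(period_s = c(0.009, 0.011, 0.009), amplitude = 1, energy = 1)
  jm <- jitter_measures(tab)
  expect_equal(jm[["mjit_ms"]], 2.0)  # (|2| + |-2|) / 2 ms
  const <- data.frame(period_s = rep(0.01, 5), amplitude = 1, energy = 1)
  expect_equal(unname(jitter_measures(const)), c(0, 0, 0))
  # doubling all periods doubles MJit but leaves the normalized measures alone
  tab2 <- transform(tab, period_s = 2 * period_s)
  jm2 <- jitter_measures(tab2)
  expect_equal(jm2[["mjit_ms"]], 2 * jm[["mjit_ms"]])
  expect_equal(jm2[["jit_pct"]], jm[["jit_pct"]])
  expect_equal(jm2[["pvi"]], jm[["pvi"]])
  expect_error(jitter_measures(tab[1:2, ]), "too few")
})

test_that("shimmer measures are dB-ratio based and scale-free", {
  tab <- data.frame(period_s = 0.01, amplitude = c(1, 2, 1), energy = 1)
  am <- amplitude_measures(tab)
  expect_equal(am[["mshim_db"]], 20 * log10(2), tolerance = 1e-12)  # 6.0206 dB
  tab10 <- transform(tab, amplitude = amplitude * 10)
  expect_equal(amplitude_measures(tab10), am)
  eq <- data.frame(period_s = 0.01, amplitude = rep(3, 4), energy = 1)
  expect_equal(unname(amplitude_measures(eq)), c(0, 0))
  bad <- transform(tab, amplitude = c(1, 0, 1))
  expect_error(amplitude_measures(bad), "degenerate")
})

test_that("energy perturbation factor matches hand arithmetic", {
  tab <- data.frame(period_s = 0.01, amplitude = 1, energy = c(1, 2, 1))
  expect_equal(energy_perturbation(tab), 75)  # 100 * 1 / (4/3)
  expect_equal(energy_perturbation(transform(tab, energy = energy * 7)), 75)
  same <- data.frame(period_s = 0.01, amplitude = 1, energy = rep(2, 4))
  expect_equal(energy_perturbation(same), 0)
})

test_that("measured shimmer tracks the generator's per-cycle amplitudes", {
  sim <- simulate_recording(synth_config(f0_hz = 140, jitter_rel = 0,
                                         shimmer_rel = 0.05, gaw_noise_rel = 0,
                                         gap_rel = 0,
                                         acoustic_snr_db = Inf, seed = 21))
  cyc <- detect_cycles(sim$recording$gaw_total, 4000)
  tab <- cycle_table(sim$recording$gaw_total, cyc)
  rel <- tab$amplitude / mean(tab$amplitude)
  tr_amp <- sim$truth$amps  # observable peak-based cycle amplitudes
  k <- min(nrow(tab), length(tr_amp))
  tr_rel <- tr_amp[1:k] / mean(tr_amp[1:k])
  expect_lt(max(abs(rel[1:k] - tr_rel)), 0.02)
})

test_that("jitter and shimmer recovery is monotone in the injected levels", {
  seeds <- 1:20
  jit_levels <- c(0.003, 0.008, 0.015, 0.025)
  measured <- vapply(jit_levels, function(j) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_recording(synth_config(f0_hz = 120, jitter_rel = j,
                                             shimmer_rel = 0.02, seed = s))
      cyc <- detect_cycles(sim$recording$gaw_total, 4000)
      jitter_measures(cycle_table(sim$recording$gaw_total, cyc))[["jit_pct"]]
    }, 0))
  }, 0)
  expect_gte(cor(jit_levels, measured, method = "spearman"), 0.9)

  shim_levels <- c(0.01, 0.03, 0.06, 0.1)
  measured_s <- vapply(shim_levels, function(sh) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_recording(synth_config(f0_hz = 120, jitter_rel = 0.005,
                                             shimmer_rel = sh, seed = s))
      cyc <- detect_cycles(sim$recording$gaw_total, 4000)
      amplitude_measures(cycle_table(sim$recording$gaw_total, cyc))[["mshim_db"]]
    }, 0))
  }, 0)
  expect_gte(cor(shim_levels, measured_s, method = "spearman"), 0.9)
})

test_that("period quantization inflates GAW jitter at high f0", {
  # two perfectly regular oscillations whose true periods fall midway between
  # sample counts (40.5 and 13.25 samples): every measured period is off by up
  # to half a sample, and that fixed absolute floor is a larger fraction of
  # the short high-f0 cycle, inflating Jit(%) exactly as fewer data points
  # per cycle predict
  jit_of_sine <- function(period_samples) {
    f0 <- 4000 / period_samples
    s <- test_sine(f0)
    cyc <- detect_cycles(s, 4000)
    jitter_measures(cycle_table(s, cyc))[["jit_pct"]]
  }
  low <- jit_of_sine(40.5)    # ~98.8 Hz
  high <- jit_of_sine(13.25)  # ~302 Hz
  expect_gt(low, 0)  # quantization alone creates apparent jitter
  expect_gt(high, low)
  # and the floor matches the one-sample-shift arithmetic within a factor
  expect_lt(high, 2 * one_sample_period_shift_pct(4000, 4000 / 13.25))
})
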