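# shared fixtures: a clean periodic GAW pulse train and a noisy copy with
# exactly known SNR (cycles detected on the clean track, then transferred,
# so the injected noise is the only residual)
noisy_pair <- function(f0 = 125, snr_db = 20, seed = 9) {
  rec <- simulate_recording(clean_cfg(f0_hz = f0, seed = 3))$recording
  g <- rec$gaw_total
  set.seed(seed)
  nz <- rnorm(length(g))
  nz <- nz * sd(g) / sd(nz) / 10^(snr_db / 20)
  cyc <- detect_cycles(g, rec$fs_gaw)
  list(clean = g, noisy = g + nz, cycles = cyc, fs = rec$fs_gaw)
}

test_that("CPP separates periodic from aperiodic signals at equal RMS", {
  fs <- 40000
  t <- seq(0, 0.25 - 1 / fs, 1 / fs)
  pulse <- ifelse((t %% (1 / 150)) < 0.002, 1, 0)
  pulse <- pulse - mean(pulse)
  set.seed(4)
  noise <- rnorm(length(t))
  noise <- noise * sd(pulse) / sd(noise)
  expect_gt(cpp(pulse, fs) - cpp(noise, fs), 5)
  # amplitude scaling leaves CPP unchanged
  expect_equal(cpp(10 * pulse, fs), cpp(pulse, fs), tolerance = 1e-9)
})

test_that("the cepstral peak of a harmonic signal sits at its period", {
  fs <- 4000
  t <- seq(0, 0.25 - 1 / fs, 1 / fs)
  train <- ifelse((t %% (1 / 125)) < 0.003, 1, 0)
  got <- cpp(train, fs)
  expect_lte(abs(attr(got, "quefrency_s") - 1 / 125), 2 / fs)
  rec <- simulate_recording(clean_cfg(f0_hz = 100, seed = 19))$recording
  got2 <- cpp(rec$gaw_total, fs)
  expect_lte(abs(attr(got2, "quefrency_s") - 1 / 100), 2 / fs)
})

test_that("waveform-matching HNR recovers an injected SNR", {
  p <- noisy_pair(snr_db = 20)
  cyc_n <- transfer_cycles(p$cycles, p$noisy)
  expect_equal(hnr_waveform(p$noisy, cyc_n), 20, tolerance = 2)
  # strictly periodic input hits the cap
  expect_equal(hnr_waveform(p$clean, p$cycles), 60)
  # noise only: residual dominates the mean waveform
  set.seed(11)
  nz <- rnorm(length(p$clean))
  expect_lt(hnr_waveform(nz, transfer_cycles(p$cycles, nz)), 0)
})

test_that("waveform matching coefficients behave on periodic and mixed shapes", {
  p <- noisy_pair()
  w <- wmc(p$clean, p$cycles)
  expect_equal(unname(w), c(1, 1), tolerance = 1e-6)
  # alternating shapes A,B,A,B...: WMC_Mean equals corr(A, B)
  m <- 40
  u <- seq(0, 1 - 1 / m, 1 / m)
  A <- sin(pi * u)
  B <- sin(pi * u)^3 + 0.3 * cos(2 * pi * u)
  sig <- c(rep(c(A, B), 6), A)
  cyc <- structure(list(boundaries = as.integer(seq(0, 12 * m, by = m)),
                        basis = "maximum", fs = 4000, n_cycles = 12L,
                        signal_length = length(sig)), class = "cycle_set")
  expect_equal(wmc(sig, cyc)[["wmc_mean"]], cor(A, B), tolerance = 1e-9)
  # heavy noise: the best pair beats the average pair
  wn <- wmc(p$noisy, transfer_cycles(p$cycles, p$noisy))
  expect_lt(wn[["wmc_mean"]], wn[["wmc_max"]])
})

test_that("normalized noise energy tracks spectral noise content", {
  p <- noisy_pair()
  expect_lt(nne(p$clean, p$fs, 125), -20)
  expect_gt(nne(p$noisy, p$fs, 125), nne(p$clean, p$fs, 125))
  # white noise: NNE ~ band-occupancy fraction of inter-harmonic bins
  set.seed(5)
  wn <- rnorm(10000)
  cfg <- spectral_config()
  got <- nne(wn, 4000, 200, cfg)
  # uniform spectral density oracle: expected energy share = bin share
  x <- (wn - mean(wn)) * (0.5 - 0.5 * cos(2 * pi * (seq_along(wn) - 1) / (length(wn) - 1)))
  nfft <- 2^ceiling(log2(length(x)))
  freq <- (seq_len(nfft %/% 2) - 1) * 4000 / nfft
  in_band <- freq > 0 & freq <= 2000
  harm <- abs(freq - pmax(1, round(freq / 200)) * 200) <= 25
  expected <- 10 * log10(sum(in_band & !harm) / sum(in_band))
  expect_equal(got, expected, tolerance = 1)
  expect_error(nne(wn, 4000, 50), "configuration")
})

test_that("framewise SNR recovers injected noise and flags nonstationarity", {
  p <- noisy_pair(snr_db = 20)
  sk <- snr_klingholz(p$noisy, p$fs, transfer_cycles(p$cycles, p$noisy))
  expect_equal(sk[["snrk_mean"]], 20, tolerance = 3)
  # stationary clean pulse train: framewise spread stays small
  sk0 <- snr_klingholz(p$clean, p$fs, p$cycles)
  expect_lte(sk0[["snrk_std"]], 1)
  # clean first half, noisy second half: the spread blows up
  half <- length(p$clean) %/% 2
  mixed <- p$clean
  set.seed(13)
  nz <- rnorm(length(mixed) - half)
  mixed[(half + 1):length(mixed)] <- mixed[(half + 1):length(mixed)] +
    nz * sd(p$clean) / sd(nz) / 10^(10 / 20)
  skm <- snr_klingholz(mixed, p$fs, transfer_cycles(p$cycles, mixed))
  expect_gt(skm[["snrk_std"]], 3)
})

test_that("matched-waveform SNR agrees with HNR and hits the cap when periodic", {
  p <- noisy_pair(snr_db = 20)
  expect_equal(snr_qi(p$clean, p$cycles), 60)
  cyc_n <- transfer_cycles(p$cycles, p$noisy)
  expect_lte(abs(snr_qi(p$noisy, cyc_n) - hnr_waveform(p$noisy, cyc_n)), 1)
})

test_that("all noise measures move monotonically along a noise ladder", {
  snrs <- c(Inf, 30, 20, 10, 5)
  vals <- sapply(snrs, function(s) {
    cfg <- synth_config(f0_hz = 140, jitter_rel = 0, shimmer_rel = 0,
                        gaw_noise_rel = 0, acoustic_snr_db = Inf, seed = 3)
    rec <- simulate_recording(cfg)$recording
    g <- rec$gaw_total
    if (is.finite(s)) {
      set.seed(17)
      nz <- rnorm(length(g))
      g <- g + nz * sd(g) / sd(nz) / 10^(s / 20)
    }
    cyc <- transfer_cycles(detect_cycles(rec$gaw_total, 4000), g)
    c(hnr = hnr_waveform(g, cyc),
      snrk = snr_klingholz(g, 4000, cyc)[["snrk_mean"]],
      snrq = snr_qi(g, cyc),
      nne = nne(g, 4000, 140),
      cpp = cpp(g, 4000))
  })
  expect_true(all(diff(vals["hnr", ]) < 0))
  expect_true(all(diff(vals["snrk", ]) < 0))
  expect_true(all(diff(vals["snrq", ]) < 0))
  expect_true(all(diff(vals["nne", ]) > 0))
  expect_true(all(diff(vals["cpp", ]) < 0))
})

test_that("dB noise measures are invariant to uniform amplitude scaling", {
  p <- noisy_pair()
  cyc <- transfer_cycles(p$cycles, p$noisy)
  for (k in c(0.1, 10)) {
    expect_equal(hnr_waveform(k * p$noisy, cyc), hnr_waveform(p$noisy, cyc),
                 tolerance = 1e-9)
    expect_equal(snr_qi(k * p$noisy, cyc), snr_qi(p$noisy, cyc),
                 tolerance = 1e-9)
    expect_equal(nne(k * p$noisy, p$fs, 125), nne(p$noisy, p$fs, 125),
                 tolerance = 1e-9)
    expect_equal(snr_klingholz(k * p$noisy, p$fs, cyc),
                 snr_klingholz(p$noisy, p$fs, cyc), tolerance = 1e-9)
  }
})
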