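#' Spectral analysis configuration
#'
#' Settings shared by the cepstral and spectral noise measures: Hann window,
#' zero-padding to the next power of two, the quefrency search band derived
#' from the 80-400 Hz phonation band, the relative harmonic bandwidth used by
#' the harmonic/noise spectral splits, and the frame length (in cycles) of the
#' framewise SNR.
#'
#' @param f_min,f_max Phonation band in Hz (quefrency band = [1/f_max, 1/f_min]).
#' @param harmonic_bw_frac Half-width of each harmonic band as a fraction of
#'   f0 is \code{harmonic_bw_frac / 2} (i.e. full bandwidth f0/4 by default).
#' @param frame_cycles Cycles per frame for the framewise SNR (default 4).
#' @param acoustic_band_hz Upper edge of the acoustic analysis band (Hz).
#' @return A \code{spectral_config} list.
#' @export
spectral_config <- function(f_min = 80, f_max = 400, harmonic_bw_frac = 0.25,
                            frame_cycles = 4, acoustic_band_hz = 5000) {
  stopifnot(f_min > 0, f_max > f_min, harmonic_bw_frac > 0)
  structure(list(f_min = f_min, f_max = f_max,
                 harmonic_bw_frac = harmonic_bw_frac,
                 frame_cycles = frame_cycles,
                 acoustic_band_hz = acoustic_band_hz),
            class = "spectral_config")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Cepstral Peak Prominence
#'
#' Computes the dB-magnitude cepstrum of the dB log-magnitude spectrum of the
#' whole Hann-windowed segment (zero-padded to the next power of two), locates the
#' cepstral peak within the quefrency band corresponding to 80-400 Hz, fits a
#' least-squares regression line to the cepstrum over quefrencies 1-12.5 ms,
#' and reports the peak height above the line value at the peak quefrency.
#' Invariant to uniform amplitude scaling.
#'
#' @param signal Numeric vector (>= 1024 samples after zero-padding).
#' @param fs Sampling rate in samples/s.
#' @param cfg A \code{spectral_config}.
#' @param smooth_bins Width (quefrency bins) of the moving average applied to
#'   the cepstrum magnitude before peak picking; reduces the estimator's
#'   noise floor (1 disables).
#' @return CPP in dB, with the located peak quefrency (s) attached as
#'   attribute \code{"quefrency_s"}.
#' @export
cpp <- function(signal, fs, cfg = spectral_config(), smooth_bins = 3) {
  if (next_pow2(length(signal)) < 1024)
    stop("too short: CPP needs >= 1024 samples after zero-padding", call. = FALSE)
  if (all(signal == signal[1])) stop("degenerate: constant signal", call. = FALSE)
  x <- (signal - mean(signal)) * hann_window(length(signal))
  nfft <- next_pow2(length(x))
  spec_db <- 20 * log10(pmax(Mod(stats::fft(c(x, numeric(nfft - length(x))))),
                             .Machine$double.xmin))
  # clamp the dynamic range 300 dB below the spectral peak: numerically-zero
  # bins of noise-free signals would otherwise dominate the cepstrum; the
  # clamp is relative, so scale invariance is preserved
  spec_db <- pmax(spec_db, max(spec_db) - 300)
  # cepstrum in dB (log magnitude of the spectrum of the log spectrum);
  # uniform amplitude scaling only shifts quefrency bin 0, so CPP is scale-free
  cmag <- Mod(stats::fft(spec_db))
  if (smooth_bins > 1) {
    # light quefrency smoothing tames the extreme-value noise floor of the
    # single-segment cepstrum without blurring the f0 peak
    sm <- stats::filter(cmag, rep(1 / smooth_bins, smooth_bins), sides = 2)
    cmag <- ifelse(is.na(sm), cmag, as.numeric(sm))
  }
  ceps <- 20 * log10(pmax(cmag, .Machine$double.xmin))
  q <- seq_len(nfft) - 1  # quefrency in samples
  band <- which(q / fs >= 1 / cfg$f_max & q / fs <= 1 / cfg$f_min)
  peak_idx <- band[which.max(ceps[band])]
  fit_idx <- which(q / fs >= 0.001 & q / fs <= 0.0125)
  fit <- stats::lm.fit(cbind(1, q[fit_idx]), ceps[fit_idx])
  baseline <- fit$coefficients[1] + fit$coefficients[2] * q[peak_idx]
  out <- unname(ceps[peak_idx] - baseline)
  attr(out, "quefrency_s") <- q[peak_idx] / fs
  out
}

# resample a vector to length m by linear interpolation over a common [0,1] grid
resample_to <- function(x, m) {
  stats::approx(seq(0, 1, length.out = length(x)), x,
                seq(0, 1, length.out = m))$y
}

cycle_matrix <- function(signal, cycles) {
  spans <- cycle_spans(cycles)
  m <- round(mean(lengths(spans)))
  t(vapply(spans, function(s) resample_to(signal[s], m), numeric(m)))
}

#' Harmonics-to-Noise Ratio (waveform-matching)
#'
#' Resamples each cycle to the rounded mean cycle length, computes the mean
#' cycle waveform, and reports the ratio of the mean-waveform energy (summed
#' over all cycles) to the residual energy of the individual cycles around
#' the mean waveform, in dB. Capped at +60 dB for (numerically) noise-free
#' periodic input.
#'
#' @param signal Numeric vector.
#' @param cycles A \code{cycle_set}.
#' @param cap_db Ceiling applied when the residual underflows (default 60).
#' @return HNR in dB.
#' @export
hnr_waveform <- function(signal, cycles, cap_db = 60) {
  if (cycles$n_cycles < 3)
    stop("too few cycles: HNR needs >= 3", call. = FALSE)
  w <- cycle_matrix(signal, cycles)
  w <- w - mean(w)
  wbar <- colMeans(w)
  num <- nrow(w) * sum(wbar^2)
  den <- sum(sweep(w, 2, wbar)^2)
  if (den <= num * 10^(-cap_db / 10)) return(cap_db)
  10 * log10(num / den)
}

#' Waveform Matching Coefficients
#'
#' For each adjacent cycle pair, both cycles are resampled to a common length
#' and their Pearson correlation is taken; reported are the maximum and the
#' mean over pairs. Pairs with a constant cycle are skipped.
#'
#' @param signal Numeric vector.
#' @param cycles A \code{cycle_set}.
#' @return Named vector \code{c(wmc_max, wmc_mean)} (a.u.).
#' @export
wmc <- function(signal, cycles) {
  if (cycles$n_cycles < 3)
    stop("too few cycles: WMC needs >= 3", call. = FALSE)
  spans <- cycle_spans(cycles)
  r <- vapply(seq_len(length(spans) - 1), function(i) {
    a <- signal[spans[[i]]]; b <- signal[spans[[i + 1]]]
    m <- max(length(a), length(b))
    a <- resample_to(a, m); b <- resample_to(b, m)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("degenerate: all cycle pairs constant", call. = FALSE)
  c(wmc_max = max(r), wmc_mean = mean(r))
}

# power spectrum (magnitude squared) of the Hann-windowed, zero-padded signal,
# plus the frequency axis of the first half
power_spectrum <- function(signal, fs) {
  x <- (signal - mean(signal)) * hann_window(length(signal))
  nfft <- next_pow2(length(x))
  p <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2
  half <- seq_len(nfft %/% 2)
  list(freq = (half - 1) * fs / nfft, power = p[half])
}

harmonic_mask <- function(freq, f0, bw, f_hi) {
  in_band <- freq > 0 & freq <= f_hi
  k <- pmax(1, round(freq / f0))
  harm <- abs(freq - k * f0) <= bw / 2
  list(harmonic = in_band & harm, inter = in_band & !harm, in_band = in_band)
}

#' Normalized Noise Energy
#'
#' Splits the magnitude-squared spectrum into harmonic bands (within
#' bandwidth f0/4 around each multiple of the mean fundamental frequency) and
#' inter-harmonic bands inside the analysis band (full Nyquist band for the
#' GAW, 0-5 kHz for the acoustic signal), and reports
#' \eqn{10 \log_{10}(E_{inter} / E_{total})}. Always <= 0 dB; less negative
#' means noisier.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in samples/s.
#' @param f0_mean Mean fundamental frequency in Hz (80-400).
#' @param cfg A \code{spectral_config}.
#' @param band_hz Upper edge of the analysis band; defaults to \code{fs/2}
#'   capped at \code{cfg$acoustic_band_hz} for acoustic-rate signals.
#' @return NNE in dB.
#' @export
nne <- function(signal, fs, f0_mean, cfg = spectral_config(), band_hz = NULL) {
  if (f0_mean < cfg$f_min || f0_mean > cfg$f_max)
    stop("configuration error: f0_mean outside 80-400 Hz", call. = FALSE)
  if (is.null(band_hz))
    band_hz <- if (fs / 2 > cfg$acoustic_band_hz) cfg$acoustic_band_hz else fs / 2
  ps <- power_spectrum(signal, fs)
  m <- harmonic_mask(ps$freq, f0_mean, cfg$harmonic_bw_frac * f0_mean, band_hz)
  e_inter <- sum(ps$power[m$inter])
  e_total <- sum(ps$power[m$in_band])
  10 * log10(e_inter / e_total)
}

#' Framewise Signal-to-Noise Ratio (harmonic/noise spectral split)
#'
#' Partitions the signal into consecutive frames of a fixed number of cycles;
#' in each frame the spectrum is split into harmonic and inter-harmonic energy
#' (as in \code{\link{nne}}, with the frame-local fundamental frequency) and
#' the frame SNR is \eqn{10\log_{10}(E_{harm}/E_{noise})}, capped at +60 dB
#' for numerically noise-free frames. Reported are the mean and sample
#' standard deviation over frames.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate.
#' @param cycles A \code{cycle_set} on the signal.
#' @param cfg A \code{spectral_config} (frame length via \code{frame_cycles}).
#' @return Named vector \code{c(snrk_mean, snrk_std)} in dB.
#' @export
snr_klingholz <- function(signal, fs, cycles, cfg = spectral_config()) {
  fc <- cfg$frame_cycles
  n_frames <- cycles$n_cycles %/% fc
  if (n_frames < 2)
    stop("too few frames: need >= 2 frames of ", fc, " cycles", call. = FALSE)
  b <- cycles$boundaries + 1L
  band_hz <- if (fs / 2 > cfg$acoustic_band_hz) cfg$acoustic_band_hz else fs / 2
  snr <- vapply(seq_len(n_frames), function(j) {
    i0 <- b[(j - 1) * fc + 1]
    i1 <- b[j * fc + 1] - 1L
    x <- signal[i0:i1]
    f0 <- fc * fs / length(x)
    # rectangular window, no padding: the frame spans an exact number of
    # cycles, so harmonics fall on DFT bins and the harmonic/noise split is
    # leakage-free up to jitter and sample quantization
    x <- x - mean(x)
    p <- Mod(stats::fft(x))^2
    half <- seq_len(length(x) %/% 2)
    ps <- list(freq = (half - 1) * fs / length(x), power = p[half])
    m <- harmonic_mask(ps$freq, f0, cfg$harmonic_bw_frac * f0, band_hz)
    e_h <- sum(ps$power[m$harmonic])
    e_n <- sum(ps$power[m$inter])
    if (e_n <= e_h * 1e-6) return(60)  # cap noise-free frames at +60 dB
    10 * log10(e_h / e_n)
  }, 0)
  c(snrk_mean = mean(snr), snrk_std = stats::sd(snr))
}

#' Signal-to-Noise Ratio by waveform matching (whole segment)
#'
#' The signal estimate in each cycle is the mean cycle waveform scaled by the
#' cycle's least-squares matching coefficient; the noise is the per-cycle
#' residual after matching. Reported is the ratio of total matched-signal
#' energy to total residual energy over the whole segment, in dB, capped at
#' +60 dB. GAW only in the battery.
#'
#' @param signal Numeric vector.
#' @param cycles A \code{cycle_set}.
#' @param cap_db Ceiling (default 60).
#' @return SNR in dB (single value).
#' @export
snr_qi <- function(signal, cycles, cap_db = 60) {
  if (cycles$n_cycles < 3)
    stop("too few cycles: SNR needs >= 3", call. = FALSE)
  w <- cycle_matrix(signal, cycles)
  w <- w - mean(w)
  wbar <- colMeans(w)
  denom <- sum(wbar^2)
  if (denom == 0) stop("degenerate: zero mean waveform", call. = FALSE)
  coefs <- as.numeric(w %*% wbar) / denom
  fitted <- outer(coefs, wbar)
  e_sig <- sum(fitted^2)
  e_res <- sum((w - fitted)^2)
  if (e_res <= e_sig * 10^(-cap_db / 10)) return(cap_db)
  10 * log10(e_sig / e_res)
}
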