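#' Synthetic recording configuration
#'
#' Builds and validates the configuration for one synthetic sustained-phonation
#' recording. The generator emulates the glottal area waveform (GAW) of a
#' sustained /i/ vowel: a quasi-periodic train of glottal pulses with a flat
#' closed plateau and half-cosine opening/closing ramps, split into left and
#' right halves, plus an acoustic track derived from the same pulse train
#' through a source-filter model (differentiated glottal area through a bank
#' of two-pole formant resonators).
#'
#' @param f0_hz Fundamental frequency in Hz (80-400).
#' @param jitter_rel Standard deviation of the relative cycle-period
#'   perturbation (dimensionless, e.g. 0.01 for 1\% jitter).
#' @param shimmer_rel Standard deviation of the relative cycle-amplitude
#'   perturbation (dimensionless).
#' @param open_quotient Open-phase fraction of the cycle (0-1].
#' @param closing_fraction Closing-phase share of the open phase (0-1).
#' @param plateau_frac Closed-plateau fraction of the cycle [0-1).
#' @param gap_rel Residual minimum area as a fraction of peak area [0-1);
#'   models incomplete glottal closure.
#' @param lr_amp_ratio Left/right peak-amplitude ratio (> 0).
#' @param lr_phase_delay_rel Left-vs-right peak delay as a fraction of the
#'   period (-0.5 to 0.5); positive means the right half leads.
#' @param acoustic_snr_db Additive-white-noise SNR of the acoustic track in
#'   dB; \code{Inf} for a noise-free track.
#' @param gaw_noise_rel Additive GAW noise standard deviation relative to the
#'   peak area (>= 0).
#' @param duration_s Segment duration in seconds (default 0.25, matching a
#'   250 ms sustained-phonation excerpt).
#' @param fs_gaw GAW sampling rate in samples/s (default 4000).
#' @param fs_acoustic Acoustic sampling rate in samples/s (default 40000);
#'   must be an integer multiple of \code{fs_gaw}.
#' @param formants_hz Two-column matrix-like list of vocal-tract resonances:
#'   a list with \code{freq} and \code{bw} numeric vectors (Hz). Defaults to
#'   an /i/-like set (~300, 2300, 3000 Hz).
#' @param seed Integer seed; all randomness in the recording derives from it.
#'
#' @return An object of class \code{synth_config} (a named list).
#' @export
synth_config <- function(f0_hz = 180,
                         jitter_rel = 0.005,
                         shimmer_rel = 0.02,
                         open_quotient = 0.6,
                         closing_fraction = 0.4,
                         plateau_frac = 0.2,
                         gap_rel = 0.05,
                         lr_amp_ratio = 1,
                         lr_phase_delay_rel = 0,
                         acoustic_snr_db = 30,
                         gaw_noise_rel = 0.005,
                         duration_s = 0.25,
                         fs_gaw = 4000,
                         fs_acoustic = 40000,
                         formants_hz = list(freq = c(300, 2300, 3000),
                                            bw = c(80, 120, 150)),
                         seed = 1L) {
  cfg <- list(f0_hz = f0_hz, jitter_rel = jitter_rel, shimmer_rel = shimmer_rel,
              open_quotient = open_quotient, closing_fraction = closing_fraction,
              plateau_frac = plateau_frac, gap_rel = gap_rel,
              lr_amp_ratio = lr_amp_ratio,
              lr_phase_delay_rel = lr_phase_delay_rel,
              acoustic_snr_db = acoustic_snr_db, gaw_noise_rel = gaw_noise_rel,
              duration_s = duration_s, fs_gaw = fs_gaw,
              fs_acoustic = fs_acoustic, formants_hz = formants_hz,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$f0_hz < 80 || cfg$f0_hz > 400)
    stop("f0_hz must lie in the phonation band 80-400 Hz", call. = FALSE)
  if (cfg$open_quotient <= 0 || cfg$open_quotient > 1)
    stop("open_quotient must be in (0, 1]", call. = FALSE)
  if (cfg$closing_fraction <= 0 || cfg$closing_fraction >= 1)
    stop("closing_fraction must be in (0, 1)", call. = FALSE)
  if (cfg$gap_rel < 0 || cfg$gap_rel >= 1)
    stop("gap_rel must be in [0, 1)", call. = FALSE)
  if (cfg$plateau_frac < 0 || cfg$plateau_frac >= 1)
    stop("plateau_frac must be in [0, 1)", call. = FALSE)
  if (cfg$plateau_frac + cfg$open_quotient > 1)
    stop("plateau_frac + open_quotient exceed one cycle: configuration error",
         call. = FALSE)
  if (cfg$lr_amp_ratio <= 0)
    stop("lr_amp_ratio must be > 0", call. = FALSE)
  if (abs(cfg$lr_phase_delay_rel) > 0.5)
    stop("lr_phase_delay_rel must be in [-0.5, 0.5]", call. = FALSE)
  if (cfg$gaw_noise_rel < 0)
    stop("gaw_noise_rel must be >= 0", call. = FALSE)
  if (cfg$fs_acoustic %% cfg$fs_gaw != 0)
    stop("fs_acoustic must be an integer multiple of fs_gaw", call. = FALSE)
  invisible(cfg)
}

#' Normalized glottal pulse shape
#'
#' Evaluates the unit glottal pulse at a within-cycle phase. The cycle starts
#' at the closed plateau (area at the residual gap level), opens along a
#' half-cosine ramp, peaks, closes along a half-cosine ramp, and stays closed
#' for the remainder. Landmark positions (opening/closing durations, plateau
#' length, residual gap) are in closed form, which makes the pulse suitable
#' for recovery tests of CQ/SQ/PQ/GGI-style measures.
#'
#' @param phase Numeric vector of within-cycle phases in [0, 1).
#' @param cfg A \code{synth_config}.
#' @return Area values in [gap_rel, 1].
#' @export
glottal_pulse <- function(phase, cfg) {
  stopifnot(all(phase >= 0), all(phase < 1))
  oq <- cfg$open_quotient
  open_start <- cfg$plateau_frac
  opening <- (1 - cfg$closing_fraction) * oq
  closing <- cfg$closing_fraction * oq
  peak_at <- open_start + opening
  open_end <- open_start + oq

  shape <- numeric(length(phase))
  idx_open <- phase > open_start & phase <= peak_at
  idx_close <- phase > peak_at & phase < open_end
  # half-cosine ramps: 0 -> 1 over the opening phase, 1 -> 0 over closing
  shape[idx_open] <- 0.5 * (1 - cos(pi * (phase[idx_open] - open_start) / opening))
  shape[idx_close] <- 0.5 * (1 + cos(pi * (phase[idx_close] - peak_at) / closing))
  cfg$gap_rel + (1 - cfg$gap_rel) * shape
}

# Truncated (+-3 sigma) Gaussian draws for multiplicative perturbations.
rnorm_trunc3 <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  pmax(pmin(x, 3 * sd), -3 * sd)
}

#' Simulate one synchronized GAW/acoustic recording
#'
#' Generates a quasi-periodic glottal pulse train with per-cycle period jitter
#' and amplitude shimmer, splits it into left and right halves (the left half
#' scaled by the left/right amplitude ratio and delayed by the left/right
#' phase delay), sums them into the total GAW, and renders an acoustic track
#' by differentiating the pulse train sampled at the acoustic rate and passing
#' it through the formant resonator bank, plus white noise at the configured
#' SNR. The left, right and total GAW satisfy GAW_T = GAW_L + GAW_R exactly at
#' every sample.
#'
#' @param cfg A \code{synth_config}.
#' @param subject_id Optional subject identifier attached to the recording.
#' @param group Optional group label (one of "NF", "FDF", "NM", "FDM").
#' @return A list with elements \code{recording} (class \code{gaw_recording}:
#'   \code{gaw_total}, \code{gaw_left}, \code{gaw_right}, \code{acoustic},
#'   \code{fs_gaw}, \code{fs_acoustic}, \code{subject_id}, \code{group}) and
#'   \code{truth} (class \code{synth_truth}: realized per-cycle periods and
#'   amplitudes plus summary ground truth recomputed from the emitted pulse
#'   train).
#' @export
simulate_recording <- function(cfg, subject_id = "s1", group = "NF") {
  validate_synth_config(cfg)
  set.seed(cfg$seed)

  # base period quantized to GAW samples so that zero-jitter configs are
  # exactly periodic at the GAW rate
  t0_samples <- round(cfg$fs_gaw / cfg$f0_hz)
  t0 <- t0_samples / cfg$fs_gaw
  n_cycles <- ceiling(cfg$duration_s / t0) + 3L
  if (n_cycles < 3L)
    stop("duration too short for >= 3 cycles", call. = FALSE)

  periods <- t0 * (1 + rnorm_trunc3(n_cycles, cfg$jitter_rel))
  amps <- 1 + rnorm_trunc3(n_cycles, cfg$shimmer_rel)
  onsets <- c(0, cumsum(periods))

  w_left <- cfg$lr_amp_ratio / (1 + cfg$lr_amp_ratio)
  w_right <- 1 / (1 + cfg$lr_amp_ratio)
  delay <- cfg$lr_phase_delay_rel

  render <- function(fs) {
    t <- seq(0, cfg$duration_s - 1 / fs, by = 1 / fs)
    cyc <- findInterval(t, onsets)
    ph <- (t - onsets[cyc]) / periods[cyc]
    # left half delayed by `delay` periods relative to the right half
    ph_l <- (ph - delay) %% 1
    ph_l[ph_l >= 1] <- 0  # guard: x %% 1 can round up to 1 for tiny negatives
    left <- w_left * amps[cyc] * glottal_pulse(ph_l, cfg)
    right <- w_right * amps[cyc] * glottal_pulse(ph, cfg)
    list(t = t, left = left, right = right)
  }

  g <- render(cfg$fs_gaw)
  gaw_left <- g$left
  gaw_right <- g$right
  if (cfg$gaw_noise_rel > 0) {
    gaw_left <- gaw_left + stats::rnorm(length(gaw_left), 0, cfg$gaw_noise_rel / 2)
    gaw_right <- gaw_right + stats::rnorm(length(gaw_right), 0, cfg$gaw_noise_rel / 2)
  }
  gaw_total <- gaw_left + gaw_right

  # acoustic: same pulse train evaluated at the acoustic rate, differentiated
  # (flow derivative as the radiated-sound surrogate) and shaped by formants
  a <- render(cfg$fs_acoustic)
  src <- a$left + a$right
  excitation <- c(0, diff(src)) * cfg$fs_acoustic / cfg$fs_gaw
  ac <- excitation
  for (k in seq_along(cfg$formants_hz$freq)) {
    ac <- resonator_filter(ac, cfg$formants_hz$freq[k], cfg$formants_hz$bw[k],
                           cfg$fs_acoustic)
  }
  ac <- ac / max(abs(ac))
  if (is.finite(cfg$acoustic_snr_db)) {
    noise_sd <- stats::sd(ac) / 10^(cfg$acoustic_snr_db / 20)
    ac <- ac + stats::rnorm(length(ac), 0, noise_sd)
  }

  rec <- structure(list(gaw_total = gaw_total, gaw_left = gaw_left,
                        gaw_right = gaw_right, acoustic = ac,
                        fs_gaw = cfg$fs_gaw, fs_acoustic = cfg$fs_acoustic,
                        subject_id = subject_id, group = group),
                   class = "gaw_recording")

  # ground truth recomputed from the emitted pulse train, not the config.
  # Cycle landmarks are the *observable* ones: a peak picker marks cycles at
  # successive composite-pulse peaks, so realized periods are peak-to-peak
  # intervals and realized amplitudes are peak-to-trough excursions of the
  # measured (peak-based) cycles.
  u <- seq(0, 1 - 1 / 4096, by = 1 / 4096)
  u_l <- (u - delay) %% 1
  u_l[u_l >= 1] <- 0
  composite <- w_left * glottal_pulse(u_l, cfg) + w_right * glottal_pulse(u, cfg)
  u_peak <- u[which.max(composite)]
  c_max <- max(composite)
  c_min <- min(composite)
  used <- which(onsets[-1] <= cfg$duration_s)  # cycles fully inside segment
  peak_times <- onsets[used] + u_peak * periods[used]
  peak_times <- peak_times[peak_times < cfg$duration_s]
  tp <- diff(peak_times)
  a_used <- amps[seq_along(peak_times)]
  # measured cycle i spans peaks i..i+1: its max is the larger neighbouring
  # peak, its min the residual-gap floor of the cycle the trough falls in
  a_obs <- pmax(a_used[-length(a_used)], a_used[-1]) * c_max -
    a_used[-1] * c_min
  truth <- structure(list(
    periods_s = tp,
    amps = a_obs,
    peak_times_s = peak_times,
    onsets_s = onsets[used],
    mean_period_s = mean(tp),
    mjit_ms = mean(abs(diff(tp))) * 1000,
    jit_pct = 100 * mean(abs(diff(tp))) / mean(tp),
    shim_db = mean(abs(diff(20 * log10(a_obs)))),
    gap_rel = cfg$gap_rel,
    lr_phase_delay_rel = delay,
    lr_amp_ratio = cfg$lr_amp_ratio,
    acoustic_snr_db = cfg$acoustic_snr_db), class = "synth_truth")

  list(recording = rec, truth = truth)
}

# two-pole resonator (formant) filter: poles at r*exp(+-i*theta)
resonator_filter <- function(x, freq, bw, fs) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * freq / fs
  a <- c(1, -2 * r * cos(theta), r^2)
  b <- 1 - 2 * r * cos(theta) + r^2  # unit gain at DC-adjacent band
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
}

#' Default per-group configuration samplers
#'
#' Returns a list of functions, one per cohort group (\code{NF}, \code{FDF},
#' \code{NM}, \code{FDM}), each mapping a seed to a \code{synth_config}.
#' Female groups phonate at 160-300 Hz, male groups at 80-160 Hz. Disordered
#' (FD) samplers shift jitter, shimmer, residual gap and left-right asymmetry
#' upward relative to healthy samplers; these shifts are illustrative, not
#' clinically calibrated.
#'
#' @return Named list of sampler functions \code{function(seed) synth_config}.
#' @export
default_cfg_samplers <- function() {
  draw <- function(seed, f0_range, disordered) {
    set.seed(seed)
    if (disordered) {
      jit <- stats::runif(1, 0.010, 0.030)
      shim <- stats::runif(1, 0.040, 0.100)
      gap <- stats::runif(1, 0.050, 0.300)
      ratio <- stats::runif(1, 0.700, 1.300)
      delay <- stats::runif(1, -0.100, 0.100)
      snr <- stats::runif(1, 15, 28)
    } else {
      jit <- stats::runif(1, 0.002, 0.010)
      shim <- stats::runif(1, 0.010, 0.040)
      gap <- stats::runif(1, 0.000, 0.100)
      ratio <- stats::runif(1, 0.900, 1.100)
      delay <- stats::runif(1, -0.030, 0.030)
      snr <- stats::runif(1, 25, 35)
    }
    synth_config(f0_hz = stats::runif(1, f0_range[1], f0_range[2]),
                 jitter_rel = jit, shimmer_rel = shim, gap_rel = gap,
                 open_quotient = stats::runif(1, 0.5, 0.7),
                 closing_fraction = stats::runif(1, 0.35, 0.5),
                 plateau_frac = stats::runif(1, 0.1, 0.25),
                 lr_amp_ratio = ratio, lr_phase_delay_rel = delay,
                 acoustic_snr_db = snr, seed = seed)
  }
  list(
    NF  = function(seed) draw(seed, c(160, 300), FALSE),
    FDF = function(seed) draw(seed, c(160, 300), TRUE),
    NM  = function(seed) draw(seed, c(80, 160), FALSE),
    FDM = function(seed) draw(seed, c(80, 160), TRUE)
  )
}

#' Simulate a cohort of synthetic recordings
#'
#' Draws independent per-subject configurations from per-group samplers and
#' simulates each recording. Reproducible element-wise: subject i always gets
#' the same derived seed for a given master seed, regardless of group sizes.
#'
#' @param n_per_group Named integer vector with counts for groups
#'   \code{c(NF=, FDF=, NM=, FDM=)}.
#' @param cfg_samplers Per-group sampler functions as returned by
#'   \code{\link{default_cfg_samplers}}.
#' @param seed Master integer seed.
#' @return List of \code{list(recording, truth)} pairs, one per subject, in
#'   group order NF, FDF, NM, FDM.
#' @export
simulate_cohort <- function(n_per_group = c(NF = 124, FDF = 60, NM = 44, FDM = 22),
                            cfg_samplers = default_cfg_samplers(),
                            seed = 1L) {
  stopifnot(all(n_per_group >= 0), any(n_per_group >= 1))
  groups <- rep(names(n_per_group), times = n_per_group)
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sub_seed <- (as.integer(seed) * 1009L + i * 7919L) %% .Machine$integer.max
    cfg <- cfg_samplers[[groups[i]]](sub_seed)
    out[[i]] <- simulate_recording(cfg, subject_id = sprintf("s%03d", i),
                                   group = groups[i])
  }
  out
}
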