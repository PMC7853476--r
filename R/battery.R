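#' Parameter schema of the voice battery
#'
#' The frozen name set, order, source signal and unit of the 49 battery
#' parameters: 14 acoustic-based, 25 GAW-based non-symmetry, and 10 GAW
#' left-right symmetry parameters (35 GAW-based in total).
#'
#' @return Data frame with columns \code{key} (stable column name),
#'   \code{label} (display name, e.g. \code{"F0 [Mean]"}), \code{signal}
#'   (\code{"gaw"}, \code{"gaw_symmetry"} or \code{"acoustic"}) and
#'   \code{unit}.
#' @export
parameter_schema <- function() {
  g <- function(key, label, unit) data.frame(key = key, label = label,
                                             signal = "gaw", unit = unit)
  s <- function(key, label, unit) data.frame(key = key, label = label,
                                             signal = "gaw_symmetry", unit = unit)
  a <- function(key, label, unit) data.frame(key = key, label = label,
                                             signal = "acoustic", unit = unit)
  rbind(
    g("gaw_f0_mean", "F0 [Mean]", "Hz"),
    g("gaw_f0_std", "F0 [Std]", "Hz"),
    g("gaw_mjit", "MJit", "ms"),
    g("gaw_jit_pct", "Jit(%)", "a.u."),
    g("gaw_pvi", "PVI", "a.u."),
    g("gaw_mshim", "MShim", "dB"),
    g("gaw_epf", "EPF", "a.u."),
    g("gaw_cq_mean", "CQ [Mean]", "a.u."),
    g("gaw_cq_std", "CQ [Std]", "a.u."),
    g("gaw_sq_mean", "SQ [Mean]", "a.u."),
    g("gaw_sq_std", "SQ [Std]", "a.u."),
    g("gaw_ggi_mean", "GGI [Mean]", "a.u."),
    g("gaw_ggi_std", "GGI [Std]", "a.u."),
    g("gaw_pq_mean", "PQ [Mean]", "a.u."),
    g("gaw_pq_std", "PQ [Std]", "a.u."),
    g("gaw_gai_mean", "GAI [Mean]", "a.u."),
    g("gaw_gai_std", "GAI [Std]", "a.u."),
    g("gaw_cpp", "CPP", "dB"),
    g("gaw_hnr", "HNR", "dB"),
    g("gaw_wmc_max", "WMC_Max", "a.u."),
    g("gaw_wmc_mean", "WMC_Mean", "a.u."),
    g("gaw_nne", "NNE", "dB"),
    g("gaw_snrk_mean", "SNR_K [Mean]", "dB"),
    g("gaw_snrk_std", "SNR_K [Std]", "dB"),
    g("gaw_snrq", "SNR_Q", "dB"),
    s("gaw_pha_mean", "PhA [Mean]", "a.u."),
    s("gaw_phai_mean", "PhAI [Mean]", "a.u."),
    s("gaw_phai_std", "PhAI [Std]", "a.u."),
    s("gaw_ams_mean", "AmS [Mean]", "a.u."),
    s("gaw_amsi_mean", "AmSI [Mean]", "a.u."),
    s("gaw_amsi_std", "AmSI [Std]", "a.u."),
    s("gaw_sps_mean", "SpS [Mean]", "a.u."),
    s("gaw_spsi_mean", "SpSI [Mean]", "a.u."),
    s("gaw_spsi_std", "SpSI [Std]", "a.u."),
    s("gaw_wasi_mean", "WaSI [Mean]", "a.u."),
    a("ac_f0_mean", "F0 [Mean]", "Hz"),
    a("ac_f0_std", "F0 [Std]", "Hz"),
    a("ac_mjit", "MJit", "ms"),
    a("ac_jit_pct", "Jit(%)", "a.u."),
    a("ac_pvi", "PVI", "a.u."),
    a("ac_mshim", "MShim", "dB"),
    a("ac_avi", "AVI", "dB"),
    a("ac_cpp", "CPP", "dB"),
    a("ac_hnr", "HNR", "dB"),
    a("ac_wmc_max", "WMC_Max", "a.u."),
    a("ac_wmc_mean", "WMC_Mean", "a.u."),
    a("ac_nne", "NNE", "dB"),
    a("ac_snrk_mean", "SNR_K [Mean]", "dB"),
    a("ac_snrk_std", "SNR_K [Std]", "dB")
  )
}

# run a sub-computation, returning NA markers on error
safe <- function(expr, n = 1) {
  tryCatch(expr, error = function(e) rep(NA_real_, n))
}

#' Extract the 49-parameter vector from one recording
#'
#' Runs the full extraction chain: maximum-based cycles on the total GAW and
#' (independently) on the acoustic track; total-GAW cycles transferred to the
#' left and right halves; minimum-based cycles on the total GAW for the phase
#' parameters; then all fundamental-frequency, perturbation, glottal-dynamic,
#' symmetry and noise parameters. Sub-computations that fail leave explicit
#' \code{NA} markers instead of dropping entries; if cycle detection fails on
#' one track, that track's parameters are all \code{NA} while the other
#' track's parameters are still computed.
#'
#' @param rec A \code{gaw_recording}.
#' @param spectral_cfg A \code{spectral_config}.
#' @param check_duration Check that both tracks are 250 ms (+- 5 ms)?
#' @return One-row data frame: \code{subject_id}, \code{group}, then the 49
#'   parameter columns in schema order.
#' @export
extract_parameters <- function(rec, spectral_cfg = spectral_config(),
                               check_duration = TRUE) {
  stopifnot(inherits(rec, "gaw_recording"))
  if (check_duration) {
    dur_g <- length(rec$gaw_total) / rec$fs_gaw
    dur_a <- length(rec$acoustic) / rec$fs_acoustic
    if (abs(dur_g - 0.25) > 0.005 || abs(dur_a - 0.25) > 0.005)
      stop("recording duration outside 250 ms +- 5 ms", call. = FALSE)
  }
  schema <- parameter_schema()
  out <- stats::setNames(as.list(rep(NA_real_, nrow(schema))), schema$key)

  # ---- GAW side -----------------------------------------------------------
  cyc_max <- tryCatch(detect_cycles(rec$gaw_total, rec$fs_gaw, "maximum"),
                      error = function(e) NULL)
  if (!is.null(cyc_max)) {
    tab <- safe(cycle_table(rec$gaw_total, cyc_max), 0)
    if (is.data.frame(tab)) {
      out[c("gaw_f0_mean", "gaw_f0_std")] <- safe(f0_stats(tab), 2)
      out[c("gaw_mjit", "gaw_jit_pct", "gaw_pvi")] <- safe(jitter_measures(tab), 3)
      out["gaw_mshim"] <- safe(amplitude_measures(tab)[["mshim_db"]])
      out["gaw_epf"] <- safe(energy_perturbation(tab))
    }
    lm_ <- safe(phase_landmarks(rec$gaw_total, cyc_max), 0)
    if (is.data.frame(lm_)) {
      out[c("gaw_cq_mean", "gaw_cq_std", "gaw_sq_mean", "gaw_sq_std",
            "gaw_pq_mean", "gaw_pq_std")] <- safe(suppressWarnings(quotients(lm_)), 6)
      out[c("gaw_ggi_mean", "gaw_ggi_std", "gaw_gai_mean", "gaw_gai_std")] <-
        safe(gap_indices(rec$gaw_total, cyc_max, lm_), 4)
    }
    out["gaw_hnr"] <- safe(hnr_waveform(rec$gaw_total, cyc_max))
    out[c("gaw_wmc_max", "gaw_wmc_mean")] <- safe(wmc(rec$gaw_total, cyc_max), 2)
    f0g <- out[["gaw_f0_mean"]]
    if (is.finite(f0g))
      out["gaw_nne"] <- safe(nne(rec$gaw_total, rec$fs_gaw, f0g, spectral_cfg))
    out[c("gaw_snrk_mean", "gaw_snrk_std")] <-
      safe(snr_klingholz(rec$gaw_total, rec$fs_gaw, cyc_max, spectral_cfg), 2)
    out["gaw_snrq"] <- safe(snr_qi(rec$gaw_total, cyc_max))

    # symmetry parameters: left/right halves on the total-GAW cycle grid
    cyc_l <- transfer_cycles(cyc_max, rec$gaw_left)
    out[c("gaw_ams_mean", "gaw_amsi_mean", "gaw_amsi_std")] <-
      safe(amplitude_symmetry(rec$gaw_left, rec$gaw_right, cyc_l), 3)
    out[c("gaw_sps_mean", "gaw_spsi_mean", "gaw_spsi_std")] <-
      safe(spatial_symmetry(rec$gaw_left, rec$gaw_right, cyc_l), 3)
    out["gaw_wasi_mean"] <- safe(waveform_symmetry(rec$gaw_left, rec$gaw_right, cyc_l))
  }
  out["gaw_cpp"] <- safe(as.numeric(cpp(rec$gaw_total, rec$fs_gaw, spectral_cfg)))

  # phase parameters use minimum-based cycles by definition
  cyc_min <- tryCatch(detect_cycles(rec$gaw_total, rec$fs_gaw, "minimum"),
                      error = function(e) NULL)
  if (!is.null(cyc_min)) {
    out[c("gaw_pha_mean", "gaw_phai_mean", "gaw_phai_std")] <-
      safe(phase_asymmetry(rec$gaw_left, rec$gaw_right, cyc_min), 3)
  }

  # ---- acoustic side ------------------------------------------------------
  # stricter peak spacing than on the GAW: vocal-tract resonances ring
  # between glottal pulses and can produce prominent mid-cycle peaks
  cyc_ac <- tryCatch(detect_cycles(rec$acoustic, rec$fs_acoustic, "maximum",
                                   min_dist_frac = 0.7),
                     error = function(e) NULL)
  if (!is.null(cyc_ac)) {
    tab <- safe(cycle_table(rec$acoustic, cyc_ac), 0)
    if (is.data.frame(tab)) {
      out[c("ac_f0_mean", "ac_f0_std")] <- safe(f0_stats(tab), 2)
      out[c("ac_mjit", "ac_jit_pct", "ac_pvi")] <- safe(jitter_measures(tab), 3)
      out[c("ac_mshim", "ac_avi")] <- safe(amplitude_measures(tab), 2)
    }
    out["ac_hnr"] <- safe(hnr_waveform(rec$acoustic, cyc_ac))
    out[c("ac_wmc_max", "ac_wmc_mean")] <- safe(wmc(rec$acoustic, cyc_ac), 2)
    f0a <- out[["ac_f0_mean"]]
    if (is.finite(f0a))
      out["ac_nne"] <- safe(nne(rec$acoustic, rec$fs_acoustic, f0a, spectral_cfg))
    out[c("ac_snrk_mean", "ac_snrk_std")] <-
      safe(snr_klingholz(rec$acoustic, rec$fs_acoustic, cyc_ac, spectral_cfg), 2)
  }
  out["ac_cpp"] <- safe(as.numeric(cpp(rec$acoustic, rec$fs_acoustic, spectral_cfg)))

  cbind(data.frame(subject_id = rec$subject_id, group = rec$group),
        as.data.frame(out))
}

#' Extract parameters for a whole cohort
#'
#' @param cohort List of \code{list(recording, truth)} pairs (or bare
#'   \code{gaw_recording}s) as produced by \code{\link{simulate_cohort}}.
#' @param ... Passed to \code{\link{extract_parameters}}.
#' @return Data frame with one row per recording (subject_id, group, 49
#'   parameter columns).
#' @export
extract_cohort <- function(cohort, ...) {
  rows <- lapply(cohort, function(el) {
    rec <- if (inherits(el, "gaw_recording")) el else el$recording
    extract_parameters(rec, ...)
  })
  do.call(rbind, rows)
}
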