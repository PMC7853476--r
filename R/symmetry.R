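#' Left-right phase asymmetry
#'
#' Per minimum-based cycle, the signed phase asymmetry is the delay between
#' the left and right within-cycle area peaks as a fraction of the cycle
#' period: \eqn{PhA_i = (t_{peak,L} - t_{peak,R}) / T_i}. Positive values mean
#' the right half leads (peaks earlier). \eqn{PhAI_i = |PhA_i|}.
#' Minimum-based cycles are used so that each cycle contains one full open
#' phase and the peaks of both halves fall inside it.
#'
#' @param left,right Numeric vectors: left and right GAW halves.
#' @param min_cycles Minimum-based \code{cycle_set} (detected on the total GAW
#'   and transferred).
#' @return Named vector \code{c(pha_mean, phai_mean, phai_std)} (a.u.).
#' @export
phase_asymmetry <- function(left, right, min_cycles) {
  stopifnot(inherits(min_cycles, "cycle_set"))
  spans <- cycle_spans(min_cycles)
  pha <- vapply(spans, function(s) {
    l <- left[s]; r <- right[s]
    if (diff(range(l)) == 0 || diff(range(r)) == 0)
      stop("degenerate half: flat signal within a cycle", call. = FALSE)
    (which.max(l) - which.max(r)) / length(s)
  }, 0)
  phai <- abs(pha)
  c(pha_mean = mean(pha), phai_mean = mean(phai), phai_std = stats::sd(phai))
}

#' Left-right amplitude symmetry
#'
#' Per cycle, with peak-to-peak amplitudes \eqn{a_L, a_R}: the Amplitude
#' Symmetry Index \eqn{AmSI_i = \min(a_L,a_R)/\max(a_L,a_R) \in (0,1]} and the
#' signed Amplitude Symmetry \eqn{AmS_i = (a_R - a_L)/(a_R + a_L)} (positive =
#' right larger).
#'
#' @param left,right Left and right GAW halves.
#' @param cycles_T Maximum-based \code{cycle_set} detected on the total GAW.
#' @return Named vector \code{c(ams_mean, amsi_mean, amsi_std)}.
#' @export
amplitude_symmetry <- function(left, right, cycles_T) {
  sym_aggregate(left, right, cycles_T,
                function(x) diff(range(x)),
                "zero amplitude on a half",
                c("ams_mean", "amsi_mean", "amsi_std"))
}

#' Left-right spatial symmetry
#'
#' Per cycle, with cycle-integrated areas \eqn{s_L, s_R} (sum of samples times
#' the sampling step): \eqn{SpSI_i = \min(s_L,s_R)/\max(s_L,s_R)} and signed
#' \eqn{SpS_i = (s_R - s_L)/(s_R + s_L)}.
#'
#' @inheritParams amplitude_symmetry
#' @return Named vector \code{c(sps_mean, spsi_mean, spsi_std)}.
#' @export
spatial_symmetry <- function(left, right, cycles_T) {
  fs <- cycles_T$fs
  sym_aggregate(left, right, cycles_T,
                function(x) sum(x) / fs,
                "zero integrated area on a half",
                c("sps_mean", "spsi_mean", "spsi_std"))
}

sym_aggregate <- function(left, right, cycles, feature, degenerate_msg, names_out) {
  stopifnot(inherits(cycles, "cycle_set"))
  spans <- cycle_spans(cycles)
  vals <- vapply(spans, function(s) {
    fl <- feature(left[s]); fr <- feature(right[s])
    if (fl <= 0 || fr <= 0) stop("degenerate half: ", degenerate_msg, call. = FALSE)
    c(signed = (fr - fl) / (fr + fl), index = min(fl, fr) / max(fl, fr))
  }, c(signed = 0, index = 0))
  out <- c(mean(vals["signed", ]), mean(vals["index", ]), stats::sd(vals["index", ]))
  names(out) <- names_out
  out
}

#' Left-right waveform symmetry
#'
#' Per cycle, the Waveform Symmetry Index is the Pearson correlation between
#' the left and right within-cycle waveforms (equal length by construction,
#' since both halves share the total-GAW cycle grid). Cycles where either half
#' is constant are skipped.
#'
#' @inheritParams amplitude_symmetry
#' @return \code{wasi_mean}: mean per-cycle waveform correlation in [-1, 1].
#' @export
waveform_symmetry <- function(left, right, cycles_T) {
  stopifnot(inherits(cycles_T, "cycle_set"))
  spans <- cycle_spans(cycles_T)
  vals <- vapply(spans, function(s) {
    l <- left[s]; r <- right[s]
    if (stats::sd(l) == 0 || stats::sd(r) == 0) return(NA_real_)
    stats::cor(l, r)
  }, 0)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("degenerate: all cycles constant on one half", call. = FALSE)
  c(wasi_mean = mean(vals))
}
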