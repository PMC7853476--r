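#' Per-cycle period, amplitude and energy table
#'
#' For each complete cycle: period \eqn{T_i} in seconds, peak-to-peak
#' amplitude \eqn{A_i} (within-cycle max minus min, robust to the residual
#' glottal-gap offset), and energy \eqn{E_i} (sum of squared mean-removed
#' samples within the cycle).
#'
#' @param signal Numeric vector.
#' @param cycles A \code{cycle_set} on the same signal.
#' @return Data frame with columns \code{period_s}, \code{amplitude},
#'   \code{energy}, one row per cycle in time order.
#' @export
cycle_table <- function(signal, cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (cycles$n_cycles < 2)
    stop("too few cycles: need >= 2 complete cycles", call. = FALSE)
  spans <- cycle_spans(cycles)
  periods <- diff(cycles$boundaries) / cycles$fs
  amp <- vapply(spans, function(s) diff(range(signal[s])), 0)
  energy <- vapply(spans, function(s) {
    x <- signal[s]; sum((x - mean(x))^2)
  }, 0)
  data.frame(period_s = periods, amplitude = amp, energy = energy)
}

#' Fundamental-frequency statistics
#'
#' Per-cycle fundamental frequency is the inverse cycle period,
#' \eqn{f_i = 1/T_i}; the output is its mean and sample standard deviation.
#'
#' @param table A cycle table from \code{\link{cycle_table}}.
#' @return Named vector \code{c(f0_mean, f0_std)} in Hz.
#' @export
f0_stats <- function(table) {
  if (nrow(table) < 2) stop("undefined std: need >= 2 cycles", call. = FALSE)
  f <- 1 / table$period_s
  c(f0_mean = mean(f), f0_std = stats::sd(f))
}

#' Jitter measures
#'
#' Mean Jitter \code{MJit} is the mean absolute difference of consecutive
#' periods in ms; \code{Jit(\%)} normalizes it by the mean period;
#' the Period Variability Index \code{PVI} is the coefficient of variation of
#' the period, scaled by 100.
#'
#' @param table A cycle table.
#' @return Named vector \code{c(mjit_ms, jit_pct, pvi)}.
#' @export
jitter_measures <- function(table) {
  if (nrow(table) < 3)
    stop("too few cycles: jitter needs >= 3 cycles", call. = FALSE)
  t_ms <- table$period_s * 1000
  mjit <- mean(abs(diff(t_ms)))
  c(mjit_ms = mjit,
    jit_pct = 100 * mjit / mean(t_ms),
    pvi = 100 * stats::sd(t_ms) / mean(t_ms))
}

#' Amplitude perturbation measures
#'
#' Mean Shimmer \code{MShim} is the mean absolute dB ratio of consecutive
#' cycle amplitudes; the Amplitude Variability Index \code{AVI} is the sample
#' standard deviation of the per-cycle amplitude in dB relative to the mean
#' amplitude. AVI is reported for the acoustic signal only in the battery.
#'
#' @param table A cycle table.
#' @return Named vector \code{c(mshim_db, avi_db)}.
#' @export
amplitude_measures <- function(table) {
  if (nrow(table) < 3)
    stop("too few cycles: shimmer needs >= 3 cycles", call. = FALSE)
  a <- table$amplitude
  if (any(a <= 0)) stop("degenerate amplitude: A_i = 0", call. = FALSE)
  c(mshim_db = mean(abs(diff(20 * log10(a)))),
    avi_db = stats::sd(20 * log10(a / mean(a))))
}

#' Energy Perturbation Factor
#'
#' \code{EPF} = 100 x mean absolute difference of consecutive cycle energies,
#' normalized by the mean cycle energy. GAW only in the battery.
#'
#' @param table A cycle table.
#' @return EPF (a.u.).
#' @export
energy_perturbation <- function(table) {
  if (nrow(table) < 3)
    stop("too few cycles: EPF needs >= 3 cycles", call. = FALSE)
  e <- table$energy
  if (mean(e) <= 0) stop("degenerate energy: mean(E) = 0", call. = FALSE)
  100 * mean(abs(diff(e))) / mean(e)
}
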