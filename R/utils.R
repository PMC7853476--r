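#' Samples per oscillation cycle
#'
#' Number of samples representing one glottal cycle at a given sampling rate
#' and fundamental frequency. At a 4000 samples/s GAW rate, the 80-400 Hz
#' phonation band yields 50 down to 10 samples per cycle, so period
#' quantization is a real concern at high f0.
#'
#' @param fs Sampling rate in samples/s.
#' @param f0_hz Fundamental frequency in Hz.
#' @return Samples per cycle (rounded to the sample grid).
#' @export
samples_per_cycle <- function(fs, f0_hz) round(fs / f0_hz)

#' Relative period change from a one-sample boundary shift
#'
#' The relative change (in percent) of a measured cycle length when one cycle
#' boundary moves by a single sample: \code{100 / samples_per_cycle}. At
#' 4000 samples/s and 400 Hz this is 10\%, the quantization floor that
#' inflates period-perturbation measures at high fundamental frequency.
#'
#' @inheritParams samples_per_cycle
#' @return Percent change of the cycle length.
#' @export
one_sample_period_shift_pct <- function(fs, f0_hz) {
  100 / samples_per_cycle(fs, f0_hz)
}
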