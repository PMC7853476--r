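#' Estimate the dominant oscillation period
#'
#' Finds the lag maximizing the normalized autocorrelation of the mean-removed
#' signal, restricted to lags corresponding to the normal phonation band
#' (80-400 Hz).
#'
#' @param signal Numeric vector, uniformly sampled.
#' @param fs Sampling rate in samples/s.
#' @param f_min,f_max Fundamental-frequency search band in Hz.
#' @return Dominant period in samples (integer).
#' @export
estimate_dominant_period <- function(signal, fs, f_min = 80, f_max = 400) {
  x <- signal - mean(signal)
  if (all(x == 0)) stop("degenerate signal: constant input", call. = FALSE)
  n <- length(x)
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- min(n - 2L, ceiling(fs / f_min))
  if (lag_min >= lag_max)
    stop("signal too short for the 80-400 Hz search band", call. = FALSE)
  r0 <- sum(x * x)
  lags <- lag_min:lag_max
  r <- vapply(lags, function(l) sum(x[1:(n - l)] * x[(l + 1):n]) / r0, 0)
  if (max(r) < 0.2)
    stop("unvoiced signal: no autocorrelation peak above 0.2 in band",
         call. = FALSE)
  lags[which.max(r)]
}

# Local maxima with true topographic prominence. Returns indices of peaks
# whose prominence is >= prom_min, separated by at least min_dist samples
# (kept greedily in order of decreasing height).
find_peaks <- function(x, min_dist, prom_min) {
  n <- length(x)
  d <- diff(x)
  # plateau-safe local maxima: rising before, falling after
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0) return(integer(0))
  # prominence: height above the higher of the two key saddles, i.e. the
  # minimum between the peak and the nearest higher terrain on each side
  prom <- vapply(cand, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    right <- if (p < n) x[(p + 1):n] else numeric(0)
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[(max(higher_l)):(p - 1)]) else min(c(left, h))
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[1:(min(higher_r))]) else min(c(right, h))
    h - max(base_l, base_r)
  }, 0)
  keep <- cand[prom >= prom_min]
  if (length(keep) <= 1) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  acc <- integer(0)
  for (p in ord) {
    if (all(abs(p - acc) >= min_dist) || length(acc) == 0) acc <- c(acc, p)
  }
  sort(acc)
}

#' Detect oscillation cycles
#'
#' Detects maximum-based cycles (each cycle starts at a sufficiently distinct
#' local maximum and ends before the next one) or minimum-based cycles (the
#' same on the negated signal). "Sufficiently distinct" is operationalized as
#' topographic prominence of at least \code{prominence_frac} of the signal
#' peak-to-peak range, with inter-peak spacing of at least
#' \code{min_dist_frac} of the dominant period. Leading and trailing partial
#' cycles are discarded.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in samples/s.
#' @param basis Either \code{"maximum"} or \code{"minimum"}.
#' @param prominence_frac Minimum peak prominence as a fraction of
#'   peak-to-peak range (default 0.2).
#' @param min_dist_frac Minimum peak spacing as a fraction of the dominant
#'   period (default 0.5).
#' @return A \code{cycle_set}: list with \code{boundaries} (0-based sample
#'   indices of cycle starts, strictly increasing), \code{basis}, \code{fs}
#'   and \code{n_cycles}. Cycle i spans the half-open sample interval
#'   \code{[boundaries[i], boundaries[i+1])}.
#' @export
detect_cycles <- function(signal, fs, basis = c("maximum", "minimum"),
                          prominence_frac = 0.2, min_dist_frac = 0.5) {
  basis <- match.arg(basis)
  period <- estimate_dominant_period(signal, fs)
  x <- if (basis == "minimum") -signal else signal
  p2p <- diff(range(x))
  peaks <- find_peaks(x, min_dist = min_dist_frac * period,
                      prom_min = prominence_frac * p2p)
  if (length(peaks) < 3)
    stop("too few cycles: fewer than 3 cycle boundaries found", call. = FALSE)
  structure(list(boundaries = as.integer(peaks - 1L), basis = basis, fs = fs,
                 n_cycles = length(peaks) - 1L, signal_length = length(signal)),
            class = "cycle_set")
}

#' Transfer cycle boundaries to another signal
#'
#' Re-attaches the boundaries of an existing cycle set (typically detected on
#' the total GAW) to another signal of identical length and sampling rate,
#' without re-detection. Used so that the left and right GAW halves share the
#' total-GAW cycle grid.
#'
#' @param cycles A \code{cycle_set}.
#' @param target_signal Numeric vector of the same length as the signal the
#'   cycles were detected on.
#' @return A \code{cycle_set} with identical boundaries.
#' @export
transfer_cycles <- function(cycles, target_signal) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (length(target_signal) != cycles$signal_length)
    stop("alignment error: target signal length differs from source",
         call. = FALSE)
  cycles
}

# 1-based sample index ranges of complete cycles
cycle_spans <- function(cycles) {
  b <- cycles$boundaries + 1L
  lapply(seq_len(cycles$n_cycles), function(i) b[i]:(b[i + 1] - 1L))
}

#' Serialize a cycle set to a data frame
#'
#' @param cycles A \code{cycle_set}.
#' @return Data frame with columns cycle_index, start_sample, end_sample
#'   (0-based, half-open).
#' @export
cycles_as_data_frame <- function(cycles) {
  b <- cycles$boundaries
  data.frame(cycle_index = seq_len(cycles$n_cycles),
             start_sample = b[-length(b)],
             end_sample = b[-1])
}
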