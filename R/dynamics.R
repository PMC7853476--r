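#' Per-cycle phase landmarks on the total GAW
#'
#' Within each maximum-based cycle \code{[max_i, max_{i+1})}: the within-cycle
#' minimum is located (earliest sample on ties); the closing phase runs from
#' the cycle-start maximum to that minimum, the opening phase from the minimum
#' to the next maximum, and the closed plateau is the total time the signal
#' stays within \code{plateau_eps} of the within-cycle minimum, relative to
#' the cycle's amplitude range.
#'
#' @param signal Total GAW.
#' @param cycles_T Maximum-based \code{cycle_set}.
#' @param plateau_eps Relative threshold above the within-cycle minimum that
#'   still counts as "closed" (default 0.05).
#' @return Data frame with per-cycle columns \code{period_s},
#'   \code{closing_s}, \code{opening_s}, \code{plateau_s}, \code{a_min},
#'   \code{a_max}, \code{a_mean}.
#' @export
phase_landmarks <- function(signal, cycles_T, plateau_eps = 0.05) {
  stopifnot(inherits(cycles_T, "cycle_set"), cycles_T$basis == "maximum")
  if (cycles_T$n_cycles < 2)
    stop("too few cycles: need >= 2", call. = FALSE)
  spans <- cycle_spans(cycles_T)
  fs <- cycles_T$fs
  rows <- lapply(spans, function(s) {
    x <- signal[s]
    i_min <- which.min(x)  # earliest minimum on ties
    a_min <- x[i_min]; a_max <- max(x)
    thr <- a_min + plateau_eps * (a_max - a_min)
    data.frame(period_s = length(s) / fs,
               closing_s = (i_min - 1) / fs,
               opening_s = (length(s) - i_min + 1) / fs,
               plateau_s = sum(x <= thr) / fs,
               a_min = a_min, a_max = a_max, a_mean = mean(x))
  })
  do.call(rbind, rows)
}

#' Glottal-dynamic quotients
#'
#' Per cycle: Closing Quotient \eqn{CQ_i} = closing duration / period; Speed
#' Quotient \eqn{SQ_i} = opening / closing duration; Plateau Quotient
#' \eqn{PQ_i} = closed-plateau duration / period. Cycles with zero closing
#' duration are skipped for SQ with a warning.
#'
#' @param landmarks Output of \code{\link{phase_landmarks}}.
#' @return Named vector with \code{cq_mean, cq_std, sq_mean, sq_std, pq_mean,
#'   pq_std}.
#' @export
quotients <- function(landmarks) {
  cq <- landmarks$closing_s / landmarks$period_s
  pq <- landmarks$plateau_s / landmarks$period_s
  ok <- landmarks$closing_s > 0
  if (!all(ok)) warning("cycles with zero closing duration skipped for SQ")
  if (!any(ok)) stop("SQ undefined: all cycles have zero closing duration",
                     call. = FALSE)
  sq <- landmarks$opening_s[ok] / landmarks$closing_s[ok]
  c(cq_mean = mean(cq), cq_std = stats::sd(cq),
    sq_mean = mean(sq), sq_std = stats::sd(sq),
    pq_mean = mean(pq), pq_std = stats::sd(pq))
}

#' Glottal gap and area indices
#'
#' Per cycle: the Glottis Gap Index \eqn{GGI_i = A_{min}/A_{max}} (residual
#' glottal gap relative to the peak area) and the Glottal Area Index
#' \eqn{GAI_i = (\bar A - A_{min})/(A_{max} - A_{min})}, the normalized mean
#' open area.
#'
#' @param signal Total GAW.
#' @param cycles_T Maximum-based \code{cycle_set}.
#' @param landmarks Optional precomputed output of
#'   \code{\link{phase_landmarks}}; recomputed when \code{NULL}.
#' @return Named vector \code{c(ggi_mean, ggi_std, gai_mean, gai_std)}.
#' @export
gap_indices <- function(signal, cycles_T, landmarks = NULL) {
  if (is.null(landmarks)) landmarks <- phase_landmarks(signal, cycles_T)
  if (any(landmarks$a_max <= landmarks$a_min))
    stop("degenerate: flat cycle (A_max = A_min)", call. = FALSE)
  if (any(landmarks$a_max <= 0))
    stop("degenerate: non-positive cycle maximum", call. = FALSE)
  # measurement noise can push the within-cycle minimum slightly below zero;
  # a negative residual area is physically a full closure
  ggi <- pmax(landmarks$a_min, 0) / landmarks$a_max
  gai <- (landmarks$a_mean - landmarks$a_min) / (landmarks$a_max - landmarks$a_min)
  c(ggi_mean = mean(ggi), ggi_std = stats::sd(ggi),
    gai_mean = mean(gai), gai_std = stats::sd(gai))
}
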