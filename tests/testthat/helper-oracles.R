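# Independent brute-force distance-correlation oracle: explicit loops over
# the double-centering definition; shares no code with the implementation.
dcor_bruteforce <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    a[j, k] <- abs(x[j] - x[k]); b[j, k] <- abs(y[j] - y[k])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    A[j, k] <- a[j, k] - mean(a[j, ]) - mean(a[, k]) + mean(a)
    B[j, k] <- b[j, k] - mean(b[j, ]) - mean(b[, k]) + mean(b)
  }
  dcov2 <- 0; dvx <- 0; dvy <- 0
  for (j in 1:n) for (k in 1:n) {
    dcov2 <- dcov2 + A[j, k] * B[j, k]
    dvx <- dvx + A[j, k]^2
    dvy <- dvy + B[j, k]^2
  }
  dcov2 <- dcov2 / n^2; dvx <- dvx / n^2; dvy <- dvy / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0)) / sqrt(sqrt(dvx * dvy))
}

# Hand-rolled Benjamini-Yekutieli step-up oracle, straight from the
# order-statistic formula with harmonic-sum correction.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj_sorted <- m * cm * p[o] / seq_len(m)
  for (i in (m - 1):1) adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  pmin(adj_sorted, 1)[order(o)]
}
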