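# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-pixel loops, double loops over point pairs) so
# they cannot share a defect with the vectorized implementation.

diskMask <- function(shape, center, r) {
  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  (sqrt((rr - center[1])^2 + (cc - center[2])^2) <= r) * 1
}

bruteHausdorff <- function(a, b) {
  h <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  max(h(a, b), h(b, a))
}

bruteRegionMeans <- function(image, phi, eps) {
  num_i <- den_i <- num_o <- den_o <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    h <- 0.5 * (1 + (2 / pi) * atan(phi[i, j] / eps))
    num_i <- num_i + image[i, j] * h; den_i <- den_i + h
    num_o <- num_o + image[i, j] * (1 - h); den_o <- den_o + (1 - h)
  }
  c(num_i / den_i, num_o / den_o)
}

bruteContour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  at <- function(i, j) if (i < 1 || i > H || j < 1 || j > W) 0 else mask[i, j]
  pts <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 1 &&
        (at(i - 1, j) == 0 || at(i + 1, j) == 0 ||
         at(i, j - 1) == 0 || at(i, j + 1) == 0))
      pts <- rbind(pts, c(i - 1, j - 1))
  }
  pts
}

# Histogram entropy by direct counting, natural log.
bruteEntropy <- function(samples, nBins, lo = 0, hi = 255) {
  counts <- integer(nBins)
  for (s in samples) {
    b <- min(max(floor((s - lo) / (hi - lo) * nBins) + 1, 1), nBins)
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(samples)
  -sum(p * log(p))
}
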