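#' Equal-width histogram density estimate
#'
#' Bins the samples into \code{nBins} equal-width bins over \code{range} and
#' normalizes the counts to sum to 1. Samples outside the range are clipped
#' to the end bins, so the estimate is a proper probability vector for any
#' nonempty sample.
#'
#' @param samples numeric vector of intensities; must be nonempty.
#' @param nBins number of bins (>= 2).
#' @param range numeric \code{c(lo, hi)}, \code{hi > lo}.
#' @return list with \code{bin_edges} (length \code{nBins + 1}) and
#'   \code{probabilities} (length \code{nBins}, summing to 1).
#' @examples
#' estimateDensity(c(0, 0, 255, 255), 2, c(0, 255))$probabilities
#' @export
estimateDensity <- function(samples, nBins = 32L, range = c(0, 255)) {
  if (length(samples) == 0L) stop("empty region: cannot estimate a density")
  stopifnot(nBins >= 2L, range[2] > range[1])
  counts <- tabulate(binIndices(samples, nBins, range), nbins = nBins)
  list(bin_edges = seq(range[1], range[2], length.out = nBins + 1),
       probabilities = counts / sum(counts))
}

# Clipped equal-width bin index in 1..nBins.
binIndices <- function(samples, nBins, range = c(0, 255)) {
  b <- floor((samples - range[1]) / (range[2] - range[1]) * nBins) + 1
  pmin.int(pmax.int(b, 1L), nBins)
}

entropyFromCounts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Shannon entropy of a region's intensity histogram
#'
#' \eqn{E = -\sum_b p_b \log p_b} (natural log, nats) over the histogram of
#' the intensities inside \code{region}. Low entropy means a homogeneous
#' region; a constant region has entropy 0. Bounded above by
#' \eqn{\log(\code{nBins})}.
#'
#' @param image numeric intensity matrix.
#' @param region 0/1 matrix of the same shape selecting the region; must be
#'   nonempty.
#' @param nBins histogram bins.
#' @param range intensity range of the histogram.
#' @return nonnegative scalar entropy in nats.
#' @export
regionEntropy <- function(image, region, nBins = 32L, range = c(0, 255)) {
  assertMask(region)
  if (!identical(dim(image), dim(region)))
    stop("image and region shapes differ")
  if (sum(region) == 0) stop("empty region: entropy undefined")
  samples <- image[region == 1]
  entropyFromCounts(tabulate(binIndices(samples, nBins, range),
                             nbins = nBins))
}

#' Entropy weights of the interior and exterior of a level-set contour
#'
#' The adaptive weights of the entropy-weighted fitting energy: the interior
#' weight is the histogram entropy of the intensities where \eqn{\phi > 0},
#' the exterior weight that of \eqn{\phi \le 0}. Each is floored at
#' \code{weightFloor} so a perfectly homogeneous region cannot zero its
#' fitting term and freeze the evolution. The weights are recomputed every
#' iteration, so the balance between the two fitting terms adjusts as the
#' curve moves: the less homogeneous side always carries the larger weight,
#' and the energy settles when the two homogeneities are balanced.
#'
#' @param image numeric intensity matrix.
#' @param phi level-set field, same shape; interior is \eqn{\phi > 0}.
#' @param nBins histogram bins.
#' @param weightFloor lower bound on either weight.
#' @param range histogram intensity range.
#' @return numeric \code{c(E_in, E_out)} in nats (floored).
#' @export
entropyWeights <- function(image, phi, nBins = 32L, weightFloor = 0.05,
                           range = c(0, 255)) {
  if (!identical(dim(image), dim(phi)))
    stop("image and phi shapes differ")
  inside <- phi > 0
  nin <- sum(inside)
  if (nin == 0L || nin == length(phi))
    stop("contour collapse: one side of the level set is empty")
  bi <- binIndices(image, nBins, range)
  eIn <- entropyFromCounts(tabulate(bi[inside], nbins = nBins))
  eOut <- entropyFromCounts(tabulate(bi[!inside], nbins = nBins))
  c(E_in = max(eIn, weightFloor), E_out = max(eOut, weightFloor))
}
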