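#' Synthetic short-axis left-ventricle phantom with ground truth
#'
#' Renders the geometry of a black-blood mid-ventricular slice: a dark
#' blood-pool disk, a bright myocardial annulus, a mid-gray background and
#' optional bright distractor blobs (fat/muscle analogues that never touch
#' the epicardial disk), then applies a linear multiplicative bias field
#' across columns and additive Gaussian noise, clipping to [0, 255]. The
#' ground-truth masks come from the analytic geometry and are unaffected by
#' bias, noise or distractors. Output is bit-reproducible for a given spec.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{image} and the three 0/1 matrices
#'   \code{endo_mask}, \code{epi_mask}, \code{myo_mask}
#'   (\code{myo = epi AND NOT endo}).
#' @examples
#' ph <- makeLVPhantom(phantomSpec())
#' sum(ph$myo_mask) == sum(ph$epi_mask) - sum(ph$endo_mask)
#' @export
makeLVPhantom <- function(spec) {
  validObject(spec)
  H <- spec@shape[1]; W <- spec@shape[2]
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d <- sqrt((rr - spec@center[1])^2 + (cc - spec@center[2])^2)
  endo <- (d <= spec@rEndo) * 1
  epi <- (d <= spec@rEpi) * 1
  myo <- epi * (1 - endo)
  img <- matrix(spec@intensityBg, H, W)
  img[epi == 1] <- spec@intensityMyo
  img[endo == 1] <- spec@intensityBlood

  set.seed(spec@seed)
  if (spec@nDistractors > 0L) {
    placed <- 0L
    tries <- 0L
    while (placed < spec@nDistractors && tries < 1000L) {
      tries <- tries + 1L
      br <- stats::runif(1, 3, 7)
      brow <- stats::runif(1, br, H - 1 - br)
      bcol <- stats::runif(1, br, W - 1 - br)
      # keep blobs clear of the epicardial disk (2 px margin)
      if (sqrt((brow - spec@center[1])^2 + (bcol - spec@center[2])^2) <
          spec@rEpi + br + 2) next
      img[(rr - brow)^2 + (cc - bcol)^2 <= br^2] <-
        spec@distractorIntensity
      placed <- placed + 1L
    }
  }
  if (spec@biasAmplitude > 0) {
    bias <- 1 - spec@biasAmplitude +
      2 * spec@biasAmplitude * (cc / max(W - 1, 1))
    img <- img * bias
  }
  if (spec@noiseSigma > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, spec@noiseSigma), H, W)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, endo_mask = endo, epi_mask = epi, myo_mask = myo)
}

#' Draw annular circles on a constant background
#'
#' Deterministic ring-drawing fixture for circle-detection tests: each
#' circle is rendered as the set of pixels whose distance to the center is
#' within \code{thickness / 2} of the radius.
#'
#' @param shape \code{c(H, W)}.
#' @param circles data frame with columns \code{row}, \code{col},
#'   \code{radius} (0-based px); may have zero rows.
#' @param thickness ring thickness (px).
#' @param fg,bg ring and background intensities.
#' @return numeric \code{H x W} matrix.
#' @export
makeCircleImage <- function(shape, circles, thickness = 2, fg = 255,
                            bg = 0) {
  H <- shape[1]; W <- shape[2]
  img <- matrix(bg, H, W)
  if (nrow(circles) == 0L) return(img)
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (i in seq_len(nrow(circles))) {
    d <- sqrt((rr - circles$row[i])^2 + (cc - circles$col[i])^2)
    img[abs(d - circles$radius[i]) <= thickness / 2] <- fg
  }
  img
}

#' Two-region image with Gaussian intensities per region
#'
#' High-contrast bimodal fixture for the entropy-weighting experiments: the
#' foreground mask gets \code{N(muFg, sigma)} intensities, the rest
#' \code{N(muBg, sigma)}, clipped to [0, 255].
#'
#' @param shape \code{c(H, W)}.
#' @param objectMask 0/1 foreground mask of that shape.
#' @param muFg,muBg region mean intensities.
#' @param sigma common standard deviation (0 gives an exactly two-valued
#'   image).
#' @param seed RNG seed.
#' @return numeric \code{H x W} matrix.
#' @export
makeBimodalImage <- function(shape, objectMask, muFg, muBg, sigma = 0,
                             seed = 1L) {
  assertMask(objectMask)
  H <- shape[1]; W <- shape[2]
  set.seed(seed)
  img <- matrix(muBg, H, W)
  img[objectMask == 1] <- muFg
  if (sigma > 0) img <- img + matrix(stats::rnorm(H * W, 0, sigma), H, W)
  pmin(pmax(img, 0), 255)
}
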