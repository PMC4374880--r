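# Evolve one contour with the chosen model and return phi + iterations.
evolveOne <- function(image, phi0, method, evoCfg, cvCfg) {
  switch(method,
    smlv = runSMLV(image, phi0, evoCfg),
    `ncv-mode` = runSMLV(image, phi0, {
      n <- round(sum(dim(image)) / 16)
      initialize(evoCfg, winInit = as.integer(n), winMax = as.numeric(n),
                 fixedWeights = TRUE)
    }),
    cv = runCV(image, phi0, cvCfg, model = "cv"),
    ecv = runCV(image, phi0, cvCfg, model = "ecv",
                nBins = evoCfg@nBins, weightFloor = evoCfg@weightFloor),
    stop("unknown method: ", method)
  )
}

# Dual-contour evolution from a circle initialization; nesting enforced by
# intersecting the endocardial mask with the epicardial one.
evolveDual <- function(image, init, method, evoCfg, cvCfg) {
  shape <- dim(image)
  resEndo <- evolveOne(image, levelsetFromCircle(init@endocardial, shape),
                       method, evoCfg, cvCfg)
  resEpi <- evolveOne(image, levelsetFromCircle(init@epicardial, shape),
                      method, evoCfg, cvCfg)
  epi <- (resEpi$phi > 0) * 1
  endo <- (resEndo$phi > 0) * epi
  list(endo = endo, epi = epi, myo = epi * (1 - endo),
       itEndo = resEndo$iterations, itEpi = resEpi$iterations,
       diagEndo = resEndo$diagnostics, diagEpi = resEpi$diagnostics)
}

#' Segment the left-ventricular myocardium from a short-axis image
#'
#' The full automatic pipeline: circle detection by the circular Hough
#' transform, selection of the concentric epicardial/endocardial pair,
#' signed-distance initialization of two independent level sets, evolution
#' of each under the local entropy-weighted model, and thresholding
#' \eqn{\phi > 0} into masks with the endocardium intersected into the
#' epicardium so the myocardium is a well-defined annulus. Deterministic
#' for a fixed configuration.
#'
#' @param image numeric intensity matrix on the canonical [0, 255] scale
#'   (see [loadImage()]), at least 8 x 8.
#' @param cfg an [EvolutionConfig-class].
#' @param radiusMin,radiusMax,nPeaks,edgeQuantile,concentricityTol circle
#'   detection parameters, see [detectCircles()] and [selectLVPair()].
#' @return a [SegmentationResult-class].
#' @examples
#' ph <- makeLVPhantom(phantomSpec())
#' res <- segmentMyocardium(ph$image, evolutionConfig(maxIters = 40))
#' evaluateMasks(myoMask(res), ph$myo_mask)
#' @export
segmentMyocardium <- function(image, cfg = evolutionConfig(),
                              radiusMin = 0.05 * min(dim(image)),
                              radiusMax = 0.45 * min(dim(image)),
                              nPeaks = 8L, edgeQuantile = 0.9,
                              concentricityTol = 10) {
  assertImage(image, minSide = 8L)
  circles <- detectCircles(image, radiusMin, radiusMax, nPeaks,
                           edgeQuantile)
  if (nrow(circles) < 2L)
    stop("initialization failure: circle detection found ",
         nrow(circles), " circle(s)")
  init <- selectLVPair(circles, concentricityTol)
  ev <- evolveDual(image, init, "smlv", cfg, cvConfig())
  diag <- rbind(
    if (nrow(ev$diagEndo)) cbind(contour = "endo", ev$diagEndo),
    if (nrow(ev$diagEpi)) cbind(contour = "epi", ev$diagEpi))
  new("SegmentationResult",
      endoMask = ev$endo, epiMask = ev$epi, myoMask = ev$myo,
      init = init, iterationsEndo = as.integer(ev$itEndo),
      iterationsEpi = as.integer(ev$itEpi),
      diagnostics = if (is.null(diag)) data.frame() else diag,
      config = cfg)
}

#' Compare segmentation models on one image with shared initialization
#'
#' Runs any subset of the global Chan--Vese model (\code{"cv"}), its
#' entropy-weighted variant (\code{"ecv"}), the fixed-window local
#' comparator (\code{"ncv-mode"}) and the full adaptive local model
#' (\code{"smlv"}) from the same circle initialization, and scores each
#' myocardium mask against the truth.
#'
#' @param image numeric intensity matrix.
#' @param truthMyo ground-truth myocardium mask.
#' @param methods character vector drawn from
#'   \code{c("cv", "ecv", "ncv-mode", "smlv")}.
#' @param init an [LVCircleInit-class]; by default detected from the image.
#' @param evoCfg configuration for the local models.
#' @param cvCfg configuration for the global models.
#' @return data frame with one row per method: \code{dice}, \code{me},
#'   \code{hd}, and iterations for both contours.
#' @export
compareMethods <- function(image, truthMyo,
                           methods = c("cv", "ecv", "ncv-mode", "smlv"),
                           init = NULL, evoCfg = evolutionConfig(),
                           cvCfg = cvConfig()) {
  bad <- setdiff(methods, c("cv", "ecv", "ncv-mode", "smlv"))
  if (length(bad)) stop("unknown method name(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(init)) {
    circles <- detectCircles(image)
    init <- selectLVPair(circles)
  }
  rows <- lapply(methods, function(m) {
    ev <- evolveDual(image, init, m, evoCfg, cvCfg)
    met <- evaluateMasks(ev$myo, truthMyo)
    data.frame(method = m, dice = met[["dice"]], me = met[["me"]],
               hd = met[["hd"]], iterations_endo = ev$itEndo,
               iterations_epi = ev$itEpi)
  })
  do.call(rbind, rows)
}
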