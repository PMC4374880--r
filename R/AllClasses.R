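#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Evolution configuration for the local entropy-weighted level-set model
#'
#' Holds every tunable of the local model: the area penalty, the explicit
#' Euler time step, the Gaussian regularization width, the regularized
#' Heaviside width, the narrow-band width, the adaptive-window limits and
#' entropy threshold, the histogram settings for entropy estimation, and the
#' stopping rule.
#'
#' @slot nu area-term weight \eqn{\nu}; positive values shrink the contour.
#' @slot dt explicit Euler time step \eqn{\Delta t}.
#' @slot xi standard deviation (px) of the Gaussian kernel that regularizes
#'   the level-set field each iteration; must exceed \code{sqrt(dt)}.
#' @slot eps width of the regularized Heaviside/Dirac pair (px).
#' @slot bandWidth half-width (px) of the narrow band \eqn{|\phi| <}
#'   \code{bandWidth} whose points carry local windows.
#' @slot winInit initial window half-size (px).
#' @slot winMax maximum window half-size (px); \code{NULL} means
#'   \code{round((H + W)/16)} for the image at hand, the optimal fixed
#'   neighborhood size reported for the fixed-window comparator.
#' @slot winEntropyThreshold entropy (nats) a window must reach before it
#'   stops growing.
#' @slot nBins histogram bins for all entropy estimates.
#' @slot weightFloor lower bound applied to entropy weights so a perfectly
#'   homogeneous region cannot zero its fitting term.
#' @slot fixedWeights if \code{TRUE}, local entropy weights are replaced by
#'   1 (the fixed-window comparator, and the limit-case reduction to the
#'   global model).
#' @slot maxIters iteration cap.
#' @slot tol relative-area stopping tolerance.
#' @slot tolWindow number of consecutive iterations the tolerance must hold.
#' @slot seed integer seed recorded for reproducibility of any stochastic
#'   caller (the evolution itself is deterministic).
#' @seealso [evolutionConfig()] for the user-facing constructor with
#'   defaults, [runSMLV()], [segmentMyocardium()].
#' @export
setClass("EvolutionConfig",
  representation(
    nu = "numeric", dt = "numeric", xi = "numeric", eps = "numeric",
    bandWidth = "numeric", winInit = "integer", winMax = "numericOrNULL",
    winEntropyThreshold = "numeric", nBins = "integer",
    weightFloor = "numeric", fixedWeights = "logical",
    maxIters = "integer", tol = "numeric", tolWindow = "integer",
    seed = "integer"
  )
)

setValidity("EvolutionConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@xi <= 0) msg <- c(msg, "xi must be positive")
  if (object@xi <= sqrt(object@dt))
    msg <- c(msg, "xi must exceed sqrt(dt) for the Gaussian regularizer")
  if (object@eps <= 0) msg <- c(msg, "eps must be positive")
  if (object@bandWidth < object@eps)
    msg <- c(msg, "bandWidth must be at least eps")
  if (object@winInit < 1L) msg <- c(msg, "winInit must be >= 1")
  if (!is.null(object@winMax) && object@winMax < object@winInit)
    msg <- c(msg, "winMax must be >= winInit")
  if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
  if (object@weightFloor < 0) msg <- c(msg, "weightFloor must be >= 0")
  if (object@maxIters < 0L) msg <- c(msg, "maxIters must be >= 0")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an evolution configuration
#'
#' Defaults follow the study conditions of the local model: \code{nu = 0.05}
#' (the value used for the method on every patient), a small time step
#' \code{dt = 0.05} to compensate for summation over overlapping windows,
#' Gaussian width \code{xi = 1} (larger than \code{sqrt(dt)} as the
#' regularizer requires), Heaviside width 1.5 px, a 3 px narrow band, windows
#' growing from half-size 4 up to \code{(H + W)/16}, a 0.5-nat window entropy
#' threshold, and 32 histogram bins on the canonical [0, 255] range.
#'
#' @param nu,dt,xi,eps,bandWidth,winInit,winMax,winEntropyThreshold,nBins,weightFloor,fixedWeights,maxIters,tol,tolWindow,seed
#'   see the slot documentation of [EvolutionConfig-class].
#' @return A validated [EvolutionConfig-class] object.
#' @examples
#' cfg <- evolutionConfig(maxIters = 50)
#' cfg
#' @export
evolutionConfig <- function(nu = 0.05, dt = 0.05, xi = 1.0, eps = 1.5,
                            bandWidth = 3, winInit = 4L, winMax = NULL,
                            winEntropyThreshold = 0.5, nBins = 32L,
                            weightFloor = 0.05, fixedWeights = FALSE,
                            maxIters = 200L, tol = 1e-4, tolWindow = 5L,
                            seed = 1L) {
  new("EvolutionConfig",
    nu = nu, dt = dt, xi = xi, eps = eps, bandWidth = bandWidth,
    winInit = as.integer(winInit),
    winMax = if (is.null(winMax)) NULL else as.numeric(winMax),
    winEntropyThreshold = winEntropyThreshold, nBins = as.integer(nBins),
    weightFloor = weightFloor, fixedWeights = fixedWeights,
    maxIters = as.integer(maxIters), tol = tol,
    tolWindow = as.integer(tolWindow), seed = as.integer(seed)
  )
}

#' Fixed-window comparator configuration (NCV mode)
#'
#' The fixed-window local Chan--Vese comparator: window half-size pinned at
#' \code{(H + W)/16} for an \code{H x W} image and entropy weights replaced
#' by 1, so only the localization differs from the full model.
#'
#' @param shape integer vector \code{c(H, W)} of the target image.
#' @param ... further arguments passed to [evolutionConfig()].
#' @return An [EvolutionConfig-class] with a fixed window and unit weights.
#' @export
ncvConfig <- function(shape, ...) {
  n <- round(sum(shape[1:2]) / 16)
  evolutionConfig(winInit = n, winMax = n, fixedWeights = TRUE, ...)
}

#' Configuration of the global Chan--Vese baselines
#'
#' Parameters of the piecewise-constant two-region energy: length weight
#' \code{mu}, area weight \code{nu}, interior/exterior fitting weights
#' \code{lambdaIn}/\code{lambdaOut}, the time step, the Heaviside width and
#' the stopping rule. The entropy-weighted variant ignores the lambdas and
#' substitutes region entropies.
#'
#' @slot mu length-term weight.
#' @slot nu area-term weight.
#' @slot lambdaIn,lambdaOut interior/exterior fitting weights.
#' @slot dt explicit Euler time step.
#' @slot eps regularized Heaviside width (px).
#' @slot maxIters,tol,tolWindow stopping rule (as in
#'   [EvolutionConfig-class]).
#' @export
setClass("CVConfig",
  representation(
    mu = "numeric", nu = "numeric", lambdaIn = "numeric",
    lambdaOut = "numeric", dt = "numeric", eps = "numeric",
    maxIters = "integer", tol = "numeric", tolWindow = "integer"
  )
)

setValidity("CVConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@eps <= 0) msg <- c(msg, "eps must be positive")
  if (object@maxIters < 0L) msg <- c(msg, "maxIters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Chan--Vese baseline configuration
#'
#' Defaults are the high-contrast synthetic-image setting (\code{mu =
#' 0.01 * 255^2}, \code{nu = 0}, unit lambdas); the clinical parameter rows
#' are available through [cvTable1Preset()].
#'
#' @param mu,nu,lambdaIn,lambdaOut,dt,eps,maxIters,tol,tolWindow see
#'   [CVConfig-class].
#' @return A validated [CVConfig-class].
#' @export
cvConfig <- function(mu = 0.01 * 255^2, nu = 0, lambdaIn = 1, lambdaOut = 1,
                     dt = 0.1, eps = 1.5, maxIters = 400L, tol = 1e-4,
                     tolWindow = 5L) {
  new("CVConfig",
    mu = mu, nu = nu, lambdaIn = lambdaIn, lambdaOut = lambdaOut,
    dt = dt, eps = eps, maxIters = as.integer(maxIters), tol = tol,
    tolWindow = as.integer(tolWindow)
  )
}

#' Clinical Chan--Vese parameter presets
#'
#' The published per-patient parameter rows for the global model:
#' \code{lambdaIn = lambdaOut = 1}, \code{mu = 0.5 * 255^2},
#' \code{nu = 0.2}, identical for all three reported patients.
#'
#' @param patient patient index 1--3 (rows are identical; the argument is
#'   kept so configurations are addressable the way they were reported).
#' @param ... overrides passed to [cvConfig()].
#' @return A [CVConfig-class].
#' @export
cvTable1Preset <- function(patient = 1L, ...) {
  stopifnot(patient %in% 1:3)
  cvConfig(mu = 0.5 * 255^2, nu = 0.2, lambdaIn = 1, lambdaOut = 1, ...)
}

#' Detected left-ventricle circle pair
#'
#' The circular-Hough initialization: the epicardial (outer) and endocardial
#' (inner) circles, each a named numeric vector with elements \code{row},
#' \code{col}, \code{radius}, \code{votes} (0-based pixel-center
#' coordinates).
#'
#' @slot epicardial,endocardial named numeric vectors
#'   \code{(row, col, radius, votes)}.
#' @slot concentricityTol the tolerance (px) the pair was selected under.
#' @export
setClass("LVCircleInit",
  representation(
    epicardial = "numeric", endocardial = "numeric",
    concentricityTol = "numeric"
  )
)

setValidity("LVCircleInit", function(object) {
  need <- c("row", "col", "radius", "votes")
  msg <- character()
  if (!all(need %in% names(object@epicardial)) ||
      !all(need %in% names(object@endocardial)))
    msg <- c(msg, "circles need named elements row, col, radius, votes")
  else {
    if (object@endocardial[["radius"]] >= object@epicardial[["radius"]])
      msg <- c(msg, "endocardial radius must be smaller than epicardial")
    d <- sqrt((object@epicardial[["row"]] - object@endocardial[["row"]])^2 +
              (object@epicardial[["col"]] - object@endocardial[["col"]])^2)
    if (d > object@concentricityTol)
      msg <- c(msg, "circle centers exceed the concentricity tolerance")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic short-axis phantom specification
#'
#' Geometry and appearance of a black-blood-like left-ventricle phantom: a
#' dark blood pool (disk), a bright myocardial annulus, a mid-gray
#' background, optional bright distractor blobs (fat/muscle analogues), a
#' linear multiplicative bias field across columns, and additive Gaussian
#' noise. Identical spec and seed give bit-identical output.
#'
#' @slot shape integer \code{c(H, W)}.
#' @slot center numeric \code{c(row, col)} of the ventricle (0-based).
#' @slot rEndo,rEpi endocardial/epicardial radii (px).
#' @slot intensityBlood,intensityMyo,intensityBg region intensities on the
#'   canonical [0, 255] scale.
#' @slot biasAmplitude multiplicative bias spans
#'   \code{[1 - biasAmplitude, 1 + biasAmplitude]} across columns.
#' @slot noiseSigma additive Gaussian noise standard deviation.
#' @slot nDistractors number of bright background blobs.
#' @slot distractorIntensity intensity of the blobs.
#' @slot seed RNG seed.
#' @seealso [phantomSpec()], [makeLVPhantom()].
#' @export
setClass("PhantomSpec",
  representation(
    shape = "integer", center = "numeric", rEndo = "numeric",
    rEpi = "numeric", intensityBlood = "numeric", intensityMyo = "numeric",
    intensityBg = "numeric", biasAmplitude = "numeric",
    noiseSigma = "numeric", nDistractors = "integer",
    distractorIntensity = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@shape < 8L)) msg <- c(msg, "shape must be at least 8 x 8")
  if (!(object@rEndo > 0 && object@rEndo < object@rEpi))
    msg <- c(msg, "need 0 < rEndo < rEpi")
  if (object@rEpi >= min(object@shape) / 2)
    msg <- c(msg, "rEpi must be below min(H, W)/2")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 1)
    msg <- c(msg, "biasAmplitude must be in [0, 1)")
  if (object@nDistractors < 0L) msg <- c(msg, "nDistractors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom specification
#'
#' Defaults emulate a mid-ventricular short-axis black-blood slice at
#' roughly 1.6 mm/px: a 128 x 128 grid, cavity radius 16 px, epicardial
#' radius 26 px, dark blood (30), bright myocardium (150), mid-gray
#' surroundings (80) and bright distractors (200).
#'
#' @param shape,center,rEndo,rEpi,intensityBlood,intensityMyo,intensityBg,biasAmplitude,noiseSigma,nDistractors,distractorIntensity,seed
#'   see [PhantomSpec-class].
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(noiseSigma = 10, seed = 7L)
#' ph <- makeLVPhantom(spec)
#' str(ph$image[1:2, 1:2])
#' @export
phantomSpec <- function(shape = c(128L, 128L), center = NULL, rEndo = 16,
                        rEpi = 26, intensityBlood = 30, intensityMyo = 150,
                        intensityBg = 80, biasAmplitude = 0,
                        noiseSigma = 0, nDistractors = 0L,
                        distractorIntensity = 200, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape - 1) / 2
  new("PhantomSpec",
    shape = shape, center = as.numeric(center), rEndo = rEndo, rEpi = rEpi,
    intensityBlood = intensityBlood, intensityMyo = intensityMyo,
    intensityBg = intensityBg, biasAmplitude = biasAmplitude,
    noiseSigma = noiseSigma, nDistractors = as.integer(nDistractors),
    distractorIntensity = distractorIntensity, seed = as.integer(seed)
  )
}

#' Result of a full myocardium segmentation
#'
#' Endocardial, epicardial and myocardial binary masks (the myocardium is
#' exactly the epicardial mask minus the endocardial mask), the circle
#' initialization, iteration counts for both contours and the per-iteration
#' diagnostic table (entropy weights, interior areas, largest level-set
#' update).
#'
#' @slot endoMask,epiMask,myoMask 0/1 matrices of the image shape.
#' @slot init the [LVCircleInit-class] used.
#' @slot iterationsEndo,iterationsEpi iterations run for each contour.
#' @slot diagnostics data frame with one row per (contour, iteration).
#' @slot config the [EvolutionConfig-class] actually used.
#' @export
setClass("SegmentationResult",
  representation(
    endoMask = "matrix", epiMask = "matrix", myoMask = "matrix",
    init = "LVCircleInit", iterationsEndo = "integer",
    iterationsEpi = "integer", diagnostics = "data.frame",
    config = "EvolutionConfig"
  )
)

setValidity("SegmentationResult", function(object) {
  msg <- character()
  if (!identical(dim(object@endoMask), dim(object@epiMask)) ||
      !identical(dim(object@endoMask), dim(object@myoMask)))
    msg <- c(msg, "masks must share a shape")
  if (any(object@endoMask > object@epiMask))
    msg <- c(msg, "endocardial mask must be nested inside the epicardial")
  if (!identical(object@myoMask,
                 object@epiMask * (1 - object@endoMask)))
    msg <- c(msg, "myoMask must equal epiMask AND NOT endoMask")
  if (length(msg)) msg else TRUE
})

#' @describeIn SegmentationResult-class endocardial (blood-pool) mask.
#' @param object a \code{SegmentationResult}.
#' @export
setGeneric("endoMask", function(object) standardGeneric("endoMask"))
#' @describeIn SegmentationResult-class epicardial mask.
#' @export
setGeneric("epiMask", function(object) standardGeneric("epiMask"))
#' @describeIn SegmentationResult-class myocardial (annulus) mask.
#' @export
setGeneric("myoMask", function(object) standardGeneric("myoMask"))
#' @describeIn SegmentationResult-class circle initialization used.
#' @export
setGeneric("initCircles", function(object) standardGeneric("initCircles"))
#' @describeIn SegmentationResult-class per-iteration diagnostics.
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))
#' @describeIn SegmentationResult-class iterations per contour, named vector.
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))

setMethod("endoMask", "SegmentationResult", function(object) object@endoMask)
setMethod("epiMask", "SegmentationResult", function(object) object@epiMask)
setMethod("myoMask", "SegmentationResult", function(object) object@myoMask)
setMethod("initCircles", "SegmentationResult", function(object) object@init)
setMethod("diagnostics", "SegmentationResult",
          function(object) object@diagnostics)
setMethod("iterations", "SegmentationResult", function(object)
  c(endo = object@iterationsEndo, epi = object@iterationsEpi))

setMethod("show", "EvolutionConfig", function(object) {
  cat("EvolutionConfig\n")
  cat(sprintf("  nu=%g dt=%g xi=%g eps=%g band=%g\n",
              object@nu, object@dt, object@xi, object@eps,
              object@bandWidth))
  cat(sprintf("  window half-size %d..%s, entropy threshold %g nats (%s)\n",
              object@winInit,
              if (is.null(object@winMax)) "(H+W)/16"
              else as.character(object@winMax),
              object@winEntropyThreshold,
              if (object@fixedWeights) "unit weights"
              else sprintf("%d bins, floor %g", object@nBins,
                           object@weightFloor)))
  cat(sprintf("  stop: tol %g over %d iters, max %d\n",
              object@tol, object@tolWindow, object@maxIters))
})

setMethod("show", "CVConfig", function(object) {
  cat("CVConfig (global Chan-Vese)\n")
  cat(sprintf("  mu=%g nu=%g lambda=(%g, %g) dt=%g eps=%g max=%d\n",
              object@mu, object@nu, object@lambdaIn, object@lambdaOut,
              object@dt, object@eps, object@maxIters))
})

setMethod("show", "LVCircleInit", function(object) {
  cat("LVCircleInit\n")
  fmt <- function(x) sprintf("center (%.1f, %.1f) r=%.1f votes=%.3f",
                             x[["row"]], x[["col"]], x[["radius"]],
                             x[["votes"]])
  cat("  epicardial:  ", fmt(object@epicardial), "\n", sep = "")
  cat("  endocardial: ", fmt(object@endocardial), "\n", sep = "")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%d, rEndo=%g rEpi=%g\n", object@shape[1],
              object@shape[2], object@rEndo, object@rEpi))
  cat(sprintf("  intensities blood/myo/bg = %g/%g/%g; bias +/-%g%%, noise sd %g, %d distractor(s), seed %d\n",
              object@intensityBlood, object@intensityMyo, object@intensityBg,
              100 * object@biasAmplitude, object@noiseSigma,
              object@nDistractors, object@seed))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult %dx%d\n", nrow(object@myoMask),
              ncol(object@myoMask)))
  cat(sprintf("  endo: %d px (%d iters); epi: %d px (%d iters); myocardium: %d px\n",
              sum(object@endoMask), object@iterationsEndo,
              sum(object@epiMask), object@iterationsEpi,
              sum(object@myoMask)))
})
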