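#' Detect circles with a circular Hough transform
#'
#' Feature points are edge pixels whose central-difference gradient
#' magnitude lies in the top quantile of the image and above 20 percent of
#' the peak gradient (the latter keeps smooth intensity shading, such as a
#' bias field, from flooding the feature set). Each edge pixel votes
#' for every (center, radius) combination consistent with it at integer
#' radius steps, and accumulator peaks are extracted by non-maximum
#' suppression over a (radius/2)-px center neighborhood crossed with a
#' \code{max(2, radius/6)}-px radius neighborhood, so one circle cannot
#' produce near-duplicate peaks while the concentric borders of an annulus
#' as thin as a myocardial wall both survive. Scores are
#' perimeter-normalized (votes divided by the number of perimeter offsets at
#' that radius), making circles of different radii comparable.
#'
#' @param image numeric intensity matrix.
#' @param radiusMin,radiusMax radius search range (px); must satisfy
#'   \code{0 < radiusMin < radiusMax < min(H, W)/2}.
#' @param nPeaks maximum number of circles returned.
#' @param edgeQuantile quantile of gradient magnitude above which a pixel is
#'   a feature point (default keeps the strongest 10 percent).
#' @return data frame with columns \code{row}, \code{col} (0-based center),
#'   \code{radius} and \code{votes} (normalized score), sorted by
#'   descending votes; zero rows when the image has no edges.
#' @examples
#' img <- makeCircleImage(c(64, 64),
#'   data.frame(row = 31, col = 31, radius = 18))
#' detectCircles(img, 8, 28)[1, ]
#' @export
detectCircles <- function(image, radiusMin = 0.05 * min(dim(image)),
                          radiusMax = 0.45 * min(dim(image)),
                          nPeaks = 8L, edgeQuantile = 0.9) {
  assertImage(image, minSide = 8L)
  H <- nrow(image); W <- ncol(image)
  if (!(radiusMin > 0 && radiusMin < radiusMax &&
        radiusMax < min(H, W) / 2))
    stop("invalid radius range: need 0 < radiusMin < radiusMax < min(H, W)/2")
  stopifnot(nPeaks >= 1L)

  gx <- (shiftCols(image, 1L) - shiftCols(image, -1L)) / 2
  gy <- (shiftRows(image, 1L) - shiftRows(image, -1L)) / 2
  gm <- sqrt(gx^2 + gy^2)
  # quantile keeps the feature-point count bounded; the relative floor at
  # 20 percent of the peak gradient rejects smooth shading (bias fields)
  # whose gentle slopes would otherwise flood the top quantile
  thr <- max(stats::quantile(gm, edgeQuantile, names = FALSE),
             0.2 * max(gm))
  edge <- which(gm >= thr & gm > 0)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), votes = numeric(0))
  if (length(edge) == 0L) return(empty)
  eRow <- (edge - 1L) %% H + 1L
  eCol <- (edge - 1L) %/% H + 1L

  radii <- seq(ceiling(radiusMin), floor(radiusMax))
  acc <- array(0, c(H, W, length(radii)))
  for (k in seq_along(radii)) {
    r <- radii[k]
    th <- seq(0, 2 * pi, length.out = max(16L, ceiling(2 * pi * r)) + 1L)
    th <- th[-length(th)]
    off <- unique(cbind(round(r * cos(th)), round(r * sin(th))))
    cr <- rep(eRow, each = nrow(off)) + off[, 1]
    cc <- rep(eCol, each = nrow(off)) + off[, 2]
    ok <- cr >= 1L & cr <= H & cc >= 1L & cc <= W
    idx <- (cc[ok] - 1L) * H + cr[ok]
    acc[, , k] <- acc[, , k] + tabulate(idx, nbins = H * W) / nrow(off)
  }

  rowArr <- matrix(seq_len(H), H, W)
  colArr <- matrix(seq_len(W), H, W, byrow = TRUE)
  peaks <- empty
  for (p in seq_len(nPeaks)) {
    m <- which.max(acc)
    v <- acc[m]
    if (!is.finite(v) || v <= 0) break
    k <- (m - 1L) %/% (H * W) + 1L
    rest <- (m - 1L) %% (H * W)
    i <- rest %% H + 1L
    j <- rest %/% H + 1L
    r <- radii[k]
    peaks <- rbind(peaks, data.frame(row = i - 1, col = j - 1,
                                     radius = r, votes = v))
    near <- (rowArr - i)^2 + (colArr - j)^2 < (r / 2)^2
    # radial suppression only spans near-duplicate scale: a concentric
    # endocardial circle sits well inside r/2 of the epicardial radius and
    # must survive as its own peak
    for (kk in which(abs(radii - r) < max(2, r / 6))) {
      plane <- acc[, , kk]
      plane[near] <- -Inf
      acc[, , kk] <- plane
    }
  }
  peaks[order(-peaks$votes), , drop = FALSE]
}

#' Select the epicardial/endocardial circle pair
#'
#' Searches all ordered (outer, inner) pairs with \code{inner radius <
#' outer radius} and center distance within \code{concentricityTol}, and
#' returns the pair maximizing the summed accumulator score. Both
#' ventricular borders enjoy strong perimeter support, so the jointly
#' best-supported concentric pair is the ventricle even when a single
#' spurious blob outscores one of the two true circles. A bright structure
#' near the ventricle can leave no admissible pair; that is the known
#' failure mode of Hough initialization and is raised as an error rather
#' than guessed around.
#'
#' @param circles data frame from [detectCircles()] with at least two rows.
#' @param concentricityTol maximum center distance (px) between the two
#'   circles.
#' @return an [LVCircleInit-class].
#' @export
selectLVPair <- function(circles, concentricityTol = 10) {
  if (nrow(circles) < 2L)
    stop("initialization failure: fewer than two circles detected")
  best <- NULL
  for (a in seq_len(nrow(circles))) for (b in seq_len(nrow(circles))) {
    if (a == b) next
    outer <- circles[a, ]; inner <- circles[b, ]
    if (inner$radius >= outer$radius) next
    d <- sqrt((outer$row - inner$row)^2 + (outer$col - inner$col)^2)
    if (d > concentricityTol) next
    key <- outer$votes + inner$votes
    if (is.null(best) || key > best$key)
      best <- list(outer = outer, inner = inner, key = key)
  }
  if (is.null(best))
    stop("initialization failure: no concentric inner circle found")
  asVec <- function(x) c(row = x$row, col = x$col, radius = x$radius,
                         votes = x$votes)
  new("LVCircleInit", epicardial = asVec(best$outer),
      endocardial = asVec(best$inner),
      concentricityTol = concentricityTol)
}

#' Signed-distance level-set field of a circle
#'
#' \eqn{\phi(r, c) = R - \|(r, c) - \mathrm{center}\|}: positive inside,
#' zero on the circle, negative outside, and an exact signed distance
#' (\eqn{|\nabla\phi| = 1} away from the center).
#'
#' @param circle named vector or one-row data frame with \code{row},
#'   \code{col}, \code{radius} (0-based pixel units).
#' @param shape integer \code{c(H, W)}.
#' @return numeric \code{H x W} level-set field.
#' @export
levelsetFromCircle <- function(circle, shape) {
  circle <- as.list(circle)
  H <- shape[1]; W <- shape[2]
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  circle$radius - sqrt((rr - circle$row)^2 + (cc - circle$col)^2)
}
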