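#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} between two foreground masks; 1 for
#' identical masks, 0 for disjoint ones; symmetric.
#'
#' @param fManual,fAuto 0/1 matrices of the same shape, at least one
#'   nonempty.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(fManual, fAuto) {
  assertMask(fManual); assertMask(fAuto)
  if (!identical(dim(fManual), dim(fAuto))) stop("mask shapes differ")
  denom <- sum(fManual) + sum(fAuto)
  if (denom == 0) stop("undefined metric: both masks are empty")
  2 * sum(fManual * fAuto) / denom
}

#' Misclassification error against a manual partition
#'
#' \eqn{ME = 1 - (|B_M \cap B_A| + |F_M \cap F_A|) / (|B_M| + |F_M|)}: the
#' fraction of pixels whose foreground/background label disagrees with the
#' manual reference. Unlike Dice it is not symmetric in its arguments (the
#' manual masks define the denominator).
#'
#' @param manualFg,manualBg manual foreground/background masks; must
#'   partition the grid.
#' @param autoFg,autoBg automatic masks; must partition the grid.
#' @return scalar in [0, 1].
#' @export
misclassificationError <- function(manualFg, manualBg, autoFg, autoBg) {
  for (m in list(manualFg, manualBg, autoFg, autoBg)) assertMask(m)
  if (!identical(dim(manualFg), dim(autoFg))) stop("mask shapes differ")
  if (!all(manualFg + manualBg == 1) || !all(autoFg + autoBg == 1))
    stop("foreground and background must partition the grid")
  1 - (sum(manualBg * autoBg) + sum(manualFg * autoFg)) /
    (sum(manualBg) + sum(manualFg))
}

#' Hausdorff distance between two point sets
#'
#' \eqn{\max[h(A, B), h(B, A)]} with directed distance
#' \eqn{h(A, B) = \max_{a \in A} \min_{b \in B} \|a - b\|}. Intended for
#' contour point sets (pixel centers) as produced by [contourFromMask()];
#' it measures the worst boundary disagreement in pixels.
#'
#' @param a,b two-column \code{(row, col)} matrices, both nonempty.
#' @return nonnegative scalar (px).
#' @export
hausdorffDistance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("undefined metric: empty point set")
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  hAB <- max(apply(d2, 1, min))
  hBA <- max(apply(d2, 2, min))
  sqrt(max(hAB, hBA))
}

#' Evaluate an automatic mask against a manual mask
#'
#' Computes the three standard figures at once: Dice overlap,
#' misclassification error (backgrounds taken as the mask complements) and
#' the Hausdorff distance between the two extracted contours.
#'
#' @param autoMask,manualMask 0/1 matrices of the same shape.
#' @return named numeric \code{c(dice, me, hd)}.
#' @examples
#' m <- matrix(0, 16, 16); m[5:12, 5:12] <- 1
#' a <- matrix(0, 16, 16); a[5:12, 6:13] <- 1
#' evaluateMasks(a, m)
#' @export
evaluateMasks <- function(autoMask, manualMask) {
  c(dice = diceCoefficient(manualMask, autoMask),
    me = misclassificationError(manualMask, 1 - manualMask,
                                autoMask, 1 - autoMask),
    hd = hausdorffDistance(contourFromMask(manualMask),
                           contourFromMask(autoMask)))
}
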