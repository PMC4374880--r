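#' Read a grayscale image and canonicalize its intensity range
#'
#' Reads a PNG or TIFF image, averages RGB channels to luminance if needed,
#' and rescales intensities linearly to [0, 255]. A constant image has no
#' usable range and maps to all zeros. All downstream parameter scalings
#' (histogram range, the \code{255^2}-scaled length weights of the global
#' model) presume this canonical range.
#'
#' @param path path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @return A numeric \code{H x W} matrix in [0, 255], row-major with the
#'   origin at the top-left; pixel centers sit at integer (0-based)
#'   coordinates.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)")
  )
  if (length(img) == 0L) stop("zero-sized image: ", path)
  if (length(dim(img)) == 3L) {
    # average the color channels (alpha, if present, is ignored)
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img <- matrix(as.numeric(img), nrow = nrow(img))
  if (!all(is.finite(img))) stop("image contains non-finite values: ", path)
  rescaleIntensity(img)
}

#' Linear rescale of a numeric grid to [0, 255]
#'
#' @param values numeric matrix.
#' @return matrix with min 0 and max 255; a constant input returns zeros.
#' @export
rescaleIntensity <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(array(0, dim(values)))
  (values - rng[1]) / diff(rng) * 255
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (1) is written as 255, background as 0; the file round-trips
#' exactly through [loadMask()].
#'
#' @param mask 0/1 matrix.
#' @param path output PNG path.
#' @export
saveMask <- function(mask, path) {
  assertMask(mask)
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)  # 0/1 -> 8-bit 0/255
  invisible(NULL)
}

#' Read a binary mask written by [saveMask()]
#'
#' @param path PNG path.
#' @return 0/1 matrix.
#' @export
loadMask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- matrix(as.numeric(img >= 0.5), nrow = nrow(img))
  m
}

assertMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("mask values must be strictly 0/1")
  invisible(TRUE)
}

assertImage <- function(image, minSide = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (!all(is.finite(image))) stop("image values must all be finite")
  if (any(dim(image) < minSide))
    stop("image must be at least ", minSide, " x ", minSide)
  invisible(TRUE)
}

#' Boundary pixels of a binary mask
#'
#' Returns the foreground pixels 4-adjacent to background; pixels beyond the
#' image border count as background, so a full-frame mask yields the image
#' border. This 1-pixel-thick digital contour is the point set the Hausdorff
#' distance operates on.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return two-column matrix of 0-based \code{(row, col)} pixel-center
#'   coordinates in row-major order.
#' @export
contourFromMask <- function(mask) {
  assertMask(mask)
  if (sum(mask) == 0) stop("empty mask: no contour")
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb <- pad[1:H, 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
        pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)]
  boundary <- core == 1 & nb < 4
  idx <- which(t(boundary))  # row-major order
  cbind(row = (idx - 1L) %/% W, col = (idx - 1L) %% W)
}

#' Write a contour point set as CSV
#'
#' @param points two-column \code{(row, col)} matrix, as produced by
#'   [contourFromMask()].
#' @param path output path; the file has header \code{row,col}.
#' @export
writeContourCSV <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(NULL)
}

#' Write a metrics report as JSON
#'
#' @param report named list or named numeric vector (e.g. the result of
#'   [evaluateMasks()]).
#' @param path output JSON path.
#' @export
writeMetricsJSON <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}
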