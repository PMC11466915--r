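#' Pixel-to-area calibration from a plate image
#'
#' Segments a bright calibration plate of known physical area from a dark
#' background and returns the mm2-per-pixel conversion factor,
#' `known_area_mm2 / plate pixel count`.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param known_area_mm2 physical plate area in mm2 (> 0).
#' @param value_threshold brightness (HSV value) above which a pixel belongs
#'   to the plate.
#' @return mm2-per-pixel factor (positive, finite).
#' @export
calibrate_pixel_area <- function(image, known_area_mm2, value_threshold = 0.7) {
  assert_that(is.finite(known_area_mm2) && known_area_mm2 > 0,
              "known_area_mm2 must be > 0")
  v <- pmax(image[, , 1], image[, , 2], image[, , 3])
  n <- sum(v > value_threshold)
  if (n == 0) stop("no plate pixels found in calibration image", call. = FALSE)
  known_area_mm2 / n
}

.hsv_planes <- function(image) {
  d <- dim(image)
  hsv <- rgb2hsv(r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
                 b = as.vector(image[, , 3]), maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

.filter_components <- function(mask, min_component) {
  if (!any(mask) || min_component <= 1) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

.morph <- function(mask, open_radius, close_radius) {
  m <- mask * 1
  if (open_radius > 0) {
    m <- EBImage::opening(m, EBImage::makeBrush(2L * open_radius + 1L, "disc"))
  }
  if (close_radius > 0) {
    m <- EBImage::closing(m, EBImage::makeBrush(2L * close_radius + 1L, "disc"))
  }
  m > 0.5
}

.seg_result <- function(mask, calibration) {
  n <- sum(mask)
  structure(list(mask = mask, pixel_count = as.integer(n),
                 area_mm2 = n * calibration, calibration = calibration),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation: %d px  (%.2f mm2 at %.4g mm2/px)\n",
              x$pixel_count, x$area_mm2, x$calibration))
  invisible(x)
}

#' Segment the shoot from a side-view image
#'
#' Hue/saturation colour filtering isolates vegetation-coloured pixels,
#' optional morphological opening/closing removes speckle, and connected
#' components below `min_component` pixels are discarded. A simplified,
#' openly documented analogue of the commercial platform's shoot
#' segmentation.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param hue_range vegetation hue band (HSV hue in \[0,1\]; green by default).
#' @param min_saturation,min_value lower HSV saturation/value cut-offs.
#' @param open_radius,close_radius structuring-element radii in pixels for
#'   morphological opening/closing (0 = skip; component filtering then does
#'   the speckle removal).
#' @param min_component smallest connected component (pixels) retained.
#' @param calibration mm2 per pixel.
#' @return a `segmentation_result`: binary mask, pixel count, area in mm2.
#'   An image with no vegetation pixels yields an empty mask with a warning.
#' @export
segment_shoot <- function(image, hue_range = c(0.18, 0.45),
                          min_saturation = 0.20, min_value = 0.08,
                          open_radius = 0L, close_radius = 0L,
                          min_component = 9L, calibration = 1) {
  assert_that(length(dim(image)) == 3 && dim(image)[3] == 3,
              "image must be an H x W x 3 array")
  p <- .hsv_planes(image)
  mask <- p$h >= hue_range[1] & p$h <= hue_range[2] &
    p$s >= min_saturation & p$v >= min_value
  mask[is.na(mask)] <- FALSE
  mask <- .morph(mask, open_radius, close_radius)
  mask <- .filter_components(mask, min_component)
  if (!any(mask)) warning("no shoot pixels found; returning empty mask")
  .seg_result(mask, calibration)
}

#' Mean side-view projected area over six rotations
#'
#' The platform images each plant six times with a 27 degree axial rotation
#' between shots; the shoot biomass proxy is the plain arithmetic mean of
#' the six projected areas.
#'
#' @param areas numeric vector of exactly six non-negative areas (mm2).
#' @return mean area in mm2.
#' @export
mean_sideview_area <- function(areas) {
  assert_that(length(areas) == 6, "exactly six rotation areas are required")
  assert_that(all(is.finite(areas)) && all(areas >= 0),
              "areas must be finite and non-negative")
  mean(areas)
}

#' Segment peripheral roots from a pot-bottom image
#'
#' Detects the pot disc as region of interest (largest bright connected
#' component), divides the grey image by a Gaussian-blurred version of
#' itself to cancel multiplicative illumination gradients, thresholds the
#' resulting ratio to pick out the dark root strands, and applies optional
#' morphological closing plus component-size filtering. A simplified
#' analogue of the platform's FFT/bandpass root segmentation.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param roi_value_min brightness above which pixels can belong to the pot.
#' @param ratio_threshold ratio (pixel / local background) below which a
#'   ROI pixel is called root.
#' @param blur_sigma Gaussian sigma (pixels) of the background estimate;
#'   should exceed the root strand width.
#' @param close_radius morphological closing radius (0 = skip).
#' @param min_component smallest component retained (1 by default: root
#'   strands are one pixel wide and fragment under 4-connected labelling,
#'   so speckle control is left to the illumination-normalised threshold).
#' @param min_roi_px smallest acceptable ROI; below this the ROI is deemed
#'   not found and an error is raised.
#' @param calibration mm2 per pixel.
#' @return a `segmentation_result` for the root pixels.
#' @export
segment_roots <- function(image, roi_value_min = 0.25, ratio_threshold = 0.7,
                          blur_sigma = 6, close_radius = 0L,
                          min_component = 1L, min_roi_px = 100L,
                          calibration = 1) {
  assert_that(length(dim(image)) == 3 && dim(image)[3] == 3,
              "image must be an H x W x 3 array")
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3

  bright <- gray > roi_value_min
  if (!any(bright)) stop("ROI not found: no pot pixels", call. = FALSE)
  lab <- EBImage::bwlabel(bright * 1)
  sizes <- tabulate(lab[lab > 0])
  roi <- matrix(lab == which.max(sizes), nrow(gray), ncol(gray))
  if (sum(roi) < min_roi_px) stop("ROI not found: pot disc too small", call. = FALSE)
  # the pot interior includes dark root strands: fill holes in the disc
  roi <- EBImage::fillHull(roi * 1) > 0.5
  # erode the ROI rim so the background estimate is not contaminated by the
  # dark surround
  roi_core <- EBImage::erode(roi * 1, EBImage::makeBrush(9L, "disc")) > 0.5

  bg <- EBImage::gblur(gray, sigma = blur_sigma)
  ratio <- gray / pmax(bg, 1e-6)
  mask <- roi_core & ratio < ratio_threshold
  mask <- .morph(mask, 0L, close_radius)
  mask <- .filter_components(mask, min_component)
  .seg_result(mask, calibration)
}
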