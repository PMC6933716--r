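#' Segment a flatbed panicle scan from its black background
#'
#' Mature panicles are yellowish on a black scanner background, so an HSV
#' threshold of hue 0-0.3, saturation 0.2-1, value 0.5-1 (closed intervals)
#' isolates the panicle.
#'
#' @param image H x W x 3 RGB array in `[0, 255]`.
#' @param thr an [hsv_threshold()]; default as above.
#' @return H x W logical foreground mask. An empty foreground raises a
#'   warning (empty scan).
#' @export
segment_scan <- function(image,
                         thr = hsv_threshold(hue_range = c(0, 0.3),
                                             sat_range = c(0.2, 1),
                                             val_range = c(0.5, 1))) {
  mask <- segment_background(image, thr)
  if (!any(mask)) warning("empty scan: no foreground pixels after thresholding")
  mask
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a disk structuring element. Structures
#' thinner than twice the radius (the panicle branches) vanish, leaving the
#' thicker seed regions disconnected from one another. Radius 0 is the
#' identity.
#'
#' @param mask H x W logical mask.
#' @param radius disk radius in pixels.
#' @return the opened logical mask.
#' @export
open_mask <- function(mask, radius = 2) {
  stopifnot(is.logical(mask), is.matrix(mask))
  assert_that(length(radius) == 1 && radius >= 0 && radius == floor(radius),
              "panicler_validation_error", "radius must be a non-negative integer")
  if (radius == 0 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::opening(mask * 1, brush)
  matrix(as.numeric(EBImage::imageData(out)) > 0.5, nrow(mask), ncol(mask))
}

#' Detect individual seeds in an opened scan mask
#'
#' After opening has removed the branches, the remaining 8-connected
#' regions correspond to seeds, except residual thin fragments which are
#' dropped by a minor-axis ("too thin") and area floor. Seed length and
#' width are the major and minor axis lengths of the ellipse with the same
#' second central moments as the region; seed area is its pixel count.
#'
#' @param opened logical mask from [open_mask()].
#' @param min_width minimum minor-axis length in pixels (default 8).
#' @param min_area minimum region area in pixels (default 30).
#' @return `data.frame` with one row per seed: `seed`, `length`, `width`,
#'   `area`, `centroid_row`, `centroid_col`.
#' @export
detect_seeds <- function(opened, min_width = 8, min_area = 30) {
  regions <- label_regions(opened)
  keep <- regions$minor_axis >= min_width & regions$area >= min_area
  regions <- regions[keep, , drop = FALSE]
  out <- data.frame(seed = seq_len(nrow(regions)),
                    length = regions$major_axis,
                    width = regions$minor_axis,
                    area = regions$area,
                    centroid_row = regions$centroid_row,
                    centroid_col = regions$centroid_col)
  rownames(out) <- NULL
  out
}

#' Summary morphometry of one flatbed panicle scan
#'
#' Projected surface area is the foreground pixel count of the segmented
#' scan before opening (branch pixels belong to the panicle's projected
#' area); projected seed count and per-seed statistics come from
#' [detect_seeds()] after opening.
#'
#' @param image H x W x 3 RGB array, or a logical mask (already segmented).
#' @param opening_radius disk radius for [open_mask()].
#' @param min_width,min_area seed filters for [detect_seeds()].
#' @param thr segmentation threshold (ignored when `image` is a mask).
#' @return list with `projected_seed_count`, `projected_surface_area`,
#'   `mean_seed_area`, `mean_seed_length`, `mean_seed_width` (the means are
#'   `NA` and flagged via `means_defined = FALSE` when no seed is found),
#'   and the per-seed table `seeds`.
#' @export
scan_summary <- function(image, opening_radius = 2, min_width = 8,
                         min_area = 30,
                         thr = hsv_threshold(hue_range = c(0, 0.3),
                                             sat_range = c(0.2, 1),
                                             val_range = c(0.5, 1))) {
  mask <- if (is.logical(image)) image else segment_scan(image, thr)
  opened <- open_mask(mask, opening_radius)
  seeds <- detect_seeds(opened, min_width, min_area)
  n <- nrow(seeds)
  list(projected_seed_count = n,
       projected_surface_area = sum(mask),
       mean_seed_area = if (n > 0) mean(seeds$area) else NA_real_,
       mean_seed_length = if (n > 0) mean(seeds$length) else NA_real_,
       mean_seed_width = if (n > 0) mean(seeds$width) else NA_real_,
       means_defined = n > 0,
       seeds = seeds)
}
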