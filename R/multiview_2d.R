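#' Filter checkerboard distractor regions from a frame's region table
#'
#' The chamber checkerboards include green squares whose color matches the
#' panicle, so color segmentation alone leaves square regions in the mask.
#' Squares are compact and round: by default a region is excluded iff
#' (solidity > `solidity_max` AND eccentricity < `ecc_min`) OR area <
#' `min_area`. Panicle regions are elongated and/or ragged and survive.
#'
#' The combination rule between the solidity and eccentricity tests is
#' configurable: with `exclusion_mode = "or"` a region failing either shape
#' test is excluded, which is stricter and can delete compact panicle
#' fragments.
#'
#' @param regions region table from [label_regions()].
#' @param solidity_max regions more solid than this look like squares
#'   (default 0.7).
#' @param ecc_min regions rounder than this (eccentricity below) look like
#'   squares (default 0.95).
#' @param min_area minimum region area in pixels (default 1000); smaller
#'   regions are excluded regardless of shape.
#' @param exclusion_mode `"and"` (default) or `"or"`: how the solidity and
#'   eccentricity conditions combine for shape-based exclusion.
#' @return the surviving rows of `regions`, unchanged, with a logical
#'   `kept` attribute column added to the full table available via
#'   `attr(, "all")`.
#' @export
filter_panicle_regions <- function(regions, solidity_max = 0.7,
                                   ecc_min = 0.95, min_area = 1000,
                                   exclusion_mode = c("and", "or")) {
  exclusion_mode <- match.arg(exclusion_mode)
  if (nrow(regions) == 0) return(regions)
  square_like <- if (exclusion_mode == "and") {
    regions$solidity > solidity_max & regions$eccentricity < ecc_min
  } else {
    regions$solidity > solidity_max | regions$eccentricity < ecc_min
  }
  drop <- square_like | regions$area < min_area
  kept <- regions[!drop, , drop = FALSE]
  all_tab <- regions
  all_tab$kept <- !drop
  attr(kept, "all") <- all_tab
  kept
}

#' Total multi-view 2D pixel count of a panicle session
#'
#' The comparison method to the 3D voxel count: each of the session's
#' pre-processed multi-view masks is labeled, distractor regions are
#' filtered with [filter_panicle_regions()], and the surviving region areas
#' are summed; the session trait is the sum over all views (120 at the
#' default two-camera rig).
#'
#' @param masks list of logical foreground masks from
#'   [preprocess_session()].
#' @param manifest optional [session_manifest()]; when given, the mask
#'   count is validated against `n_cameras * images_per_camera`.
#' @param strict if `FALSE`, a mask/manifest count mismatch warns instead
#'   of erroring.
#' @param ... filter parameters passed to [filter_panicle_regions()].
#' @return list with `total` (pixel count) and `per_image` (`data.frame`
#'   of image index, region id, area, solidity, eccentricity, kept).
#' @export
total_pixel_count <- function(masks, manifest = NULL, strict = TRUE, ...) {
  if (!is.null(manifest)) {
    expected <- manifest$n_cameras * manifest$images_per_camera
    if (length(masks) != expected) {
      msg <- sprintf("session has %d masks but manifest expects %d",
                     length(masks), expected)
      if (strict) stop_panicler("panicler_validation_error", msg)
      warning(msg)
    }
  }
  per_image <- NULL
  total <- 0L
  for (i in seq_along(masks)) {
    regions <- label_regions(masks[[i]])
    kept <- filter_panicle_regions(regions, ...)
    total <- total + sum(kept$area)
    if (nrow(regions) > 0) {
      tab <- attr(kept, "all")
      tab <- cbind(image = i, tab)
      per_image <- rbind(per_image, tab)
    }
  }
  if (is.null(per_image))
    per_image <- data.frame(image = integer(), region = integer(),
                            area = integer(), solidity = numeric(),
                            eccentricity = numeric(), major_axis = numeric(),
                            minor_axis = numeric(), centroid_row = numeric(),
                            centroid_col = numeric(), kept = logical())
  list(total = total, per_image = per_image)
}
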