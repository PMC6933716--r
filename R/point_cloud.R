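#' Colored 3D point cloud
#'
#' Container for one imaging session's reconstructed geometry: point
#' coordinates (in arbitrary reconstruction units until aligned), 8-bit RGB
#' colors, and an optional per-point component label assigned by
#' [segment_components()].
#'
#' @param points numeric N x 3 matrix of coordinates.
#' @param colors numeric N x 3 matrix of RGB values in `[0, 255]`.
#' @param label optional character vector of length N with values among
#'   `"panicle"`, `"checkerboard"`, `"apparatus"`, `"unassigned"`.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(runif(30), 10), matrix(128, 10, 3))
#' n_points(pc)
#' @export
point_cloud <- function(points, colors, label = NULL) {
  points <- as.matrix(points)
  colors <- as.matrix(colors)
  if (length(points) == 0) points <- matrix(numeric(), 0, 3)
  if (length(colors) == 0) colors <- matrix(numeric(), 0, 3)
  assert_that(ncol(points) == 3, "panicler_validation_error",
              "points must have 3 columns, got %d", ncol(points))
  assert_that(ncol(colors) == 3, "panicler_validation_error",
              "colors must have 3 columns, got %d", ncol(colors))
  assert_that(nrow(points) == nrow(colors), "panicler_validation_error",
              "points (%d) and colors (%d) differ in length",
              nrow(points), nrow(colors))
  assert_that(all(is.finite(points)) || nrow(points) == 0,
              "panicler_validation_error", "non-finite coordinates")
  assert_that(nrow(colors) == 0 || (min(colors) >= 0 && max(colors) <= 255),
              "panicler_validation_error", "colors must lie in [0, 255]")
  if (!is.null(label)) {
    assert_that(length(label) == nrow(points), "panicler_validation_error",
                "label length %d != point count %d", length(label), nrow(points))
    bad <- setdiff(unique(label), point_labels())
    assert_that(length(bad) == 0, "panicler_validation_error",
                "unknown label(s): %s", paste(bad, collapse = ", "))
  }
  structure(
    list(points = unname(points), colors = unname(colors), label = label),
    class = "point_cloud"
  )
}

point_labels <- function() c("unassigned", "panicle", "checkerboard", "apparatus")

#' @rdname point_cloud
#' @param x a `point_cloud`.
#' @export
n_points <- function(x) nrow(x$points)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points", n_points(x)))
  if (!is.null(x$label)) {
    tab <- table(factor(x$label, levels = point_labels()))
    cat(" (", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Subset a point cloud by a logical or integer index
#' @param cloud a `point_cloud`.
#' @param idx logical or integer point index.
#' @return the subsetted `point_cloud`.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              cloud$colors[idx, , drop = FALSE],
              if (!is.null(cloud$label)) cloud$label[idx])
}
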