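#' Shared bounding cube for voxelization
#'
#' The same cube, fixed in the canonical chamber frame, encloses every
#' aligned cloud so that voxel counts are comparable across sessions and
#' weeks. Each edge is divided into `resolution` equal bins (default 1000,
#' i.e. a 1000 x 1000 x 1000 grid).
#'
#' @param min_corner numeric length-3: the cube's minimum corner.
#' @param edge positive edge length.
#' @param resolution bins per edge.
#' @return an object of class `bounding_cube`.
#' @export
bounding_cube <- function(min_corner, edge, resolution = 1000) {
  assert_that(length(min_corner) == 3 && all(is.finite(min_corner)),
              "panicler_validation_error", "min_corner must be a 3-vector")
  assert_that(length(edge) == 1 && is.finite(edge) && edge > 0,
              "panicler_validation_error", "edge must be positive")
  assert_that(is_count(resolution), "panicler_validation_error",
              "resolution must be a positive integer")
  structure(list(min_corner = as.numeric(min_corner), edge = edge,
                 resolution = as.integer(resolution)),
            class = "bounding_cube")
}

#' Default bounding cube of a chamber model
#'
#' Centered below the board aperture, leaving `cube_top` centimeters for
#' the hook between the cube's top face and the board.
#'
#' @param model a [chamber_model()].
#' @param resolution bins per edge.
#' @return a [bounding_cube()].
#' @export
chamber_cube <- function(model = chamber_model(), resolution = 1000) {
  e <- model$cube_edge
  bounding_cube(c(-e / 2, -e / 2, -model$cube_top - e), e, resolution)
}

#' Voxelize a panicle point cloud on a bounding cube
#'
#' Each point maps to the voxel `floor((p - min_corner) / voxel_edge)` with
#' half-open bins `[lo, hi)`; coordinates exactly on the cube's maximum
#' face are clamped into the last voxel so the bins are disjoint and cover
#' the cube. A voxel is filled iff at least one point maps to it; each
#' filled voxel carries the arithmetic mean RGB color of its member points.
#'
#' @param panicle a [point_cloud()] of panicle points in the cube's frame.
#' @param cube a [bounding_cube()]. Points outside it indicate failed
#'   alignment and raise an error.
#' @return an object of class `voxel_grid`: list with `cube`, `index`
#'   (M x 3 integer matrix of 0-based voxel indices `i`, `j`, `k`), and
#'   `color` (M x 3 mean RGB).
#' @export
voxelize <- function(panicle, cube) {
  stopifnot(inherits(panicle, "point_cloud"), inherits(cube, "bounding_cube"))
  res <- cube$resolution
  n <- n_points(panicle)
  if (n == 0) {
    return(structure(list(cube = cube,
                          index = matrix(integer(), 0, 3),
                          color = matrix(numeric(), 0, 3)),
                     class = "voxel_grid"))
  }
  rel <- sweep(panicle$points, 2, cube$min_corner) / (cube$edge / res)
  outside <- rel < 0 | rel > res
  if (any(outside)) {
    bad <- which(rowSums(outside) > 0)[1]
    stop_panicler("panicler_out_of_bounds_error",
                  paste0("point %d at (%s) lies outside the bounding cube ",
                         "(failed alignment?)"),
                  bad, paste(signif(panicle$points[bad, ], 6), collapse = ", "))
  }
  ijk <- pmin(floor(rel), res - 1)
  key <- ijk[, 1] + res * (ijk[, 2] + res * ijk[, 3])
  grp <- match(key, unique(key))
  counts <- tabulate(grp)
  color <- rowsum(panicle$colors, grp) / counts
  index <- ijk[!duplicated(key), , drop = FALSE]
  storage.mode(index) <- "integer"
  structure(list(cube = cube, index = unname(index), color = unname(color)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d filled voxels at resolution %d\n",
              nrow(x$index), x$cube$resolution))
  invisible(x)
}

#' Extract panicle traits from a voxel grid
#'
#' Voxel count is the number of filled voxels (a proxy for panicle volume);
#' the per-channel color sums add up the mean 8-bit intensities of the
#' filled voxels; their red-to-green ratio tracks the green-to-yellow color
#' shift of the maturing panicle.
#'
#' @param grid a `voxel_grid` from [voxelize()].
#' @return an object of class `panicle_traits`: list with `voxel_count`,
#'   `color_sum_r`, `color_sum_g`, `color_sum_b`, `rg_ratio`. With an empty
#'   grid (or a zero green sum) the ratio is undefined and an error of
#'   class `panicler_undefined_ratio_error` is raised unless
#'   `allow_undefined_ratio = TRUE`, in which case `rg_ratio` is `NA` and
#'   flagged.
#' @param allow_undefined_ratio return `NA` (flagged) instead of erroring
#'   when the green sum is zero.
#' @export
extract_traits <- function(grid, allow_undefined_ratio = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  vc <- nrow(grid$index)
  sums <- if (vc == 0) c(0, 0, 0) else colSums(grid$color)
  if (sums[2] <= 0) {
    if (!allow_undefined_ratio)
      stop_panicler("panicler_undefined_ratio_error",
                    "green color sum is zero; R:G ratio undefined")
    rg <- NA_real_
  } else {
    rg <- sums[1] / sums[2]
  }
  structure(list(voxel_count = vc,
                 color_sum_r = sums[1], color_sum_g = sums[2],
                 color_sum_b = sums[3], rg_ratio = rg),
            class = "panicle_traits")
}

#' @export
print.panicle_traits <- function(x, ...) {
  cat(sprintf(
    "panicle_traits: voxel_count %d, color sums (R %.1f, G %.1f, B %.1f), R:G %.4f\n",
    x$voxel_count, x$color_sum_r, x$color_sum_g, x$color_sum_b, x$rg_ratio))
  invisible(x)
}

#' Full 3D trait pipeline for one imaging session
#'
#' Composition of the per-session stages: segment the scene into
#' components, estimate the similarity transform from the constant
#' reference geometry, align the cloud into the canonical frame, keep only
#' panicle points, voxelize on the shared cube, and extract traits.
#'
#' @param cloud the session's [point_cloud()] (any frame).
#' @param model a [chamber_model()].
#' @param cube a [bounding_cube()]; defaults to [chamber_cube()] at the
#'   given `resolution`.
#' @param resolution grid resolution used when `cube` is `NULL`.
#' @param keep_intermediate if `TRUE`, the labeled cloud, transform and
#'   voxel grid are attached as attributes for audit.
#' @return a `panicle_traits` object.
#' @export
session_traits <- function(cloud, model = chamber_model(), cube = NULL,
                           resolution = 1000, keep_intermediate = FALSE) {
  if (is.null(cube)) cube <- chamber_cube(model, resolution)
  labeled <- segment_components(cloud, model)
  tf <- estimate_reference_transform(labeled, model)
  aligned <- apply_transform(labeled, tf)
  panicle <- subset_cloud(aligned, aligned$label == "panicle")
  grid <- voxelize(panicle, cube)
  traits <- extract_traits(grid, allow_undefined_ratio = TRUE)
  if (keep_intermediate) {
    attr(traits, "labeled") <- labeled
    attr(traits, "transform") <- tf
    attr(traits, "grid") <- grid
  }
  traits
}

#' Read / write a voxel grid as sparse CSV
#'
#' Columns `i`, `j`, `k` (0-based indices) and `r`, `g`, `b` (mean colors),
#' with the cube parameters stored in a `#`-prefixed header line.
#'
#' @param grid a `voxel_grid`.
#' @param path CSV path.
#' @return `write_voxel_grid`: `path` invisibly; `read_voxel_grid`: the
#'   `voxel_grid`.
#' @export
write_voxel_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cube %s edge %.10g resolution %d",
                     paste(grid$cube$min_corner, collapse = " "),
                     grid$cube$edge, grid$cube$resolution), con)
  df <- data.frame(i = grid$index[, 1], j = grid$index[, 2],
                   k = grid$index[, 3], r = grid$color[, 1],
                   g = grid$color[, 2], b = grid$color[, 3])
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  hdr <- readLines(path, n = 1)
  tok <- strsplit(sub("^# cube ", "", hdr), " ")[[1]]
  cube <- bounding_cube(as.numeric(tok[1:3]), as.numeric(tok[5]),
                        as.integer(tok[7]))
  df <- read.csv(path, comment.char = "#")
  structure(list(cube = cube,
                 index = as.matrix(df[, c("i", "j", "k")]),
                 color = as.matrix(df[, c("r", "g", "b")])),
            class = "voxel_grid")
}
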