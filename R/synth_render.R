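#' Render multi-view foreground masks of a synthetic scene
#'
#' Orthographic projections of the panicle points at `n_views` equally
#' spaced azimuths around the vertical axis (120 views at the default rig:
#' two cameras, one frame every six degrees). Each panicle point is
#' splatted as a small disk so the projected panicle forms a solid
#' connected silhouette. Optionally, checkerboard-square distractor
#' regions, as left behind by color segmentation of the green squares, are
#' drawn near the frame edges. The true panicle pixel count of every view
#' (before distractors) is recorded.
#'
#' @param scene a scene from [make_scene()] (cloud plus truth labels), or a
#'   [point_cloud()] with labels.
#' @param n_views number of azimuths.
#' @param image_size output frames are `image_size x image_size`.
#' @param pixels_per_unit projection scale (pixels per cloud unit).
#' @param splat_radius disk radius (pixels) splatted per projected point.
#' @param distractors number of checkerboard squares to draw per frame.
#' @param distractor_size square edge (pixels).
#' @param seed RNG seed for distractor placement.
#' @return list with `masks` (list of logical matrices), `images` (list of
#'   H x W x 3 arrays: panicle pixels in stage color, distractors green,
#'   background black), and `truth`: `pixel_count` per view (distractor
#'   free) and `distractor_pixels` per view.
#' @export
render_views <- function(scene, n_views = 120, image_size = 220,
                         pixels_per_unit = 8, splat_radius = 1,
                         distractors = 0, distractor_size = 24, seed = 1L) {
  if (inherits(scene, "point_cloud")) {
    cloud <- scene
    label <- cloud$label
  } else {
    cloud <- scene$cloud
    label <- scene$truth$label
  }
  assert_that(!is.null(label), "panicler_validation_error",
              "render_views needs labeled points")
  pan <- cloud$points[label == "panicle", , drop = FALSE]
  pan_col <- cloud$colors[label == "panicle", , drop = FALSE]

  H <- W <- as.integer(image_size)
  ctr_row <- H / 2; ctr_col <- W / 2
  # center projections on the panicle centroid
  if (nrow(pan) > 0) {
    cz <- mean(pan[, 3])
    cx <- mean(pan[, 1]); cy <- mean(pan[, 2])
  } else {
    cx <- cy <- cz <- 0
  }

  disk <- which(outer((-splat_radius:splat_radius)^2,
                      (-splat_radius:splat_radius)^2, "+") <=
                  splat_radius^2, arr.ind = TRUE) - (splat_radius + 1L)

  masks <- images <- vector("list", n_views)
  pix_truth <- dist_pixels <- integer(n_views)
  with_local_seed(seed, {
    for (v in seq_len(n_views)) {
      theta <- 2 * pi * (v - 1) / n_views
      mask <- matrix(FALSE, H, W)
      img <- array(0, c(H, W, 3))
      if (nrow(pan) > 0) {
        u <- -(pan[, 1] - cx) * sin(theta) + (pan[, 2] - cy) * cos(theta)
        w <- pan[, 3] - cz
        col0 <- round(ctr_col + u * pixels_per_unit)
        row0 <- round(ctr_row - w * pixels_per_unit)
        for (d in seq_len(nrow(disk))) {
          rr <- row0 + disk[d, 1]; cc <- col0 + disk[d, 2]
          ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
          idx <- rr[ok] + (cc[ok] - 1L) * H
          mask[idx] <- TRUE
          img[idx] <- pan_col[ok, 1]
          img[idx + H * W] <- pan_col[ok, 2]
          img[idx + 2 * H * W] <- pan_col[ok, 3]
        }
      }
      pix_truth[v] <- sum(mask)
      if (distractors > 0) {
        green <- checker_palette()[2, ]
        for (q in seq_len(distractors)) {
          side <- sample.int(2L, 1L)
          r0 <- sample.int(H - distractor_size, 1L)
          c0 <- if (side == 1) sample.int(max(1L, round(W * 0.12)), 1L) else
            W - distractor_size - sample.int(max(1L, round(W * 0.12)), 1L)
          rows <- r0:(r0 + distractor_size - 1L)
          cols <- c0:(c0 + distractor_size - 1L)
          mask[rows, cols] <- TRUE
          for (ch in 1:3) img[rows, cols, ch] <- green[ch]
        }
        dist_pixels[v] <- sum(mask) - pix_truth[v]
      }
      masks[[v]] <- mask
      images[[v]] <- img
    }
  })
  list(masks = masks, images = images,
       truth = list(pixel_count = pix_truth, distractor_pixels = dist_pixels))
}
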