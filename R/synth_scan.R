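# Rasterize a filled rotated ellipse into a logical canvas (in place).
draw_ellipse <- function(mask, center, semiaxes, angle) {
  H <- nrow(mask); W <- ncol(mask)
  rad <- max(semiaxes)
  rr <- max(1L, floor(center[1] - rad)):min(H, ceiling(center[1] + rad))
  cc <- max(1L, floor(center[2] - rad)):min(W, ceiling(center[2] + rad))
  dr <- rep(rr - center[1], times = length(cc))
  dc <- rep(cc - center[2], each = length(rr))
  a1 <- (dr * cos(angle) + dc * sin(angle)) / semiaxes[1]
  a2 <- (-dr * sin(angle) + dc * cos(angle)) / semiaxes[2]
  sel <- a1^2 + a2^2 <= 1
  idx <- rep(rr, times = length(cc)) + (rep(cc, each = length(rr)) - 1L) * H
  mask[idx[sel]] <- TRUE
  mask
}

# Rasterize a thick line segment (width w pixels) between two points.
draw_segment <- function(mask, p1, p2, width) {
  H <- nrow(mask); W <- ncol(mask)
  hw <- width / 2
  r0 <- max(1L, floor(min(p1[1], p2[1]) - hw))
  r1 <- min(H, ceiling(max(p1[1], p2[1]) + hw))
  c0 <- max(1L, floor(min(p1[2], p2[2]) - hw))
  c1 <- min(W, ceiling(max(p1[2], p2[2]) + hw))
  rr <- r0:r1; cc <- c0:c1
  pr <- rep(rr, times = length(cc))
  pc <- rep(cc, each = length(rr))
  v <- p2 - p1
  len2 <- sum(v^2)
  tt <- if (len2 == 0) rep(0, length(pr)) else
    pmin(1, pmax(0, ((pr - p1[1]) * v[1] + (pc - p1[2]) * v[2]) / len2))
  d2 <- (pr - (p1[1] + tt * v[1]))^2 + (pc - (p1[2] + tt * v[2]))^2
  sel <- d2 <= hw^2
  mask[pr[sel] + (pc[sel] - 1L) * H] <- TRUE
  mask
}

#' Generate a mock flatbed scan of a spread panicle
#'
#' Places `n_seeds` non-overlapping yellow ovals on a jittered grid over a
#' black background (emulating branches spread out to avoid overlaps on the
#' scanner glass) and joins consecutive grid neighbors with thin branch
#' segments of `connector_width` pixels. Ground truth records the seed
#' count, per-seed axes and centers, and the total foreground pixel count.
#'
#' @param n_seeds number of seeds.
#' @param axes numeric length-2 full axis lengths in pixels (major, minor).
#' @param connector_width branch segment width in pixels.
#' @param seed RNG seed.
#' @param jitter maximum center jitter (pixels) within a grid cell.
#' @param stage maturation stage of the seed color (default mature yellow).
#' @return list with `image` (H x W x 3 array), `mask` (logical truth
#'   foreground), and `truth`: `n_seeds`, `axes`, `centers`, `angles`,
#'   `foreground_pixels`.
#' @export
make_scan <- function(n_seeds = 30, axes = c(40, 20), connector_width = 3,
                      seed = 1L, jitter = 5, stage = 1) {
  assert_that(n_seeds >= 0, "panicler_validation_error",
              "n_seeds must be non-negative")
  assert_that(length(axes) == 2 && all(axes > 0) && axes[1] >= axes[2],
              "panicler_validation_error",
              "axes must be c(major, minor) full lengths in pixels")
  with_local_seed(seed, {
    # grid spacing leaves clearance: cells 2.2x the major axis apart
    spacing <- ceiling(axes[1] * 2.2)
    assert_that(spacing - 2 * jitter >= 1.2 * axes[1],
                "panicler_capacity_error",
                "cannot place seeds without overlap at this jitter/axes")
    ncol_g <- ceiling(sqrt(max(1, n_seeds)))
    nrow_g <- ceiling(max(1, n_seeds) / ncol_g)
    margin <- axes[1]
    H <- as.integer(nrow_g * spacing + 2 * margin)
    W <- as.integer(ncol_g * spacing + 2 * margin)
    mask <- matrix(FALSE, H, W)
    centers <- matrix(numeric(), 0, 2)
    angles <- numeric(0)
    if (n_seeds > 0) {
      cells <- seq_len(nrow_g * ncol_g)[seq_len(n_seeds)]
      gr <- (cells - 1L) %/% ncol_g
      gc <- (cells - 1L) %% ncol_g
      centers <- cbind(margin + spacing * (gr + 0.5) +
                         runif(n_seeds, -jitter, jitter),
                       margin + spacing * (gc + 0.5) +
                         runif(n_seeds, -jitter, jitter))
      angles <- runif(n_seeds, 0, pi)
      semi <- axes / 2
      for (s in seq_len(n_seeds))
        mask <- draw_ellipse(mask, centers[s, ], semi, angles[s])
      if (n_seeds > 1 && connector_width > 0) {
        for (s in seq_len(n_seeds - 1L))
          mask <- draw_segment(mask, centers[s, ], centers[s + 1L, ],
                               connector_width)
      }
    }
    col <- stage_color(stage)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(0, H, W)
      plane[mask] <- col[ch]
      img[, , ch] <- plane
    }
    list(image = img, mask = mask,
         truth = list(n_seeds = n_seeds, axes = axes, centers = centers,
                      angles = angles, foreground_pixels = sum(mask)))
  })
}
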