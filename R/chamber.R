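#' Chamber reference-geometry model
#'
#' Canonical description of the constant imaging-chamber geometry used to
#' scale and align reconstructed clouds: the checkerboard-covered board
#' surface and walls, the board aperture through which the panicle hangs,
#' and the gray metal hook at the top of the scene.
#'
#' Canonical frame: the board surface is the plane `z = 0` with the
#' aperture center at the origin; the chamber interior (walls, hook,
#' panicle) lies below, at negative `z`. Three checkerboard walls are
#' modeled (the fourth side is the camera opening): a back wall at
#' `x = -board_x/2` and side walls at `y = +/- board_y/2`, all descending
#' to `z = -wall_depth`. The three wall/board rectangles have pairwise
#' distinct aspect ratios, which is what lets detected planes be identified
#' without markers.
#'
#' All lengths are in centimeters; the checkerboard square edge (1 cm)
#' gives the absolute scale of one canonical unit.
#'
#' @param board_x,board_y board extents (cm).
#' @param wall_depth wall height below the board (cm).
#' @param cube_edge edge length of the shared bounding cube (cm).
#' @param cube_top gap between board and cube top face (cm); the hook
#'   occupies this band.
#' @param aperture_radius board aperture radius (cm).
#' @param checker_edge checkerboard square edge (cm).
#' @param hook_top_frac hook search band as a fraction of scene height.
#' @param gray_tol max RGB channel spread (8-bit) for "gray" hook points.
#' @return an object of class `chamber_model`.
#' @export
chamber_model <- function(board_x = 40, board_y = 30, wall_depth = 60,
                          cube_edge = 24, cube_top = 2,
                          aperture_radius = 3, checker_edge = 1,
                          hook_top_frac = 0.1, gray_tol = 30) {
  assert_that(board_x > 0 && board_y > 0 && wall_depth > 0 && cube_edge > 0 &&
                checker_edge > 0, "panicler_validation_error",
              "chamber dimensions must be positive")
  ratios <- sort(c(board_x / board_y, wall_depth / board_y,
                   wall_depth / board_x))
  assert_that(min(ratios[-1] / ratios[-3]) > 1.1, "panicler_validation_error",
              "wall/board aspect ratios must be distinct for identification")
  structure(list(board_x = board_x, board_y = board_y,
                 wall_depth = wall_depth, cube_edge = cube_edge,
                 cube_top = cube_top, aperture_radius = aperture_radius,
                 checker_edge = checker_edge, hook_top_frac = hook_top_frac,
                 gray_tol = gray_tol),
            class = "chamber_model")
}

# Total least-squares plane through points: list(normal, offset, centroid)
# with distance(p) = p . normal - offset. Refined by MAD outlier rejection.
fit_plane <- function(pts, refine = TRUE) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0)
  normal <- sv$v[, 3]
  if (refine) {
    # iterate MAD outlier rejection to convergence: points dragged in from
    # adjacent walls near chamber edges need more than one pass
    keep <- rep(TRUE, nrow(pts))
    for (pass in 1:5) {
      d <- as.numeric(sweep(pts, 2, ctr) %*% normal)
      s <- stats::mad(d[keep])
      new_keep <- abs(d - stats::median(d[keep])) <= max(3 * s, 1e-12)
      if (sum(new_keep) < 3 || identical(new_keep, keep)) break
      keep <- new_keep
      ctr <- colMeans(pts[keep, , drop = FALSE])
      sv <- svd(sweep(pts[keep, , drop = FALSE], 2, ctr), nu = 0)
      normal <- sv$v[, 3]
    }
  }
  list(normal = normal, offset = sum(normal * ctr), centroid = ctr)
}

plane_distance <- function(pts, plane) {
  abs(as.numeric(pts %*% plane$normal) - plane$offset)
}

# Deterministic sequential RANSAC: extract up to n_planes dominant planes.
extract_planes <- function(points, n_planes, tol, min_inliers,
                           iters = 600) {
  with_local_seed(608131, {
    remaining <- seq_len(nrow(points))
    planes <- list()
    for (k in seq_len(n_planes)) {
      pts <- points[remaining, , drop = FALSE]
      if (nrow(pts) < max(min_inliers, 3)) break
      best_n <- 0L
      best_inl <- NULL
      for (it in seq_len(iters)) {
        tri <- pts[sample.int(nrow(pts), 3L), ]
        nrm <- pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
        len <- sqrt(sum(nrm^2))
        if (len < 1e-12) next
        nrm <- nrm / len
        d <- abs(as.numeric(pts %*% nrm) - sum(nrm * tri[1, ]))
        inl <- d <= tol
        ni <- sum(inl)
        if (ni > best_n) {
          best_n <- ni
          best_inl <- inl
        }
      }
      if (best_n < min_inliers) break
      # refine on consensus set, then re-select inliers once
      pl <- fit_plane(pts[best_inl, , drop = FALSE])
      inl <- plane_distance(pts, pl) <= tol
      if (sum(inl) < min_inliers) break
      pl <- fit_plane(pts[inl, , drop = FALSE])
      inl <- plane_distance(pts, pl) <= tol
      pl$point_idx <- remaining[inl]
      planes[[length(planes) + 1L]] <- pl
      remaining <- remaining[!inl]
    }
    planes
  })
}

# In-plane extent (sorted ranges along the two principal in-plane axes).
plane_extents <- function(pts, plane) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0)
  spans <- apply(sweep(pts, 2, ctr) %*% sv$v[, 1:2], 2,
                 function(u) diff(range(u)))
  sort(spans, decreasing = TRUE)
}

# Detect the four chamber planes (board, back wall, two side walls) in a
# cloud of arbitrary scale/orientation and recover the canonical frame.
# Returns basis vectors (data-frame directions of canonical +x, +y, +z),
# the data-frame point at the canonical origin, the data-units-per-cm
# scale, plane objects, and indices of all reference (plane inlier) points.
detect_chamber_frame <- function(points, model, rel_tol = 0.004) {
  assert_that(nrow(points) >= 12, "panicler_alignment_error",
              "too few points to recover chamber geometry")
  diag_extent <- sqrt(sum(apply(points, 2, function(u) diff(range(u)))^2))
  tol <- rel_tol * diag_extent
  # decimate on a coarse voxel grid so that a densely sampled panicle
  # cannot out-vote the 2D wall surfaces during plane extraction
  pitch <- diag_extent / 150
  cell <- floor(sweep(points, 2, apply(points, 2, min)) / pitch)
  dec_idx <- which(!duplicated(cell[, 1] + 4096 * (cell[, 2] + 4096 * cell[, 3])))
  dec <- points[dec_idx, , drop = FALSE]
  min_inliers <- max(50, round(0.02 * nrow(dec)))
  # extract more candidates than needed: stray near-planar subsets of a
  # dense panicle may slip in and are weeded out by the consistency search
  cand <- extract_planes(dec, 6L, tol, min_inliers)
  assert_that(length(cand) >= 4, "panicler_alignment_error",
              "found %d reference plane(s), need 4: cannot align",
              length(cand))

  # select a consistent chamber set: a parallel wall pair plus two planes
  # orthogonal to the pair and to each other. Preference uses DECIMATED
  # inlier counts: on the full cloud a near-planar slab through a densely
  # sampled panicle can carry more raw points than a wall surface.
  n_inl <- vapply(cand, function(p) length(p$point_idx), numeric(1))
  normals <- t(vapply(cand, `[[`, numeric(3), "normal"))
  dots <- abs(tcrossprod(normals))
  diag(dots) <- 0
  pairs <- which(dots > 0.98, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  assert_that(nrow(pairs) >= 1, "panicler_alignment_error",
              "no parallel side-wall pair among detected planes")
  pairs <- pairs[order(-(n_inl[pairs[, 1]] + n_inl[pairs[, 2]])), ,
                 drop = FALSE]
  side_idx <- other_idx <- NULL
  for (pr in seq_len(nrow(pairs))) {
    sides <- as.integer(pairs[pr, ])
    ortho <- setdiff(which(dots[, sides[1]] < 0.2 & dots[, sides[2]] < 0.2),
                     sides)
    ortho <- ortho[order(-n_inl[ortho])]
    found <- NULL
    for (a in seq_along(ortho)) {
      for (b in seq_along(ortho)) {
        if (a < b && dots[ortho[a], ortho[b]] < 0.2) {
          found <- c(ortho[a], ortho[b])
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      side_idx <- sides
      other_idx <- found
      break
    }
  }
  assert_that(!is.null(side_idx), "panicler_alignment_error",
              "detected planes are not mutually orthogonal")
  # refit the four selected planes on their full-cloud inlier sets
  planes <- cand
  for (i in c(side_idx, other_idx)) {
    pl <- planes[[i]]
    inl <- which(plane_distance(points, pl) <= tol)
    pl2 <- fit_plane(points[inl, , drop = FALSE])
    inl <- which(plane_distance(points, pl2) <= tol)
    pl2 <- fit_plane(points[inl, , drop = FALSE])
    pl2$point_idx <- inl
    planes[[i]] <- pl2
  }
  # the separation of the parallel pair must match the extent of the two
  # orthogonal planes along the pair normal (both equal the board width)
  sep <- abs(sum(planes[[side_idx[1]]]$normal * planes[[side_idx[1]]]$centroid) -
               sum(planes[[side_idx[1]]]$normal * planes[[side_idx[2]]]$centroid))
  ey0 <- planes[[side_idx[1]]]$normal
  ext_y <- diff(range(points[planes[[other_idx[1]]]$point_idx, ] %*% ey0))
  assert_that(abs(log(max(sep, 1e-12) / max(ext_y, 1e-12))) < 0.25,
              "panicler_alignment_error",
              "side-wall separation inconsistent with board extent")

  # board vs back wall by in-plane aspect ratio (distinct by construction)
  ratio_of <- function(i) {
    ext <- plane_extents(points[planes[[i]]$point_idx, , drop = FALSE],
                         planes[[i]])
    ext[1] / ext[2]
  }
  r1 <- ratio_of(other_idx[1]); r2 <- ratio_of(other_idx[2])
  board_ratio <- max(model$board_x, model$board_y) /
    min(model$board_x, model$board_y)
  back_ratio <- model$wall_depth / min(model$board_x, model$board_y)
  cost12 <- abs(log(r1 / board_ratio)) + abs(log(r2 / back_ratio))
  cost21 <- abs(log(r2 / board_ratio)) + abs(log(r1 / back_ratio))
  if (cost12 <= cost21) {
    board_i <- other_idx[1]; back_i <- other_idx[2]
  } else {
    board_i <- other_idx[2]; back_i <- other_idx[1]
  }
  board <- planes[[board_i]]; back <- planes[[back_i]]
  side_a <- planes[[side_idx[1]]]; side_b <- planes[[side_idx[2]]]

  # interior reference: centroid of side-wall points (always inside chamber)
  interior <- colMeans(points[c(side_a$point_idx, side_b$point_idx), ,
                              drop = FALSE])
  # canonical +z: away from interior (interior sits below the board)
  ez <- board$normal
  if (sum(ez * interior) - board$offset > 0) ez <- -ez
  # canonical +x: from the back wall toward the interior
  ex <- back$normal
  if (sum(ex * interior) - back$offset < 0) ex <- -ex
  ex <- ex - sum(ex * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- pracma::cross(ez, ex)

  scale_data <- abs(sum(ey * side_a$centroid) - sum(ey * side_b$centroid)) /
    model$board_y
  assert_that(scale_data > 0, "panicler_alignment_error",
              "side walls coincide; cannot recover scale")

  # data-frame point at the canonical origin (aperture center)
  a_x <- sum(ex * back$centroid) + scale_data * model$board_x / 2
  a_y <- (sum(ey * side_a$centroid) + sum(ey * side_b$centroid)) / 2
  a_z <- sum(ez * board$centroid)
  origin <- a_x * ex + a_y * ey + a_z * ez

  ref_idx <- sort(unlist(lapply(planes[c(side_idx, other_idx)], `[[`,
                                "point_idx")))
  list(ex = ex, ey = ey, ez = ez, origin = origin, scale = scale_data,
       planes = list(board = board, back = back,
                     side_neg = if (sum(ey * side_a$centroid) <
                                      sum(ey * side_b$centroid)) side_a else side_b,
                     side_pos = if (sum(ey * side_a$centroid) <
                                      sum(ey * side_b$centroid)) side_b else side_a),
       ref_idx = ref_idx, tol = tol)
}

#' Segment a reconstructed scene into panicle, checkerboard and apparatus
#'
#' Components are told apart by their distinct positions and colors:
#' points lying on the constant wall/board planes are checkerboard, gray
#' points (RGB channel spread at most `model$gray_tol`) in the top band of
#' the scene are the metal hook/apparatus, and everything else is panicle.
#' Plane positions are recovered from the cloud itself, so the cloud may be
#' in any reconstruction frame.
#'
#' @param cloud a [point_cloud()].
#' @param model a [chamber_model()].
#' @param wall_distance_tol distance to a wall plane (cm, canonical scale)
#'   within which a point is labeled checkerboard.
#' @return the cloud with `label` filled in; the detected chamber frame is
#'   attached as attribute `"frame"`.
#' @export
segment_components <- function(cloud, model = chamber_model(),
                               wall_distance_tol = 1) {
  assert_that(n_points(cloud) > 0, "panicler_validation_error",
              "cannot segment an empty cloud")
  frame <- detect_chamber_frame(cloud$points, model)
  tol_data <- wall_distance_tol * frame$scale
  d <- do.call(pmin, lapply(frame$planes, function(pl)
    plane_distance(cloud$points, pl)))
  label <- rep("panicle", n_points(cloud))
  label[d <= tol_data] <- "checkerboard"

  rest <- which(label == "panicle")
  if (length(rest) > 0) {
    z_all <- as.numeric(cloud$points %*% frame$ez)
    zr <- range(z_all)
    z <- z_all[rest]
    top <- z >= zr[2] - model$hook_top_frac * max(zr[2] - zr[1], 1e-12)
    spread <- apply(cloud$colors[rest, , drop = FALSE], 1, function(cc)
      max(cc) - min(cc))
    label[rest[top & spread <= model$gray_tol]] <- "apparatus"
  }
  out <- point_cloud(cloud$points, cloud$colors, label)
  attr(out, "frame") <- frame
  out
}

#' Estimate the similarity transform into the canonical chamber frame
#'
#' Fits the wall/board planes to the checkerboard-labeled points, derives
#' landmark points from their intersections (the two lower back corners,
#' their counterparts at the wall top, and the board aperture center), and
#' returns the least-squares similarity transform mapping the detected
#' landmarks onto their known canonical-frame positions. The landmark-fit
#' residual RMS (canonical units) is attached as attribute `"rms"`.
#'
#' @param cloud a labeled [point_cloud()] from [segment_components()] (an
#'   unlabeled cloud is segmented first).
#' @param model a [chamber_model()].
#' @return a [similarity_transform()] taking the cloud into the canonical
#'   frame.
#' @export
estimate_reference_transform <- function(cloud, model = chamber_model()) {
  if (is.null(cloud$label)) cloud <- segment_components(cloud, model)
  frame <- attr(cloud, "frame")
  if (is.null(frame)) {
    ref <- cloud$points[cloud$label == "checkerboard", , drop = FALSE]
    assert_that(nrow(ref) >= 12, "panicler_alignment_error",
                "no checkerboard points: cannot align")
    frame <- detect_chamber_frame(ref, model)
  }
  pl <- frame$planes
  # three-plane intersection: solve [n1; n2; n3] x = (o1, o2, o3)
  intersect3 <- function(p1, p2, p3) {
    A <- rbind(p1$normal, p2$normal, p3$normal)
    assert_that(abs(det(A)) > 1e-6, "panicler_rank_error",
                "degenerate plane configuration")
    as.numeric(solve(A, c(p1$offset, p2$offset, p3$offset)))
  }
  A <- intersect3(pl$back, pl$side_neg, pl$board)
  B <- intersect3(pl$back, pl$side_pos, pl$board)
  sH <- frame$scale * model$wall_depth
  landmarks <- rbind(A, B,
                     A - sH * frame$ez,
                     B - sH * frame$ez,
                     frame$origin)
  canonical <- rbind(
    c(-model$board_x / 2, -model$board_y / 2, 0),
    c(-model$board_x / 2, model$board_y / 2, 0),
    c(-model$board_x / 2, -model$board_y / 2, -model$wall_depth),
    c(-model$board_x / 2, model$board_y / 2, -model$wall_depth),
    c(0, 0, 0))
  fit_similarity(landmarks, canonical)
}
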