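random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

test_that("similarity transforms apply, invert and compose correctly", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)), matrix(100, 2, 3))
  expect_equal(apply_transform(cl, similarity_transform())$points, cl$points)
  scaled <- apply_transform(cl, similarity_transform(scale = 2))
  expect_equal(sqrt(sum((scaled$points[2, ] - scaled$points[1, ])^2)), 2)
  set.seed(21)
  for (i in 1:5) {
    tf <- similarity_transform(runif(1, 0.5, 3), random_rotation(),
                               rnorm(3, 0, 5))
    pts <- matrix(rnorm(30), ncol = 3)
    back <- apply_transform(apply_transform(pts, tf), invert_transform(tf))
    expect_lt(max(abs(back - pts)), 1e-9)
    comp <- compose_transform(invert_transform(tf), tf)
    expect_lt(max(abs(comp$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(comp$translation)), 1e-9)
  }
})

test_that("scene segmentation recovers generated component labels", {
  scene <- make_scene(synthetic_panicle_spec(seed = 3), week = 2)
  seg <- segment_components(scene$cloud)
  expect_gte(mean(seg$label == scene$truth$label), 0.99)
})

test_that("walls-only scenes segment without error; no walls cannot align", {
  scene <- make_scene(synthetic_panicle_spec(n_branches = 0, seed = 2))
  seg <- segment_components(scene$cloud)
  expect_equal(sum(seg$label == "panicle"), 0)
  blob <- point_cloud(matrix(rnorm(3000), ncol = 3),
                      matrix(120, 1000, 3))
  expect_error(segment_components(blob),
               class = "panicler_alignment_error")
})

test_that("a canonical-frame scene yields the identity transform", {
  scene <- make_scene(synthetic_panicle_spec(seed = 5), week = 1)
  tf <- estimate_reference_transform(segment_components(scene$cloud))
  expect_lt(abs(tf$scale - 1), 1e-9)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)
  expect_lt(attr(tf, "rms"), 1e-9)
})

test_that("known similarity transforms are recovered to 1e-6", {
  set.seed(31)
  spec <- synthetic_panicle_spec(seed = 8)
  for (i in 1:3) {
    truth_tf <- similarity_transform(runif(1, 0.4, 2.5), random_rotation(),
                                     rnorm(3, 0, 10))
    scene <- make_scene(spec, week = 2, transform = truth_tf)
    est <- estimate_reference_transform(segment_components(scene$cloud))
    comp <- compose_transform(est, truth_tf)
    expect_lt(abs(comp$scale - 1), 1e-6)
    expect_lt(max(abs(comp$rotation - diag(3))), 1e-6)
    expect_lt(max(abs(comp$translation)), 1e-6)
  }
})

test_that("degenerate landmark configurations raise a rank error", {
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(panicler:::fit_similarity(line, line),
               class = "panicler_rank_error")
})

test_that("voxelization matches a brute-force binning oracle", {
  # independent oracle: per-point loop over an explicit dense array
  oracle_voxelize <- function(pts, cube) {
    res <- cube$resolution
    edge <- cube$edge / res
    filled <- array(FALSE, c(res, res, res))
    for (i in seq_len(nrow(pts))) {
      ijk <- floor((pts[i, ] - cube$min_corner) / edge)
      ijk <- pmin(pmax(ijk, 0), res - 1)
      filled[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] <- TRUE
    }
    which(filled, arr.ind = TRUE) - 1L
  }
  set.seed(17)
  for (rep_i in 1:10) {
    res <- sample(2:50, 1)
    n <- sample(c(10, 500, 2000), 1)
    cube <- bounding_cube(rnorm(3), runif(1, 1, 10), res)
    pts <- sweep(matrix(runif(3 * n), ncol = 3) * cube$edge, 2,
                 cube$min_corner, "+")
    grid <- voxelize(point_cloud(pts, matrix(128, n, 3)), cube)
    got <- grid$index[order(grid$index[, 1], grid$index[, 2],
                            grid$index[, 3]), , drop = FALSE]
    exp_idx <- oracle_voxelize(pts, cube)
    exp_idx <- exp_idx[order(exp_idx[, 1], exp_idx[, 2], exp_idx[, 3]), ,
                       drop = FALSE]
    expect_equal(unname(got), unname(exp_idx))
  }
})

test_that("voxelization handles single points, boundaries, and errors", {
  cube <- bounding_cube(c(0, 0, 0), 10, 5)
  g <- voxelize(point_cloud(matrix(c(3.2, 7.7, 0.1), 1), matrix(c(10, 20, 30), 1)),
                cube)
  expect_equal(nrow(g$index), 1)
  expect_equal(g$color[1, ], c(10, 20, 30))
  # a coordinate exactly on the max face falls into the last voxel
  g2 <- voxelize(point_cloud(matrix(c(10, 10, 10), 1), matrix(0, 1, 3)), cube)
  expect_equal(g2$index[1, ], rep(4L, 3))
  expect_error(voxelize(point_cloud(matrix(c(11, 0, 0), 1), matrix(0, 1, 3)),
                        cube),
               class = "panicler_out_of_bounds_error")
  expect_equal(bounding_cube(c(0, 0, 0), 1)$resolution, 1000)
})

test_that("per-voxel colors are arithmetic means of member points", {
  cube <- bounding_cube(c(0, 0, 0), 10, 2)
  pts <- rbind(c(1, 1, 1), c(2, 2, 2), c(8, 8, 8))
  cols <- rbind(c(100, 0, 0), c(200, 0, 0), c(40, 50, 60))
  g <- voxelize(point_cloud(pts, cols), cube)
  expect_equal(nrow(g$index), 2)
  first <- which(g$index[, 1] == 0)
  expect_equal(g$color[first, ], c(150, 0, 0))
})

test_that("voxel count is monotone under point addition", {
  set.seed(23)
  cube <- bounding_cube(c(0, 0, 0), 1, 20)
  pts <- matrix(runif(3 * 3000), ncol = 3)
  counts <- vapply(c(100, 500, 1500, 3000), function(n) {
    nrow(voxelize(point_cloud(pts[1:n, ], matrix(1, n, 3)), cube)$index)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_lte(counts[4], min(3000, 20^3))
})

test_that("trait extraction computes counts, sums and the R:G ratio", {
  g <- structure(list(cube = bounding_cube(c(0, 0, 0), 1, 10),
                      index = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(2L, 0L, 0L)),
                      color = matrix(rep(c(200, 100, 50), each = 3), ncol = 3)),
                 class = "voxel_grid")
  tr <- extract_traits(g)
  expect_equal(tr$voxel_count, 3)
  expect_equal(c(tr$color_sum_r, tr$color_sum_g, tr$color_sum_b),
               c(600, 300, 150))
  expect_equal(tr$rg_ratio, 2)
  empty <- voxelize(point_cloud(matrix(numeric(), 0, 3),
                                matrix(numeric(), 0, 3)),
                    bounding_cube(c(0, 0, 0), 1, 10))
  expect_error(extract_traits(empty),
               class = "panicler_undefined_ratio_error")
  flagged <- extract_traits(empty, allow_undefined_ratio = TRUE)
  expect_equal(flagged$voxel_count, 0)
  expect_true(is.na(flagged$rg_ratio))
})

test_that("voxel grids round trip through sparse CSV", {
  scene <- make_scene(synthetic_panicle_spec(seed = 12))
  tr <- session_traits(scene$cloud, resolution = 100, keep_intermediate = TRUE)
  grid <- attr(tr, "grid")
  path <- withr::local_tempfile(fileext = ".csv")
  write_voxel_grid(grid, path)
  back <- read_voxel_grid(path)
  expect_equal(unname(back$index), unname(grid$index))
  expect_equal(unname(back$color), unname(grid$color), tolerance = 1e-9)
  expect_equal(back$cube$resolution, 100)
})

test_that("weekly growth and maturation translate into the traits", {
  spec <- synthetic_panicle_spec(seed = 6)
  stages <- c(0.15, 0.5, 0.85)
  traits <- lapply(1:3, function(w) {
    scene <- make_scene(spec, week = w, color_stage = stages[w])
    session_traits(scene$cloud, resolution = 150)
  })
  vc <- vapply(traits, `[[`, numeric(1), "voxel_count")
  rg <- vapply(traits, `[[`, numeric(1), "rg_ratio")
  expect_true(all(diff(vc) > 0))
  expect_true(all(diff(rg) > 0))
})
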