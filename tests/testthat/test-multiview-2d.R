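draw_blob <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

test_that("region properties match closed-form shapes", {
  # filled square: convex and isotropic
  sq <- label_regions(draw_blob(40, 40, 11:30, 11:30))
  expect_equal(nrow(sq), 1)
  expect_equal(sq$area, 400)
  expect_equal(sq$solidity, 1.0)
  expect_equal(sq$eccentricity, 0.0)

  # filled ellipse with semi-axes 25:15 -> e = sqrt(1 - 9/25) = 0.8
  m <- matrix(FALSE, 80, 80)
  rr <- rep(1:80, 80); cc <- rep(1:80, each = 80)
  m[((rr - 40) / 25)^2 + ((cc - 40) / 15)^2 <= 1] <- TRUE
  el <- label_regions(m)
  expect_equal(el$eccentricity, 0.8, tolerance = 0.02)
  expect_equal(el$major_axis, 50, tolerance = 0.06 * 50)
  expect_gte(el$solidity, 0.95)

  # two disjoint blobs with known pixel counts
  two <- draw_blob(60, 60, 5:14, 5:14) | draw_blob(60, 60, 40:49, 30:59)
  regs <- label_regions(two)
  expect_equal(nrow(regs), 2)
  expect_setequal(regs$area, c(100, 300))
})

test_that("8-connectivity keeps diagonal branch segments together", {
  m <- matrix(FALSE, 10, 10)
  for (i in 1:9) m[i, i] <- TRUE
  expect_equal(max(label_mask(m)), 1L)
  expect_equal(nrow(label_regions(m)), 1)
})

test_that("filter excludes squares and small regions, keeps panicle blobs", {
  mask <- matrix(FALSE, 300, 300)
  mask[11:70, 11:70] <- TRUE            # checkerboard square, area 3600
  mask[101:290, 141:160] <- TRUE        # elongated blob, 190 x 20 = 3800
  regs <- label_regions(mask)
  kept <- filter_panicle_regions(regs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$area, 3800)
  sq <- regs[regs$area == 3600, ]
  expect_gt(sq$solidity, 0.7)
  expect_lt(sq$eccentricity, 0.95)

  # any region under 1000 px is excluded regardless of shape
  thin <- matrix(FALSE, 200, 200)
  thin[50:52, 10:190] <- TRUE   # elongated, area 543 < 1000
  small <- label_regions(thin)
  expect_gte(small$eccentricity, 0.95)
  expect_equal(nrow(filter_panicle_regions(small)), 0)

  # area 999 exactly: excluded; area 1000: kept if shape passes
  r999 <- data.frame(region = 1, area = 999, solidity = 0.4,
                     eccentricity = 0.99)
  expect_equal(nrow(filter_panicle_regions(r999)), 0)
  r1000 <- transform(r999, area = 1000)
  expect_equal(nrow(filter_panicle_regions(r1000)), 1)
})

test_that("AND vs OR exclusion modes differ on half-square regions", {
  # compact but elongated region: solidity > 0.7 AND ecc >= 0.95
  regs <- data.frame(region = 1:3,
                     area = c(5000, 5000, 5000),
                     solidity = c(0.9, 0.5, 0.9),
                     eccentricity = c(0.99, 0.5, 0.5))
  and_kept <- filter_panicle_regions(regs, exclusion_mode = "and")
  or_kept <- filter_panicle_regions(regs, exclusion_mode = "or")
  expect_equal(and_kept$region, c(1, 2))
  expect_equal(or_kept$region, integer(0) + numeric(0))
})

test_that("filtering is monotone in its thresholds", {
  set.seed(5)
  regs <- data.frame(region = 1:40, area = sample(100:6000, 40),
                     solidity = runif(40), eccentricity = runif(40))
  px <- function(...) sum(filter_panicle_regions(regs, ...)$area)
  base <- px()
  expect_lte(px(min_area = 2000), base)
  expect_lte(px(solidity_max = 0.5), base)
  expect_lte(px(ecc_min = 0.99), base)
})

test_that("session pixel totals sum surviving areas across views", {
  blob <- matrix(FALSE, 300, 300)
  blob[51:250, 141:165] <- TRUE   # 200 x 25 = 5000 px elongated blob
  masks <- replicate(120, blob, simplify = FALSE)
  res <- total_pixel_count(masks)
  expect_equal(res$total, 120 * 5000)

  # frames containing only checkerboard squares count zero
  sq <- matrix(FALSE, 300, 300)
  sq[11:70, 11:70] <- TRUE
  sq[101:160, 201:260] <- TRUE
  expect_equal(total_pixel_count(replicate(10, sq, simplify = FALSE))$total, 0)

  manifest <- session_manifest("p", "G", "control", 1, 2, 60)
  expect_error(total_pixel_count(masks[1:5], manifest),
               class = "panicler_validation_error")
  expect_warning(res2 <- total_pixel_count(masks[1:5], manifest,
                                           strict = FALSE))
  expect_equal(res2$total, 5 * 5000)
})

test_that("rendered growing panicles give increasing 2D totals", {
  spec <- synthetic_panicle_spec(seed = 14)
  totals <- vapply(1:3, function(w) {
    scene <- make_scene(spec, week = w)
    rv <- render_views(point_cloud(scene$cloud$points, scene$cloud$colors,
                                   scene$truth$label),
                       n_views = 12, splat_radius = 2)
    total_pixel_count(rv$masks)$total
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("2D totals equal renderer truth when distractors are filtered", {
  spec <- synthetic_panicle_spec(seed = 10)
  scene <- make_scene(spec, week = 2)
  labeled <- point_cloud(scene$cloud$points, scene$cloud$colors,
                         scene$truth$label)
  rv <- render_views(labeled, n_views = 20, splat_radius = 2,
                     distractors = 3, seed = 4)
  res <- total_pixel_count(rv$masks)
  expect_equal(res$total, sum(rv$truth$pixel_count))
  # without distractors and with filters disabled the totals match exactly
  rv0 <- render_views(labeled, n_views = 20, splat_radius = 2)
  res0 <- total_pixel_count(rv0$masks, min_area = 1, solidity_max = 1.01,
                            ecc_min = 0)
  expect_equal(res0$total, sum(rv0$truth$pixel_count))
})
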