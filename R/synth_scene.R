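# Endpoint colors of the maturation schedule: immature panicles are green,
# mature ones yellow; stage tau in [0, 1] interpolates linearly.
panicle_green <- c(50, 160, 60)
panicle_yellow <- c(210, 180, 60)

stage_color <- function(stage) {
  (1 - stage) * panicle_green + stage * panicle_yellow
}

#' Specification of a synthetic panicle
#'
#' Parameters of the seeded scene generator: a panicle is a set of drooping
#' branches bearing ellipsoidal seeds, volumetrically point-sampled at
#' fixed density so voxel occupancy tracks true volume. `week_scale` is the
#' strictly increasing weekly volume multiplier emulating grain filling;
#' `color_stage` moves seed colors from green (0) to yellow (1) emulating
#' maturation.
#'
#' @param n_branches number of branches.
#' @param seeds_per_branch seeds per branch.
#' @param seed_semiaxes numeric length-3 ellipsoid semi-axes (cm).
#' @param week_scale strictly increasing length-3 volume multipliers for
#'   weeks 1-3.
#' @param color_stage maturation stage in `[0, 1]`.
#' @param points_per_cm3 volumetric sampling density of seed points.
#' @param wall_points_per_cm2 sampling density of the checkerboard
#'   reference surfaces.
#' @param color_jitter sd of per-point RGB jitter (8-bit units).
#' @param placement_jitter multiplier on branch-angle and seed-center
#'   placement jitter. The default 0 gives a deterministic skeleton, so the
#'   occupied volume is a strictly increasing function of the week's volume
#'   multiplier (seeds grow concentrically); set > 0 to randomize the
#'   architecture between plants.
#' @param seed integer RNG seed; every random choice in the generator flows
#'   from it.
#' @return an object of class `synthetic_panicle_spec`.
#' @export
synthetic_panicle_spec <- function(n_branches = 8, seeds_per_branch = 12,
                                   seed_semiaxes = c(0.5, 0.35, 0.35),
                                   week_scale = c(1, 1.6, 2.2),
                                   color_stage = 0.3,
                                   points_per_cm3 = 150,
                                   wall_points_per_cm2 = 0.5,
                                   color_jitter = 4,
                                   placement_jitter = 0,
                                   seed = 1L) {
  assert_that(n_branches >= 0 && seeds_per_branch >= 1,
              "panicler_validation_error", "counts must be non-negative")
  assert_that(length(seed_semiaxes) == 3 && all(seed_semiaxes > 0),
              "panicler_validation_error", "seed_semiaxes must be 3 positive lengths")
  assert_that(length(week_scale) == 3 && all(diff(week_scale) > 0),
              "panicler_validation_error", "week_scale must be strictly increasing")
  assert_that(color_stage >= 0 && color_stage <= 1,
              "panicler_validation_error", "color_stage must lie in [0, 1]")
  structure(list(n_branches = n_branches, seeds_per_branch = seeds_per_branch,
                 seed_semiaxes = seed_semiaxes, week_scale = week_scale,
                 color_stage = color_stage, points_per_cm3 = points_per_cm3,
                 wall_points_per_cm2 = wall_points_per_cm2,
                 color_jitter = color_jitter,
                 placement_jitter = placement_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_panicle_spec")
}

# Uniform points inside an ellipsoid centered at `center`.
sample_ellipsoid <- function(n, center, semiaxes) {
  if (n == 0) return(matrix(numeric(), 0, 3))
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  r <- runif(n)^(1 / 3)
  sweep(g * r * rep(semiaxes, each = n), 2, center, "+")
}

checker_palette <- function() {
  rbind(c(200, 40, 40), c(60, 170, 70), c(40, 60, 190),
        c(220, 200, 50), c(235, 235, 235), c(150, 60, 160))
}

# Sample points on a checkerboard-covered rectangle. `u_axis`/`v_axis` are
# orthogonal in-plane unit vectors, `origin` the rectangle corner.
sample_checker_rect <- function(origin, u_axis, v_axis, u_len, v_len,
                                density, square_edge, drop_disk = NULL) {
  n <- max(4L, round(density * u_len * v_len))
  u <- runif(n, 0, u_len)
  v <- runif(n, 0, v_len)
  pts <- sweep(outer(u, u_axis) + outer(v, v_axis), 2, origin, "+")
  if (!is.null(drop_disk)) {
    keep <- sqrt((pts[, 1] - drop_disk$center[1])^2 +
                   (pts[, 2] - drop_disk$center[2])^2) > drop_disk$radius
    pts <- pts[keep, , drop = FALSE]
    u <- u[keep]; v <- v[keep]
  }
  pal <- checker_palette()
  sq <- (floor(u / square_edge) + floor(v / square_edge)) %% nrow(pal) + 1L
  # a fixed per-square color drawn deterministically from the square index
  col <- pal[((sq * 7L + floor(u / square_edge) * 3L) %% nrow(pal)) + 1L, ,
             drop = FALSE]
  list(points = pts, colors = col)
}

# Branch curve: drooping arc from the hang point outward and down.
branch_curve <- function(tt, phi, model, reach, drop) {
  radial <- reach * sin(tt * pi / 2)
  cbind(radial * cos(phi), radial * sin(phi),
        -model$cube_top - 1 - drop * tt^1.2)
}

branch_seed_centers <- function(b, n_branches, seeds_per_branch, model,
                                reach, drop, jitter = 0) {
  phi <- 2 * pi * (b - 1) / n_branches + runif(1, -0.15, 0.15) * jitter
  tt <- seq(0.18, 1, length.out = seeds_per_branch)
  ctr <- branch_curve(tt, phi, model, reach, drop)
  ctr[, 1] <- ctr[, 1] + rnorm(seeds_per_branch, 0, 0.08) * jitter
  ctr[, 2] <- ctr[, 2] + rnorm(seeds_per_branch, 0, 0.08) * jitter
  attr(ctr, "phi") <- phi
  ctr
}

# Thin rachis/pedicel point samples along a branch curve (connects the
# seeds in 3D and in every projected view; its volume is negligible and is
# deliberately not part of the ground-truth seed volume).
branch_rachis_points <- function(phi, model, reach, drop, n = 60,
                                 thickness = 0.08) {
  tt <- runif(n, 0, 1)
  pts <- branch_curve(tt, phi, model, reach, drop)
  pts + matrix(rnorm(3 * n, 0, thickness), ncol = 3)
}

# Rasterized occupied volume of a union of ellipsoids: counts cells of a
# fine regular grid whose centers fall in any ellipsoid. Handles seed
# overlap exactly at grid precision.
union_ellipsoid_volume <- function(centers, semiaxes, resolution = 300,
                                   lo = NULL, hi = NULL) {
  if (nrow(centers) == 0) return(0)
  if (is.null(lo)) lo <- apply(centers, 2, min) - semiaxes
  if (is.null(hi)) hi <- apply(centers, 2, max) + semiaxes
  h <- (hi - lo) / resolution
  res <- resolution
  # accumulate unique occupied cell keys across seeds
  keys_all <- NULL
  for (s in seq_len(nrow(centers))) {
    c0 <- centers[s, ]
    i0 <- pmax(0, floor((c0 - semiaxes - lo) / h))
    i1 <- pmin(res - 1, floor((c0 + semiaxes - lo) / h))
    if (any(i1 < i0)) next
    gx <- lo[1] + (i0[1]:i1[1] + 0.5) * h[1]
    gy <- lo[2] + (i0[2]:i1[2] + 0.5) * h[2]
    gz <- lo[3] + (i0[3]:i1[3] + 0.5) * h[3]
    dx2 <- ((gx - c0[1]) / semiaxes[1])^2
    dy2 <- ((gy - c0[2]) / semiaxes[2])^2
    dz2 <- ((gz - c0[3]) / semiaxes[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    if (!any(inside)) next
    ii <- which(inside, arr.ind = TRUE)
    keys <- (i0[1] + ii[, 1] - 1) +
      res * ((i0[2] + ii[, 2] - 1) + res * (i0[3] + ii[, 3] - 1))
    keys_all <- c(keys_all, keys)
  }
  length(unique(keys_all)) * prod(h)
}

#' Generate a synthetic chamber scene with ground truth
#'
#' Emits a colored point cloud of one imaging session: a panicle built
#' from ellipsoidal seeds along drooping branches (volumetrically sampled),
#' checkerboard points on the board and three walls, and a gray hook at the
#' top of the scene. The true component label of every point, the true
#' occupied panicle volume (rasterized union of the seed ellipsoids), and
#' the seed centers are returned alongside.
#'
#' @param spec a [synthetic_panicle_spec()].
#' @param model a [chamber_model()].
#' @param week week 1-3; selects `spec$week_scale[week]`, which multiplies
#'   seed volume (semi-axes scale with its cube root).
#' @param color_stage override of `spec$color_stage`.
#' @param transform optional [similarity_transform()] applied to the whole
#'   scene (emulating the arbitrary frame of a reconstruction).
#' @return list with `cloud` (unlabeled [point_cloud()]), and `truth`: a
#'   list with `label`, `volume` (cm^3), `seed_centers`, `semiaxes`,
#'   `color_stage`, `week`.
#' @export
make_scene <- function(spec, model = chamber_model(), week = 1,
                       color_stage = spec$color_stage, transform = NULL) {
  stopifnot(inherits(spec, "synthetic_panicle_spec"))
  assert_that(week %in% 1:3, "panicler_validation_error", "week must be 1..3")
  with_local_seed(spec$seed + 97L * as.integer(week), {
    semi <- spec$seed_semiaxes * spec$week_scale[week]^(1 / 3)
    # long narrow habit: a rice panicle droops 15-20 cm with a few cm of
    # lateral spread, so multi-view silhouettes are strongly elongated
    reach <- model$cube_edge * 0.07
    drop <- model$cube_edge * 0.85

    centers <- NULL
    rachis <- matrix(numeric(), 0, 3)
    if (spec$n_branches > 0) {
      per_branch <- lapply(seq_len(spec$n_branches), function(b)
        branch_seed_centers(b, spec$n_branches, spec$seeds_per_branch,
                            model, reach, drop, spec$placement_jitter))
      centers <- do.call(rbind, per_branch)
      rachis <- do.call(rbind, lapply(per_branch, function(cb)
        branch_rachis_points(attr(cb, "phi"), model, reach, drop)))
    }
    seed_vol <- 4 / 3 * pi * prod(semi)
    pts_per_seed <- max(8L, round(spec$points_per_cm3 * seed_vol))
    pan_pts <- if (is.null(centers)) matrix(numeric(), 0, 3) else
      rbind(do.call(rbind, lapply(seq_len(nrow(centers)), function(s)
        sample_ellipsoid(pts_per_seed, centers[s, ], semi))), rachis)

    base_col <- stage_color(color_stage)
    pan_col <- matrix(rep(base_col, each = nrow(pan_pts)), ncol = 3)
    if (spec$color_jitter > 0 && nrow(pan_pts) > 0)
      pan_col <- pan_col + matrix(rnorm(length(pan_col), 0, spec$color_jitter),
                                  ncol = 3)
    pan_col <- pmin(pmax(pan_col, 0), 255)

    bx <- model$board_x; by <- model$board_y; h <- model$wall_depth
    dens <- spec$wall_points_per_cm2
    ce <- model$checker_edge
    board <- sample_checker_rect(c(-bx / 2, -by / 2, 0), c(1, 0, 0),
                                 c(0, 1, 0), bx, by, dens, ce,
                                 drop_disk = list(center = c(0, 0),
                                                  radius = model$aperture_radius))
    back <- sample_checker_rect(c(-bx / 2, -by / 2, 0), c(0, 1, 0),
                                c(0, 0, -1), by, h, dens, ce)
    side_n <- sample_checker_rect(c(-bx / 2, -by / 2, 0), c(1, 0, 0),
                                  c(0, 0, -1), bx, h, dens, ce)
    side_p <- sample_checker_rect(c(-bx / 2, by / 2, 0), c(1, 0, 0),
                                  c(0, 0, -1), bx, h, dens, ce)
    ref_pts <- rbind(board$points, back$points, side_n$points, side_p$points)
    ref_col <- rbind(board$colors, back$colors, side_n$colors, side_p$colors)

    n_hook <- 60L
    hook_ang <- runif(n_hook, 0, 2 * pi)
    hook_r <- 0.3 * sqrt(runif(n_hook))
    hook_pts <- cbind(hook_r * cos(hook_ang), hook_r * sin(hook_ang),
                      runif(n_hook, -model$cube_top, -1.2))
    hook_col <- matrix(128, n_hook, 3) +
      matrix(rep(round(rnorm(n_hook, 0, 4)), 3), ncol = 3)
    hook_col <- pmin(pmax(hook_col, 0), 255)

    pts <- rbind(pan_pts, ref_pts, hook_pts)
    cols <- rbind(pan_col, ref_col, hook_col)
    label <- c(rep("panicle", nrow(pan_pts)),
               rep("checkerboard", nrow(ref_pts)),
               rep("apparatus", n_hook))

    volume <- if (is.null(centers)) 0 else
      union_ellipsoid_volume(centers, semi)

    cloud <- point_cloud(pts, cols)
    if (!is.null(transform)) cloud <- apply_transform(cloud, transform)
    list(cloud = cloud,
         truth = list(label = label, volume = volume,
                      seed_centers = centers, semiaxes = semi,
                      color_stage = color_stage, week = week))
  })
}
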