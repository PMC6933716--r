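#' Generate a synthetic multi-genotype cohort with ground truth
#'
#' Emulates the weekly-imaging study design: `n_genotypes` genotypes under
#' two treatments (control and high night-time temperature, HNT) with two
#' to three replicates per genotype and treatment (alternating so the
#' default 11-genotype design totals 55 plants), each imaged in weeks 1-3.
#' Genotypes belong to designed growth groups with distinct weekly volume
#' schedules (for cluster recovery); HNT accelerates the green-to-yellow
#' maturation schedule. Manual end-point measurements (seed number, total
#' seed weight, fertility) are generated proportional to the plant's final
#' volume multiplier plus Gaussian relative noise of sd `noise_sd`, so the
#' voxel-count / seed-weight correlation is positive by construction. With
#' `noise_sd = 0` replicates are exact copies and end-points are exactly
#' proportional to volume.
#'
#' @param n_genotypes number of genotypes.
#' @param n_groups number of designed growth groups.
#' @param growth_schedules list (length `n_groups`) of strictly increasing
#'   length-3 weekly volume multipliers.
#' @param noise_sd relative sd of biological noise on end-points and
#'   replicate volumes.
#' @param seed integer RNG seed.
#' @param scenes if `TRUE`, generate and store the point-cloud scenes (one
#'   per unique scene key). With the default `FALSE`, scenes are not
#'   materialized; [cohort_traits()] and [cohort_scene()] generate them on
#'   demand, which bounds memory for densely sampled cohorts.
#' @param base_spec a [synthetic_panicle_spec()] used as the template for
#'   all scenes. The default samples seeds densely (2500 points per cm^3)
#'   so that voxel occupancy saturates and tracks true volume.
#' @param model a [chamber_model()].
#' @return list with `plants` (one row per plant: genotype, replicate,
#'   treatment, group), `observations` (one row per plant x week with the
#'   true volume multiplier, color stage and scene key), `end_points`
#'   (trait-table rows at maturity), `scenes` (named list of
#'   [make_scene()] outputs, or `NULL`), and `truth` (genotype group map
#'   and schedules).
#' @export
make_cohort <- function(n_genotypes = 11, n_groups = 2,
                        growth_schedules = list(c(1, 1.3, 4.5),
                                                c(1.7, 2.6, 3.4)),
                        noise_sd = 0.05, seed = 1L, scenes = FALSE,
                        base_spec = synthetic_panicle_spec(
                          points_per_cm3 = 2500, wall_points_per_cm2 = 0.4),
                        model = chamber_model()) {
  assert_that(length(growth_schedules) == n_groups,
              "panicler_validation_error",
              "need one growth schedule per group")
  for (gs in growth_schedules)
    assert_that(length(gs) == 3 && all(diff(gs) > 0),
                "panicler_validation_error",
                "growth schedules must be strictly increasing over 3 weeks")
  genotypes <- sprintf("G%02d", seq_len(n_genotypes))
  group <- rep(seq_len(n_groups), length.out = n_genotypes)
  group <- sort(group)
  # Deterministic within-group size spread keeps genotype volumes distinct.
  # Together with the default growth schedules (weekly factors pairwise
  # separated by >= 1.25x across all group-week combinations, and of
  # different shape: sustained late filling vs early vigor) every scene's
  # nominal volume lands in its own band, so true volume totally orders
  # the cohort and trajectory shapes separate the groups.
  base_mult <- numeric(n_genotypes)
  for (g in seq_len(n_groups)) {
    idx <- which(group == g)
    base_mult[idx] <- seq(0.93, 1.07, length.out = length(idx))
  }
  treatments <- c("control", "HNT")
  stages <- list(control = c(0.15, 0.45, 0.75), HNT = c(0.30, 0.60, 0.90))

  with_local_seed(seed, {
    plants <- NULL
    observations <- NULL
    end_points <- NULL
    for (gi in seq_len(n_genotypes)) {
      for (ti in seq_along(treatments)) {
        n_reps <- if ((gi + ti) %% 2 == 0) 3L else 2L
        for (rep_i in seq_len(n_reps)) {
          rep_noise <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
          vol_mult3 <- base_mult[gi] * growth_schedules[[group[gi]]] *
            (1 + rep_noise)
          plants <- rbind(plants, data.frame(
            genotype = genotypes[gi], replicate = rep_i,
            treatment = treatments[ti], group = group[gi],
            stringsAsFactors = FALSE))
          for (w in 1:3) {
            # seed depends on the genotype only: the same plant geometry is
            # imaged across weeks and treatments (color differs, not shape)
            scene_seed <- (abs(seed) * 7919L + gi * 211L) %% 100000L
            key <- sprintf("%s_%s_w%d_m%.6f", genotypes[gi],
                           treatments[ti], w, vol_mult3[w])
            observations <- rbind(observations, data.frame(
              genotype = genotypes[gi], replicate = rep_i,
              treatment = treatments[ti], week = w, group = group[gi],
              volume_mult = vol_mult3[w],
              color_stage = stages[[treatments[ti]]][w],
              scene_key = key, scene_seed = scene_seed,
              stringsAsFactors = FALSE))
          }
          final_mult <- vol_mult3[3]
          e_n <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
          e_w <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
          seed_number <- round(150 * final_mult * (1 + e_n))
          weight <- 3.1 * final_mult * (1 + e_w)
          end_points <- rbind(end_points, data.frame(
            genotype = genotypes[gi], replicate = rep_i,
            treatment = treatments[ti], week = 3L,
            seed_number = seed_number, total_seed_weight = weight,
            weight_per_seed = weight / seed_number,
            fertility = min(100, max(0, 88 + (if (noise_sd > 0)
              rnorm(1, 0, 100 * noise_sd) else 0))),
            stringsAsFactors = FALSE))
        }
      }
    }

    cohort <- list(plants = plants, observations = observations,
                   end_points = validate_trait_table(end_points),
                   scenes = NULL, base_spec = base_spec, model = model,
                   truth = list(genotype = genotypes,
                                group = stats::setNames(group, genotypes),
                                base_mult = stats::setNames(base_mult, genotypes),
                                growth_schedules = growth_schedules,
                                stages = stages))
    if (scenes) {
      uniq <- observations[!duplicated(observations$scene_key), ]
      cohort$scenes <- lapply(seq_len(nrow(uniq)), function(i)
        cohort_scene(cohort, uniq[i, ]))
      names(cohort$scenes) <- uniq$scene_key
    }
    cohort
  })
}

#' Generate one cohort scene on demand
#'
#' @param cohort output of [make_cohort()].
#' @param observation one row of `cohort$observations` (or a scene key).
#' @return the [make_scene()] output for that observation.
#' @export
cohort_scene <- function(cohort, observation) {
  if (is.character(observation)) {
    i <- match(observation, cohort$observations$scene_key)
    assert_that(!is.na(i), "panicler_validation_error",
                "unknown scene key: %s", observation)
    observation <- cohort$observations[i, ]
  }
  o <- observation
  gi <- match(o$genotype, cohort$truth$genotype)
  base <- cohort$truth$base_mult[gi]
  sched <- base * cohort$truth$growth_schedules[[o$group]] *
    (o$volume_mult / (base * cohort$truth$growth_schedules[[o$group]][o$week]))
  bs <- cohort$base_spec
  spec <- synthetic_panicle_spec(
    n_branches = bs$n_branches, seeds_per_branch = bs$seeds_per_branch,
    seed_semiaxes = bs$seed_semiaxes, week_scale = sched,
    color_stage = o$color_stage, points_per_cm3 = bs$points_per_cm3,
    wall_points_per_cm2 = bs$wall_points_per_cm2,
    color_jitter = bs$color_jitter,
    placement_jitter = bs$placement_jitter, seed = o$scene_seed)
  make_scene(spec, cohort$model, week = o$week, color_stage = o$color_stage)
}

#' Run the 3D trait pipeline over a generated cohort
#'
#' Applies [session_traits()] to every unique scene of a cohort generated
#' with `scenes = TRUE` and joins the traits back onto the per-plant
#' observations.
#'
#' @param cohort output of [make_cohort()] with scenes.
#' @param model the [chamber_model()] the cohort was built with.
#' @param resolution voxel resolution for [chamber_cube()].
#' @return the cohort `observations` data.frame with `voxel_count`,
#'   `color_sum_r/g/b`, `rg_ratio` and `true_volume` columns added.
#' @export
cohort_traits <- function(cohort, model = cohort$model, resolution = 200) {
  cube <- chamber_cube(model, resolution)
  uniq <- cohort$observations[!duplicated(cohort$observations$scene_key), ]
  keys <- uniq$scene_key
  per_scene <- lapply(seq_len(nrow(uniq)), function(i) {
    sc <- if (!is.null(cohort$scenes)) cohort$scenes[[keys[i]]] else
      cohort_scene(cohort, uniq[i, ])
    tr <- session_traits(sc$cloud, model, cube = cube)
    c(voxel_count = tr$voxel_count, color_sum_r = tr$color_sum_r,
      color_sum_g = tr$color_sum_g, color_sum_b = tr$color_sum_b,
      rg_ratio = tr$rg_ratio, true_volume = sc$truth$volume)
  })
  tab <- do.call(rbind, per_scene)
  obs <- cohort$observations
  m <- match(obs$scene_key, keys)
  cbind(obs, as.data.frame(tab[m, , drop = FALSE], row.names = FALSE))
}
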