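#' Read / write a pipeline run configuration as JSON
#'
#' A run configuration bundles every tunable parameter of the pipeline
#' (HSV thresholds, denoising size, voxel resolution, 2D filter thresholds,
#' opening radius, statistics options) plus the RNG seed, and is serialized
#' verbatim into every output directory so a run can be reproduced exactly.
#'
#' @param ... parameter overrides of the defaults.
#' @return `run_config`: a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    hue_range = c(0, 1), sat_range = c(0, 1), val_range = c(0.15, 1),
    min_component_px = 50,
    resolution = 1000,
    wall_distance_tol = 1,
    solidity_max = 0.7, ecc_min = 0.95, min_area = 1000,
    exclusion_mode = "and",
    scan_hue = c(0, 0.3), scan_sat = c(0.2, 1), scan_val = c(0.5, 1),
    opening_radius = 2, min_seed_width = 8, min_seed_area = 30,
    alpha = 0.1, var_equal = TRUE, clusters = 4,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  assert_that(length(bad) == 0, "panicler_validation_error",
              "unknown config parameter(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "panicler_io_error", "no such file: %s", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
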