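#' Imaging-session manifest
#'
#' One manifest describes a single panicle imaging session: which plant was
#' imaged, under which treatment, in which week, and the multi-view image
#' files the rotating two-camera rig produced (60 images per camera per
#' session, i.e. one frame every six degrees, 120 views in total at the
#' default rig configuration).
#'
#' @param panicle_id plant identifier (the physical rig reads it from a QR
#'   tag; here it is just a string key).
#' @param genotype genotype name.
#' @param treatment `"control"` or `"HNT"` (high night-time temperature).
#' @param week integer week post-fertilization, 1 to 3.
#' @param n_cameras number of cameras on the rotary ring.
#' @param images_per_camera frames per camera per session.
#' @param image_paths character vector of image files; must have length
#'   `n_cameras * images_per_camera`.
#' @return an object of class `session_manifest`.
#' @export
session_manifest <- function(panicle_id, genotype, treatment, week,
                             n_cameras = 2L, images_per_camera = 60L,
                             image_paths = character()) {
  treatment <- match.arg(treatment, c("control", "HNT"))
  assert_that(is_count(week), "panicler_validation_error",
              "week must be a positive integer")
  assert_that(is_count(n_cameras) && is_count(images_per_camera),
              "panicler_validation_error",
              "camera counts must be positive integers")
  expected <- n_cameras * images_per_camera
  assert_that(length(image_paths) == 0 || length(image_paths) == expected,
              "panicler_validation_error",
              "expected %d image paths (%d cameras x %d images), got %d",
              expected, n_cameras, images_per_camera, length(image_paths))
  structure(
    list(panicle_id = panicle_id, genotype = genotype, treatment = treatment,
         week = as.integer(week), n_cameras = as.integer(n_cameras),
         images_per_camera = as.integer(images_per_camera),
         image_paths = image_paths),
    class = "session_manifest"
  )
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("session_manifest: %s (%s, %s, week %d), %d x %d views\n",
              x$panicle_id, x$genotype, x$treatment, x$week,
              x$n_cameras, x$images_per_camera))
  invisible(x)
}

#' Enumerate imaging sessions for a whole experiment
#'
#' Builds one manifest per panicle per timepoint and reports the total
#' image count of the campaign, `n_panicles * n_timepoints * n_cameras *
#' images_per_camera`. At the study scale of 55 panicles imaged weekly for
#' three weeks with two cameras taking 60 frames each, that is 19,800 images.
#'
#' @param n_panicles number of panicles (plants) in the experiment.
#' @param n_timepoints number of weekly imaging sessions per panicle.
#' @param n_cameras cameras per session.
#' @param images_per_camera frames per camera per session.
#' @return a list with `manifests` (list of [session_manifest()]) and
#'   `total_images`.
#' @examples
#' build_imaging_manifest(55, 3, 2, 60)$total_images  # 19800
#' @export
build_imaging_manifest <- function(n_panicles, n_timepoints,
                                   n_cameras = 2L, images_per_camera = 60L) {
  for (arg in list(n_panicles, n_timepoints, n_cameras, images_per_camera))
    assert_that(is_count(arg), "panicler_validation_error",
                "all manifest arguments must be positive integers")
  manifests <- vector("list", n_panicles * n_timepoints)
  k <- 1L
  for (p in seq_len(n_panicles)) {
    for (w in seq_len(n_timepoints)) {
      manifests[[k]] <- session_manifest(
        panicle_id = sprintf("P%03d", p), genotype = sprintf("G%02d", p),
        treatment = "control", week = w,
        n_cameras = n_cameras, images_per_camera = images_per_camera)
      k <- k + 1L
    }
  }
  list(manifests = manifests,
       total_images = n_panicles * n_timepoints * n_cameras * images_per_camera)
}
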