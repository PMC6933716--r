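random_cloud <- function(n, labeled = FALSE, seed = 1) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n, -10, 10), ncol = 3),
              matrix(sample(0:255, 3 * n, replace = TRUE), ncol = 3),
              if (labeled) sample(c("panicle", "checkerboard", "apparatus",
                                    "unassigned"), n, replace = TRUE))
}

test_that("PLY round trip is lossless for random clouds of all sizes", {
  for (n in c(0, 1, 1000)) {
    for (fmt in c("binary_little_endian", "ascii")) {
      cl <- random_cloud(n, seed = n + 1)
      path <- withr::local_tempfile(fileext = ".ply")
      write_point_cloud(cl, path, format = fmt)
      back <- read_point_cloud(path)
      expect_equal(n_points(back), n)
      if (n > 0) {
        expect_lt(max(abs(back$points - cl$points) /
                        pmax(abs(cl$points), 1)), 1e-6)
        expect_equal(unname(back$colors + 0), unname(cl$colors + 0))
      }
    }
  }
})

test_that("labels survive a PLY round trip as an integer property", {
  cl <- random_cloud(200, labeled = TRUE, seed = 9)
  path <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(cl, path)
  expect_identical(read_point_cloud(path)$label, cl$label)
})

test_that("hand-written ASCII PLY parses to the exact listed vertices", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0", "element vertex 3",
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header",
    "0 0 0 255 0 0", "1 0 0 0 255 0", "0 1 0 0 0 255"), path)
  cl <- read_point_cloud(path)
  expect_equal(n_points(cl), 3)
  expect_equal(cl$points, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(cl$colors, rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255)))
})

test_that("PLY reader reports missing color properties and bad headers", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "end_header", "0 0 0 1 2"), path)
  expect_error(read_point_cloud(path), "blue",
               class = "panicler_format_error")
  writeLines(c("not_ply", "format ascii 1.0"), path)
  expect_error(read_point_cloud(path), "byte offset",
               class = "panicler_parse_error")
})

test_that("r/g/b color property names are accepted", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "property uchar r", "property uchar g", "property uchar b",
               "end_header", "1 2 3 10 20 30"), path)
  cl <- read_point_cloud(path)
  expect_equal(cl$colors, matrix(c(10, 20, 30), 1))
})

test_that("manifest totals are multiplicative and match the study design", {
  expect_equal(build_imaging_manifest(55, 3, 2, 60)$total_images, 19800)
  expect_equal(build_imaging_manifest(1, 1, 1, 1)$total_images, 1)
  expect_equal(build_imaging_manifest(1, 1, 2, 60)$total_images, 120)
  # permutation invariance of the product
  set.seed(4)
  for (i in 1:10) {
    args <- sample(1:6, 4, replace = TRUE)
    t1 <- do.call(build_imaging_manifest, as.list(args))$total_images
    t2 <- do.call(build_imaging_manifest, as.list(sample(args)))$total_images
    expect_identical(t1, t2)
    expect_equal(t1, prod(args))
  }
  m <- build_imaging_manifest(3, 2)
  expect_length(m$manifests, 6)
  expect_s3_class(m$manifests[[1]], "session_manifest")
  expect_error(build_imaging_manifest(0, 1, 1, 1),
               class = "panicler_validation_error")
})

test_that("trait tables round trip and duplicate keys are rejected", {
  tab <- data.frame(genotype = rep(sprintf("G%02d", 1:11), each = 5),
                    replicate = rep(1:5, 11),
                    treatment = "control", week = 3,
                    voxel_count = seq_len(55) * 100,
                    fertility = runif(55, 60, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(tab, path)
  back <- read_trait_table(path)
  expect_equal(back, tab, tolerance = 1e-12)

  empty <- tab[0, ]
  write_trait_table(empty, path)
  expect_equal(nrow(read_trait_table(path)), 0)

  dup <- rbind(tab, tab[1, ])
  expect_error(write_trait_table(dup, path), "G01",
               class = "panicler_integrity_error")
  expect_error(validate_trait_table(transform(tab, fertility = 101)),
               class = "panicler_validation_error")
})
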