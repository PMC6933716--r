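trait_table_keys <- c("genotype", "replicate", "treatment", "week")

trait_table_cols <- c(
  "voxel_count", "color_sum_r", "color_sum_g", "color_sum_b", "rg_ratio",
  "pixel_count_2d", "projected_surface_area", "projected_seed_count",
  "seed_area", "seed_length", "seed_width",
  "total_seed_weight", "seed_number", "weight_per_seed", "fertility"
)

#' Validate a long-format trait table
#'
#' A trait table holds one row per (genotype, replicate, treatment, week)
#' observation and joins the digital traits (voxel count, color sums, R:G
#' ratio, 2D pixel count, scan morphometry) with manual end-point
#' measurements (seed number, weight, fertility). Missing values are `NA`;
#' keys must be unique.
#'
#' @param table a `data.frame` with the four key columns and any subset of
#'   the trait columns.
#' @return the table, with keys coerced to character/integer, invisibly
#'   usable downstream.
#' @export
validate_trait_table <- function(table) {
  assert_that(is.data.frame(table), "panicler_validation_error",
              "trait table must be a data.frame")
  miss <- setdiff(trait_table_keys, names(table))
  assert_that(length(miss) == 0, "panicler_validation_error",
              "missing key column(s): %s", paste(miss, collapse = ", "))
  key <- do.call(paste, c(table[trait_table_keys], sep = "\r"))
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0)
    stop_panicler("panicler_integrity_error",
                  "duplicate (genotype, replicate, treatment, week) key(s): %s",
                  paste(gsub("\r", "/", dup), collapse = "; "))
  counts <- intersect(c("voxel_count", "pixel_count_2d", "projected_seed_count",
                        "seed_number"), names(table))
  for (cc in counts)
    assert_that(all(is.na(table[[cc]]) | table[[cc]] >= 0),
                "panicler_validation_error", "negative values in %s", cc)
  if ("fertility" %in% names(table))
    assert_that(all(is.na(table$fertility) |
                      (table$fertility >= 0 & table$fertility <= 100)),
                "panicler_validation_error", "fertility outside [0, 100]")
  table
}

#' Read / write trait tables as CSV
#'
#' Plain comma-separated UTF-8 CSV with a header row, `.` decimal separator
#' and empty cells for missing values. Reading validates key uniqueness and
#' value ranges.
#'
#' @param path CSV file path.
#' @return `read_trait_table`: the validated `data.frame`.
#' @export
read_trait_table <- function(path) {
  assert_that(file.exists(path), "panicler_io_error", "no such file: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(tab)
}

#' @rdname read_trait_table
#' @param table a validated trait table.
#' @return `write_trait_table`: `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  validate_trait_table(table)
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
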