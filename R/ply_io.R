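ply_type_size <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

ply_is_float <- function(type) type %in% c("float", "float32", "double", "float64")

# Decode one fixed-width property from an interleaved binary vertex block.
ply_decode_column <- function(raw, offset, size, type, n, stride) {
  sel <- rep(offset + seq_len(size), n) + rep((seq_len(n) - 1L) * stride, each = size)
  readBin(raw[sel],
          what = if (ply_is_float(type)) "double" else "integer",
          n = n, size = size, signed = !(size <= 2 && grepl("^u", type)),
          endian = "little")
}

#' Read a colored point cloud from a PLY file
#'
#' Accepts ASCII and binary little-endian PLY with `x`, `y`, `z` vertex
#' coordinates and per-vertex colors named either `red`/`green`/`blue` or
#' `r`/`g`/`b`. A `label` integer property, as written by
#' [write_point_cloud()] for segmented clouds, is restored when present.
#'
#' @param path path to a `.ply` file.
#' @return a [point_cloud()] with vertices in file order.
#' @export
read_point_cloud <- function(path) {
  assert_that(file.exists(path), "panicler_io_error", "no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  header <- character()
  offset <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0)
      stop_panicler("panicler_parse_error",
                    "%s: header ended prematurely at byte offset %d", path, offset)
    offset <- offset + nchar(line, type = "bytes") + 1L
    line <- sub("\r$", "", line)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 1000)
      stop_panicler("panicler_parse_error",
                    "%s: no end_header within first %d bytes", path, offset)
  }
  if (header[1] != "ply")
    stop_panicler("panicler_parse_error",
                  "%s: missing 'ply' magic at byte offset 0", path)

  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1)
    stop_panicler("panicler_parse_error", "%s: missing format line", path)
  format <- strsplit(fmt_line, "\\s+")[[1]][2]
  assert_that(format %in% c("ascii", "binary_little_endian"),
              "panicler_format_error", "%s: unsupported PLY format '%s'",
              path, format)

  # Collect elements and their properties; only 'vertex' is interpreted.
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  types = character(), props = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$types <- c(cur$types, "list")
        cur$props <- c(cur$props, tok[5])
      } else {
        cur$types <- c(cur$types, tok[2])
        cur$props <- c(cur$props, tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  assert_that("vertex" %in% names(elements), "panicler_format_error",
              "%s: no vertex element in header", path)
  vtx <- elements$vertex
  assert_that(names(elements)[1] == "vertex", "panicler_format_error",
              "%s: vertex element must come first", path)
  assert_that(!any(vtx$types == "list"), "panicler_format_error",
              "%s: list-typed vertex properties are unsupported", path)

  for (p in c("x", "y", "z"))
    assert_that(p %in% vtx$props, "panicler_format_error",
                "%s: missing vertex property '%s'", path, p)
  col_names <- if (all(c("red", "green", "blue") %in% vtx$props)) {
    c("red", "green", "blue")
  } else if (all(c("r", "g", "b") %in% vtx$props)) {
    c("r", "g", "b")
  } else {
    miss <- setdiff(c("red", "green", "blue"), vtx$props)
    stop_panicler("panicler_format_error",
                  "%s: missing color property '%s' (accepts red/green/blue or r/g/b)",
                  path, miss[1])
  }

  n <- vtx$count
  if (format == "ascii") {
    vals <- scan(con, what = numeric(), n = n * length(vtx$props), quiet = TRUE)
    if (length(vals) != n * length(vtx$props))
      stop_panicler("panicler_parse_error",
                    "%s: expected %d vertex values, found %d", path,
                    n * length(vtx$props), length(vals))
    dat <- matrix(vals, ncol = length(vtx$props), byrow = TRUE)
    colnames(dat) <- vtx$props
    cols <- lapply(vtx$props, function(p) dat[, p])
    names(cols) <- vtx$props
  } else {
    sizes <- ply_type_size[vtx$types]
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride)
      stop_panicler("panicler_parse_error",
                    "%s: truncated binary body at byte offset %d",
                    path, offset + length(raw))
    offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
    cols <- mapply(function(o, s, tp) ply_decode_column(raw, o, s, tp, n, stride),
                   offs, sizes, vtx$types, SIMPLIFY = FALSE)
    names(cols) <- vtx$props
  }

  pts <- cbind(cols$x, cols$y, cols$z)
  rgb <- cbind(cols[[col_names[1]]], cols[[col_names[2]]], cols[[col_names[3]]])
  label <- NULL
  if ("label" %in% vtx$props) {
    codes <- as.integer(cols$label)
    assert_that(all(codes %in% 0:3), "panicler_format_error",
                "%s: label codes outside 0..3", path)
    label <- point_labels()[codes + 1L]
  }
  if (n == 0) {
    pts <- matrix(numeric(), 0, 3)
    rgb <- matrix(numeric(), 0, 3)
  }
  point_cloud(pts, rgb, label)
}

#' Write a point cloud to PLY
#'
#' Emits binary little-endian PLY by default (coordinates as 32-bit floats,
#' colors as `uchar`); pass `format = "ascii"` for a readable file. Component
#' labels, when present, are stored as an extra integer vertex property
#' `label` with codes 0 = unassigned, 1 = panicle, 2 = checkerboard,
#' 3 = apparatus.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  has_label <- !is.null(cloud$label)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_panicler(
                    "panicler_io_error", "cannot open '%s' for writing", path))
  on.exit(close(con))

  header <- c(
    "ply",
    sprintf("format %s 1.0", format),
    "comment written by panicler",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    if (has_label) "property int label",
    "end_header"
  )
  writeLines(header, con, sep = "\n")

  codes <- if (has_label) match(cloud$label, point_labels()) - 1L
  cols <- round(cloud$colors)
  if (format == "ascii") {
    if (n > 0) {
      rows <- cbind(format(cloud$points, digits = 9, trim = TRUE, scientific = FALSE),
                    cols, if (has_label) codes)
      writeLines(apply(rows, 1L, paste, collapse = " "), con, sep = "\n")
    }
  } else if (n > 0) {
    # interleave per-vertex: 3 x float32, 3 x uchar, optional int32
    stride <- 12L + 3L + if (has_label) 4L else 0L
    out <- raw(n * stride)
    base <- (seq_len(n) - 1L) * stride
    pts_raw <- writeBin(as.numeric(t(cloud$points)), raw(),
                        size = 4, endian = "little")
    out[rep(base, each = 12L) + seq_len(12L)] <- pts_raw
    out[rep(base, each = 3L) + 12L + seq_len(3L)] <- as.raw(t(cols))
    if (has_label) {
      lab_raw <- writeBin(codes, raw(), size = 4, endian = "little")
      out[rep(base, each = 4L) + 15L + seq_len(4L)] <- lab_raw
    }
    writeBin(out, con)
  }
  invisible(path)
}
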