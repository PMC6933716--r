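# Connected-component labeling and region properties shared by the
# multi-view 2D pipeline and the seed-scan pipeline.

#' Label 8-connected foreground components
#'
#' 8-connectivity keeps thin diagonal branch segments connected. Components
#' are found with a 4-connected pass (EBImage) and diagonal-touching labels
#' are then merged by union-find.
#'
#' @param mask H x W logical mask.
#' @return H x W integer matrix; 0 = background, components numbered from 1.
#' @export
label_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))

  nr <- nrow(lab); nc <- ncol(lab)
  edges <- NULL
  # diagonal neighbor pairs: down-right and down-left
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) edges <- cbind(a[sel], b[sel])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) edges <- rbind(edges, cbind(a[sel], b[sel]))

  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(edges)) {
    edges <- unique(edges)
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Area of the convex image of a pixel set: pixels of the bounding box whose
# centers lie inside (or on) the convex hull of the set's pixel centers.
convex_image_area <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2) return(n)
  hull <- grDevices::chull(cols, rows)
  hx <- cols[hull]; hy <- rows[hull]
  if (length(hull) <= 2) return(n)
  rr <- seq(min(rows), max(rows))
  cc <- seq(min(cols), max(cols))
  grid_r <- rep(rr, times = length(cc))
  grid_c <- rep(cc, each = length(rr))
  inside <- pracma::inpolygon(grid_c, grid_r, hx, hy, boundary = TRUE)
  sum(inside)
}

# Second-central-moment ellipse of a pixel set. Axis lengths follow the
# uniform-ellipse convention (full axis = 4 * sqrt(eigenvalue)), so a filled
# digital ellipse of semi-axes (a, b) measures close to (2a, 2b).
moment_ellipse <- function(rows, cols) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  # 1/12 term: second moment of the unit pixel itself
  crr <- sum((rows - mr)^2) / n + 1 / 12
  ccc <- sum((cols - mc)^2) / n + 1 / 12
  crc <- sum((rows - mr) * (cols - mc)) / n
  tr <- crr + ccc
  det <- crr * ccc - crc^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(0, tr / 2 - disc)
  list(
    major_axis = 4 * sqrt(l1),
    minor_axis = 4 * sqrt(l2),
    eccentricity = if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1)),
    centroid = c(mr, mc)
  )
}

#' Measure connected regions of a binary mask
#'
#' Labels the mask with 8-connectivity and computes, per region: pixel area,
#' solidity (area over convex-image area, in (0, 1]), eccentricity of the
#' ellipse with the same second central moments as the region (0 isotropic,
#' approaching 1 when elongated), major/minor axis lengths of that ellipse,
#' and the centroid.
#'
#' @param mask H x W logical mask.
#' @return `data.frame` with one row per region: `region`, `area`,
#'   `solidity`, `eccentricity`, `major_axis`, `minor_axis`,
#'   `centroid_row`, `centroid_col`.
#' @export
label_regions <- function(mask) {
  lab <- label_mask(mask)
  k <- max(lab)
  empty <- data.frame(region = integer(), area = integer(),
                      solidity = numeric(), eccentricity = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      centroid_row = numeric(), centroid_col = numeric())
  if (k == 0) return(empty)
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  labs <- lab[idx]
  ord <- order(labs)
  rows <- rows[ord]; cols <- cols[ord]; labs <- labs[ord]
  bounds <- c(0L, cumsum(tabulate(labs, k)))
  res <- empty
  for (i in seq_len(k)) {
    sel <- (bounds[i] + 1L):bounds[i + 1L]
    r <- rows[sel]; cl <- cols[sel]
    area <- length(sel)
    hull_area <- convex_image_area(r, cl)
    me <- moment_ellipse(r, cl)
    res <- rbind(res, data.frame(
      region = i, area = area,
      solidity = min(1, area / hull_area),
      eccentricity = me$eccentricity,
      major_axis = me$major_axis, minor_axis = me$minor_axis,
      centroid_row = me$centroid[1], centroid_col = me$centroid[2]))
  }
  res
}
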