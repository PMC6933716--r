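#' Similarity transform (scale, rotation, translation)
#'
#' Maps a point `p` to `scale * R %*% p + t`. Used to bring reconstructed
#' clouds, whose scale and orientation are arbitrary after multi-view
#' stereo, into the canonical chamber frame.
#'
#' @param scale positive scalar.
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric vector.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  assert_that(length(scale) == 1 && is.finite(scale) && scale > 0,
              "panicler_validation_error", "scale must be positive")
  rotation <- as.matrix(rotation)
  assert_that(all(dim(rotation) == c(3, 3)) &&
                max(abs(crossprod(rotation) - diag(3))) < 1e-9 &&
                abs(det(rotation) - 1) < 1e-9,
              "panicler_validation_error",
              "rotation must be orthonormal with det +1")
  assert_that(length(translation) == 3 && all(is.finite(translation)),
              "panicler_validation_error", "translation must be a 3-vector")
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform: scale %.6g, translation (%s)\n",
              x$scale, paste(signif(x$translation, 6), collapse = ", ")))
  invisible(x)
}

#' Apply a similarity transform to a point cloud or coordinate matrix
#'
#' @param cloud a [point_cloud()] or an N x 3 matrix.
#' @param transform a [similarity_transform()].
#' @return the transformed cloud (colors and labels unchanged) or matrix.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  tf <- function(m) {
    if (nrow(m) == 0) return(m)
    sweep(transform$scale * (m %*% t(transform$rotation)), 2,
          transform$translation, "+")
  }
  if (inherits(cloud, "point_cloud")) {
    point_cloud(tf(cloud$points), cloud$colors, cloud$label)
  } else {
    tf(as.matrix(cloud))
  }
}

#' Invert / compose similarity transforms
#'
#' `compose_transform(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param transform,a,b [similarity_transform()] objects.
#' @return a [similarity_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  similarity_transform(1 / transform$scale, Rt,
                       -(Rt %*% transform$translation) / transform$scale)
}

#' @rdname invert_transform
#' @export
compose_transform <- function(a, b) {
  similarity_transform(a$scale * b$scale, a$rotation %*% b$rotation,
                       a$scale * as.numeric(a$rotation %*% b$translation) +
                         a$translation)
}

# Least-squares similarity fit (Umeyama): finds s, R, t minimizing
# sum_i || s R x_i + t - y_i ||^2 for corresponding landmark sets.
fit_similarity <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3, nrow(x) >= 3)
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  S <- crossprod(yc, xc) / nrow(x)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- sum(xc^2) / nrow(x)
  assert_that(var_x > 0 && sv$d[2] > 1e-12 * sv$d[1],
              "panicler_rank_error",
              "degenerate (collinear) landmark configuration")
  s <- sum(diag(D) * sv$d) / var_x
  t_vec <- my - s * as.numeric(R %*% mx)
  tf <- similarity_transform(s, R, t_vec)
  fitted <- apply_transform(x, tf)
  rms <- sqrt(mean(rowSums((fitted - y)^2)))
  attr(tf, "rms") <- rms
  tf
}
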