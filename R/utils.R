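#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dist hclust pt qt rnorm runif sd t.test var
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices chull rgb2hsv
NULL

# Abort with a classed condition so callers can test for specific failures.
stop_panicler <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "panicler_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) stop_panicler(class, msg, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Evaluate `expr` with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All generator randomness flows through
# this so results depend only on the explicit seed argument.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Shoelace area of a polygon given vertex coordinates.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
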