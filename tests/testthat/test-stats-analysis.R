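# independent oracle for Pearson r: explicit covariance over variance
oracle_r <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("pearson_matrix reproduces closed-form and oracle values", {
  x <- 1:10
  tab <- data.frame(a = x, b = 2 * x + 1)
  cm <- pearson_matrix(tab)
  expect_equal(cm$r["a", "b"], 1.0)

  tab2 <- data.frame(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  cm2 <- pearson_matrix(tab2)
  expect_equal(cm2$r["a", "b"], 0.6)

  set.seed(19)
  for (i in 1:20) {
    u <- rnorm(25); v <- rnorm(25)
    cm3 <- pearson_matrix(data.frame(u = u, v = v))
    expect_equal(cm3$r["u", "v"], oracle_r(u, v), tolerance = 1e-12)
    # p from the t transform with n - 2 df
    r <- cm3$r["u", "v"]
    tt <- r * sqrt(23 / (1 - r^2))
    expect_equal(cm3$p["u", "v"], 2 * pt(-abs(tt), 23), tolerance = 1e-12)
  }
})

test_that("sign flips negate r and keep p; missing pairs are dropped", {
  set.seed(3)
  tab <- data.frame(a = rnorm(30), b = rnorm(30))
  flipped <- transform(tab, b = -b)
  cm <- pearson_matrix(tab); cmf <- pearson_matrix(flipped)
  expect_equal(cmf$r["a", "b"], -cm$r["a", "b"])
  expect_equal(cmf$p["a", "b"], cm$p["a", "b"])

  tab$b[1:5] <- NA
  cmn <- pearson_matrix(tab)
  expect_equal(cmn$n["a", "b"], 25L)
  expect_equal(cmn$r["a", "b"], oracle_r(tab$a[-(1:5)], tab$b[-(1:5)]))

  const <- data.frame(a = rnorm(10), b = rep(2, 10))
  cmc <- pearson_matrix(const)
  expect_true(is.na(cmc$r["a", "b"]))
  expect_false(cmc$defined["a", "b"])
})

test_that("type-I error is calibrated under the Gaussian null", {
  set.seed(55)
  n <- 55; reps <- 4000
  x <- matrix(rnorm(n * reps), n)
  y <- matrix(rnorm(n * reps), n)
  r <- vapply(seq_len(reps), function(i) oracle_r(x[, i], y[, i]), numeric(1))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), n - 2)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.25)
})

test_that("trajectory clustering recovers separated groups", {
  set.seed(9)
  g1 <- matrix(rep(c(10, 14, 18), each = 5), 5) + rnorm(15, 0, 0.3)
  g2 <- matrix(rep(c(30, 50, 70), each = 5), 5) + rnorm(15, 0, 0.3)
  traj <- rbind(g1, g2)
  rownames(traj) <- sprintf("G%02d", 1:10)
  cl <- cluster_genotypes(traj, k = 2)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_equal(length(unique(cl$labels[6:10])), 1)
  expect_true(cl$labels[1] != cl$labels[6])
  expect_equal(length(cl$tree$height), 9)

  # k = n gives singletons; duplicated rows share a label
  cln <- cluster_genotypes(traj, k = 10)
  expect_equal(sort(unname(cln$labels)), 1:10)
  dup <- traj[c(1, 1, 6), ]
  rownames(dup) <- c("A", "B", "C")
  cld <- cluster_genotypes(dup, k = 2)
  expect_equal(cld$labels[["A"]], cld$labels[["B"]])
  expect_error(cluster_genotypes(traj, k = 11),
               class = "panicler_validation_error")
})

test_that("cluster partitions are invariant under row permutation", {
  set.seed(12)
  traj <- matrix(rnorm(36, rep(c(0, 8, 20), each = 12)), 12)
  rownames(traj) <- sprintf("G%02d", 1:12)
  cl1 <- cluster_genotypes(traj, k = 3)$labels
  perm <- sample(12)
  cl2 <- cluster_genotypes(traj[perm, ], k = 3)$labels[rownames(traj)]
  # same partition up to label renaming
  expect_equal(length(unique(paste(cl1, cl2))), 3)
})

test_that("missing trajectory cells are imputed and flagged", {
  traj <- matrix(c(1, 2, 3, 10, NA, 14), 2, byrow = TRUE)
  rownames(traj) <- c("A", "B")
  cl <- cluster_genotypes(traj, k = 2)
  expect_true(cl$imputed)
  expect_equal(sort(unname(cl$labels)), 1:2)
})

test_that("letter displays separate distant groups, join identical ones", {
  set.seed(33)
  a <- rnorm(20, 0); b <- rnorm(20, 10)
  gc <- group_compare(list(low = a, high = b))
  expect_true(gc$letters[["low"]] != gc$letters[["high"]])

  gc2 <- group_compare(list(x = a, y = a))
  expect_equal(gc2$letters[["x"]], gc2$letters[["y"]])

  c3 <- rnorm(20, 0)
  gc3 <- group_compare(list(g1 = a, g2 = c3, g3 = b))
  expect_equal(gc3$letters[["g1"]], gc3$letters[["g2"]])
  expect_false(any(strsplit(gc3$letters[["g3"]], "")[[1]] %in%
                     strsplit(gc3$letters[["g1"]], "")[[1]]))
})

test_that("letter display is consistent with the significance matrix", {
  set.seed(41)
  for (rep_i in 1:5) {
    k <- sample(3:6, 1)
    vals <- lapply(seq_len(k), function(i) rnorm(12, sample(0:3, 1) * 2))
    names(vals) <- paste0("g", seq_len(k))
    gc <- group_compare(vals, alpha = 0.1)
    share <- function(i, j) {
      any(strsplit(gc$letters[i], "")[[1]] %in%
            strsplit(gc$letters[j], "")[[1]])
    }
    for (e in seq_len(nrow(gc$pairwise))) {
      i <- gc$pairwise$group_i[e]; j <- gc$pairwise$group_j[e]
      if (gc$pairwise$significant[e]) {
        expect_false(share(i, j))
      } else {
        expect_true(share(i, j))
      }
    }
  }
})

test_that("degenerate zero-variance comparisons are flagged", {
  gc <- group_compare(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_true(gc$degenerate)
  expect_equal(gc$letters[["a"]], gc$letters[["b"]])
  gc2 <- group_compare(list(a = c(1, 1, 1), b = c(2, 2, 2)))
  expect_true(gc2$degenerate)
  expect_false(gc2$letters[["a"]] == gc2$letters[["b"]])
})

test_that("Student vs Welch flag changes the test for unequal variances", {
  set.seed(77)
  a <- rnorm(10, 0, 1); b <- rnorm(40, 0.8, 6)
  ps <- group_compare(list(a = a, b = b))$pairwise$p
  pw <- group_compare(list(a = a, b = b), var_equal = FALSE)$pairwise$p
  expect_equal(ps, t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(pw, t.test(a, b)$p.value)
})

test_that("BH adjustment only rescales p-values, never r", {
  set.seed(99)
  tab <- as.data.frame(matrix(rnorm(200), 40))
  raw <- pearson_matrix(tab)
  adj <- pearson_matrix(tab, adjust = "BH")
  expect_identical(adj$r, raw$r)
  ut <- upper.tri(raw$p)
  expect_equal(adj$p[ut], p.adjust(raw$p[ut], "BH"))
})
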