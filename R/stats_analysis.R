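#' Pairwise Pearson correlation matrix over trait columns
#'
#' For every trait pair, rows with a missing value in either trait are
#' dropped (pairwise-complete), the Pearson coefficient `r` is computed,
#' and its two-sided p-value follows from `t = r * sqrt((n - 2) / (1 -
#' r^2))` on `n - 2` degrees of freedom. A constant trait leaves `r`
#' undefined; such entries are `NA` and flagged in the `defined` matrix
#' rather than propagated as errors.
#'
#' @param table a trait `data.frame` (e.g. a trait table).
#' @param traits character vector of numeric column names; default all
#'   numeric non-key columns.
#' @param adjust `"none"` (default: raw p-values) or `"BH"` for a
#'   Benjamini-Hochberg correction over the distinct trait pairs.
#' @return an object of class `correlation_matrix`: list of matrices `r`,
#'   `p`, `n` (complete-pair counts) and logical `defined`.
#' @export
pearson_matrix <- function(table, traits = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(traits)) {
    traits <- names(table)[vapply(table, is.numeric, logical(1))]
    traits <- setdiff(traits, trait_table_keys)
  }
  miss <- setdiff(traits, names(table))
  assert_that(length(miss) == 0, "panicler_validation_error",
              "trait column(s) not in table: %s", paste(miss, collapse = ", "))
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  n <- matrix(0L, k, k, dimnames = list(traits, traits))
  defined <- matrix(TRUE, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- table[[traits[i]]]; y <- table[[traits[j]]]
      ok <- is.finite(x) & is.finite(y)
      m <- sum(ok)
      n[i, j] <- n[j, i] <- m
      assert_that(m >= 3, "panicler_validation_error",
                  "fewer than 3 complete pairs for (%s, %s)",
                  traits[i], traits[j])
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        defined[i, j] <- defined[j, i] <- FALSE
        next
      }
      rij <- cor(x[ok], y[ok])
      r[i, j] <- r[j, i] <- rij
      tt <- rij * sqrt((m - 2) / max(1 - rij^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df = m - 2)
    }
  }
  if (adjust == "BH" && k > 1) {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, n = n, defined = defined),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("correlation_matrix (Pearson r):\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Write a correlation matrix as long-format CSV
#' @param cm a `correlation_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(cm, path) {
  traits <- rownames(cm$r)
  idx <- which(upper.tri(cm$r, diag = FALSE), arr.ind = TRUE)
  df <- data.frame(trait_i = traits[idx[, 1]], trait_j = traits[idx[, 2]],
                   r = cm$r[idx], p = cm$p[idx], n = cm$n[idx])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Hierarchical clustering of genotype voxel-count trajectories
#'
#' Genotypes are clustered on their weekly voxel-count vectors (weeks as
#' columns) by agglomerative clustering, Euclidean distance with Ward
#' linkage by default, and the tree is cut at `k` clusters. Missing cells
#' are imputed by the genotype's row mean and flagged.
#'
#' @param trajectories numeric matrix, genotypes x weeks, with genotype
#'   row names.
#' @param k number of clusters to cut (the weekly growth study used 4).
#' @param method linkage method for [stats::hclust()].
#' @param metric distance metric for [stats::dist()].
#' @return an object of class `cluster_result`: list with `labels` (named
#'   integer vector in `1..k`), `tree` (the `hclust` object), `k`, and
#'   `imputed` (logical: any cell imputed).
#' @export
cluster_genotypes <- function(trajectories, k = 4, method = "ward.D2",
                              metric = "euclidean") {
  trajectories <- as.matrix(trajectories)
  ng <- nrow(trajectories)
  assert_that(is_count(k) && k <= ng, "panicler_validation_error",
              "k = %s exceeds the %d genotypes", format(k), ng)
  imputed <- FALSE
  if (anyNA(trajectories)) {
    imputed <- TRUE
    for (i in seq_len(ng)) {
      nas <- is.na(trajectories[i, ])
      assert_that(!all(nas), "panicler_validation_error",
                  "genotype row %d has no observed weeks", i)
      trajectories[i, nas] <- mean(trajectories[i, !nas])
    }
  }
  tree <- hclust(dist(trajectories, method = metric), method = method)
  labels <- cutree(tree, k = k)
  structure(list(labels = labels, tree = tree, k = as.integer(k),
                 imputed = imputed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d genotypes in %d clusters\n",
              length(x$labels), x$k))
  print(split(names(x$labels), x$labels))
  invisible(x)
}

# Compact letter display by insert-and-absorb over a logical significance
# matrix (TRUE = significantly different).
letter_display <- function(signif_mat) {
  groups <- rownames(signif_mat)
  n <- length(groups)
  # columns of `letters_mat` are letter classes; entry TRUE = group carries it
  letters_mat <- matrix(TRUE, n, 1)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!signif_mat[i, j]) next
      viol <- which(letters_mat[i, ] & letters_mat[j, ])
      for (v in viol) {
        col <- letters_mat[, v]
        # duplicate the class, remove i from one copy and j from the other
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        letters_mat <- cbind(letters_mat[, -v, drop = FALSE], a, b)
        # absorb columns contained in another column
        keep <- rep(TRUE, ncol(letters_mat))
        for (c1 in seq_len(ncol(letters_mat))) {
          for (c2 in seq_len(ncol(letters_mat))) {
            if (c1 != c2 && keep[c1] && keep[c2] &&
                all(letters_mat[, c1] | !letters_mat[, c2]) &&
                !identical(letters_mat[, c1], letters_mat[, c2]))
              keep[c2] <- FALSE
          }
        }
        letters_mat <- letters_mat[, keep, drop = FALSE]
      }
    }
  }
  ord <- order(apply(letters_mat, 2, function(cc) which(cc)[1]))
  letters_mat <- letters_mat[, ord, drop = FALSE]
  out <- apply(letters_mat, 1, function(row) paste(letters[which(row)],
                                                   collapse = ""))
  names(out) <- groups
  out
}

#' Pairwise group comparison with a compact letter display
#'
#' All pairwise two-sample t-tests between groups (classical equal-variance
#' Student's t by default, Welch by flag), followed by an insert-and-absorb
#' compact letter display: groups sharing a letter are not significantly
#' different at `alpha`. Raw p-values are used (no multiple-testing
#' correction) unless `adjust = "BH"`.
#'
#' @param values list of numeric vectors, one per group (named), or a
#'   numeric vector with `groups` giving group membership.
#' @param groups optional grouping factor when `values` is a vector.
#' @param alpha significance level (default 0.1).
#' @param var_equal classical Student's t (`TRUE`, default) or Welch.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return an object of class `group_compare`: list with `letters` (named
#'   character vector), `pairwise` (`data.frame` of group pairs and
#'   p-values), `means`, and `degenerate` (logical: some pair had zero
#'   variance in both groups and was flagged).
#' @export
group_compare <- function(values, groups = NULL, alpha = 0.1,
                          var_equal = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.list(values)) {
    assert_that(!is.null(groups), "panicler_validation_error",
                "groups required when values is a vector")
    values <- split(values, groups)
  }
  g <- length(values)
  assert_that(g >= 2, "panicler_validation_error", "need at least 2 groups")
  assert_that(all(lengths(values) >= 2), "panicler_validation_error",
              "each group needs at least 2 samples")
  gn <- names(values)
  if (is.null(gn)) gn <- paste0("g", seq_len(g))
  pairs <- which(upper.tri(matrix(0, g, g)), arr.ind = TRUE)
  pv <- numeric(nrow(pairs))
  degenerate <- FALSE
  for (e in seq_len(nrow(pairs))) {
    a <- values[[pairs[e, 1]]]; b <- values[[pairs[e, 2]]]
    if (var(a) == 0 && var(b) == 0) {
      degenerate <- TRUE
      pv[e] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      pv[e] <- t.test(a, b, var.equal = var_equal)$p.value
    }
  }
  if (adjust == "BH") pv <- stats::p.adjust(pv, "BH")
  sig <- matrix(FALSE, g, g, dimnames = list(gn, gn))
  sig[pairs] <- pv < alpha
  sig <- sig | t(sig)
  structure(list(
    letters = letter_display(sig),
    pairwise = data.frame(group_i = gn[pairs[, 1]], group_j = gn[pairs[, 2]],
                          p = pv, significant = pv < alpha),
    means = vapply(values, mean, numeric(1)),
    degenerate = degenerate),
    class = "group_compare")
}

#' @export
print.group_compare <- function(x, ...) {
  df <- data.frame(group = names(x$letters), mean = signif(x$means, 5),
                   letters = x$letters)
  rownames(df) <- NULL
  print(df)
  invisible(x)
}
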