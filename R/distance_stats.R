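#' Pairwise divergence-time matrix from a host tree or table
#'
#' From an ultrametric tree, the divergence time of a pair is half the
#' patristic distance (the height of their most recent common ancestor).
#' Trees whose tip-height spread exceeds 1% of tree depth trigger a warning
#' but are still processed the same way. A precomputed pairwise table is
#' validated (symmetry, zero diagonal) and passed through.
#'
#' @param tree An \code{ape::phylo} tree, or NULL when \code{matrix} given.
#' @param matrix A labeled square matrix of divergence times, used instead of
#'   a tree.
#' @return Labeled symmetric matrix of divergence times.
#' @export
divergence_matrix <- function(tree = NULL, matrix = NULL) {
  if (is.null(tree) == is.null(matrix)) stop("supply exactly one of tree or matrix")
  if (!is.null(matrix)) return(validate_distance_matrix(matrix))
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (max(depths) > 0 && diff(range(depths)) > 0.01 * max(depths)) {
    warning("tree is not ultrametric (tip-height spread > 1% of depth); ",
            "patristic distance / 2 may not equal divergence time")
  }
  m <- ape::cophenetic.phylo(tree) / 2
  validate_distance_matrix(m)
}

# align two labeled distance matrices on their common labels (sorted for
# determinism); partial overlap is reduced to the intersection, not an error,
# because host trees rarely match sample sheets exactly
align_matrices <- function(d1, d2) {
  common <- intersect(rownames(d1), rownames(d2))
  if (length(common) < 4) stop("fewer than 4 shared labels between matrices")
  dropped <- length(union(rownames(d1), rownames(d2))) - length(common)
  common <- sort(common)
  list(d1 = d1[common, common], d2 = d2[common, common],
       labels = common, n_dropped = dropped)
}

#' Mantel test between two distance matrices
#'
#' Correlates the strict lower triangles of two labeled distance matrices
#' (Pearson by default, Spearman optionally) and assesses significance by
#' seeded joint row/column permutation of the second matrix. The p-value
#' follows the (b + 1) / (m + 1) convention and can never be 0. Matrices with
#' partially overlapping labels are reduced to their intersection, reported
#' in the result.
#'
#' @param d1,d2 Labeled symmetric matrices (e.g. host divergence times and
#'   microbiota UniFrac distances).
#' @param n_perm Number of permutations (default 999).
#' @param seed Mandatory integer seed.
#' @param method "pearson" (default) or "spearman".
#' @param alternative "two.sided" (default) or "greater".
#' @return List of class \code{mantel_result}: r, p, n_perm, n (matrix side),
#'   method, alternative, n_dropped labels.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed, method = c("pearson", "spearman"),
                        alternative = c("two.sided", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("seed is required")
  al <- align_matrices(d1, d2)
  n <- length(al$labels)
  lt <- lower.tri(al$d1)
  v1 <- al$d1[lt]
  if (stats::sd(v1) == 0 || stats::sd(al$d2[lt]) == 0) {
    stop("constant distances: Mantel correlation undefined")
  }
  if (method == "spearman") v1 <- rank(v1)
  corr <- function(m2) {
    v2 <- m2[lt]
    if (method == "spearman") v2 <- rank(v2)
    stats::cor(v1, v2)
  }
  r_obs <- corr(al$d2)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    corr(al$d2[p, p])
  }, numeric(1)))
  b <- if (alternative == "two.sided") {
    sum(abs(r_perm) >= abs(r_obs))
  } else sum(r_perm >= r_obs)
  structure(list(r = r_obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm,
                 n = n, method = method, alternative = alternative,
                 n_dropped = al$n_dropped),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s, n = %d, %d permutations): r = %.4g, p = %.4g\n",
              x$method, x$alternative, x$n, x$n_perm, x$r, x$p))
  if (x$n_dropped > 0) cat("  (", x$n_dropped, " unmatched labels dropped)\n", sep = "")
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: partitions the
#' total sum of squared distances into among- and within-group components and
#' forms the pseudo-F statistic
#' \deqn{F = (SS_A / (k - 1)) / (SS_W / (n - k)),}
#' with significance from seeded permutation of group labels (one-sided,
#' upper tail, (b + 1) / (m + 1)).
#'
#' @param d Labeled symmetric distance matrix.
#' @param grouping Named character/factor vector (names = labels of d), or an
#'   unnamed vector in d's label order.
#' @param n_perm Number of permutations (default 999, the conventional
#'   setting).
#' @param seed Mandatory integer seed.
#' @return List of class \code{permanova_result}: pseudo_F, p, n_perm,
#'   group_sizes, df.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed) {
  if (missing(seed)) stop("seed is required")
  d <- validate_distance_matrix(d)
  if (!is.null(names(grouping))) {
    common <- intersect(rownames(d), names(grouping))
    if (length(common) < 4) stop("fewer than 4 labeled samples shared with grouping")
    d <- d[common, common]
    grouping <- grouping[common]
  } else if (length(grouping) != nrow(d)) {
    stop("unnamed grouping must match the matrix dimension")
  }
  g <- as.factor(as.character(grouping))
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members (singletons: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  n <- nrow(d)
  k <- length(sizes)
  d2 <- d^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  pseudo_f <- function(g) {
    ss_within <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
    ss_among <- ss_total - ss_within
    (ss_among / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- pseudo_f(g)
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pseudo_f(g[sample.int(n)])
  }, numeric(1)))
  structure(list(pseudo_F = f_obs, p = (sum(f_perm >= f_obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, group_sizes = as.integer(sizes),
                 df = c(k - 1, n - k)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d groups, df = %d/%d, %d permutations): pseudo-F = %.4g, p = %.4g\n",
              length(x$group_sizes), x$df[1], x$df[2], x$n_perm, x$pseudo_F, x$p))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, order
#' preserving. Thin wrapper over \code{stats::p.adjust(method = "BH")} so the
#' whole test battery shares one entry point.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 df, via
#' \code{stats::kruskal.test}.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector, same length.
#' @return List: H, p, df.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (length(unique(values)) < 2) stop("all values identical: test undefined")
  kt <- stats::kruskal.test(values, as.factor(as.character(groups)))
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with the t-approximation p-value
#' (ties allowed), via \code{stats::cor.test}.
#'
#' @param x,y Numeric vectors, length >= 4.
#' @return List: rho, p, n.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
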