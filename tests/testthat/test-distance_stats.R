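test_that("divergence matrix halves patristic distance on ultrametric trees", {
  two <- ape::read.tree(text = "(A:10,B:10);")
  d <- divergence_matrix(tree = two)
  expect_equal(d["A", "B"], 10)
  # 3-tip caterpillar with known node heights
  cat3 <- ape::read.tree(text = "((A:2,B:2):3,C:5);")
  d3 <- divergence_matrix(tree = cat3)
  expect_equal(d3["A", "B"], 2)
  expect_equal(d3["A", "C"], 5)
  expect_equal(d3["B", "C"], 5)
  nonultra <- ape::read.tree(text = "((A:1,B:4):1,C:5);")
  expect_warning(divergence_matrix(tree = nonultra), "not ultrametric")
  # matrix pass-through round-trips via TSV
  p <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d3, p)
  expect_equal(read_distance_matrix(p), d3)
})

test_that("mantel r is exact on identity and joint-relabel invariant", {
  set.seed(2)
  d1 <- labeled_dist(matrix(rnorm(20), 10))
  res <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  d2 <- labeled_dist(matrix(rnorm(20), 10))
  r0 <- mantel_test(d1, d2, n_perm = 99, seed = 1)$r
  perm <- sample(rownames(d1))
  r1 <- mantel_test(d1[perm, perm], d2[perm, perm], n_perm = 99, seed = 1)$r
  expect_equal(r0, r1)
  # vegan agreement on the statistic (independent implementation)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(r0, unname(vg$statistic), tolerance = 1e-12)
})

test_that("mantel p honors the (b+1)/(m+1) convention and label intersection", {
  set.seed(4)
  d1 <- labeled_dist(matrix(rnorm(12), 6))
  d2 <- labeled_dist(matrix(rnorm(12), 6))
  res <- mantel_test(d1, d2, n_perm = 99, seed = 7)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
  # partial label overlap reduces to the intersection with a report
  d2b <- d2
  rownames(d2b) <- colnames(d2b) <- c(rownames(d2)[1:5], "zz")
  res2 <- mantel_test(d1, d2b, n_perm = 99, seed = 7)
  expect_equal(res2$n, 5)
  expect_equal(res2$n_dropped, 2)
  expect_error(mantel_test(d1 * 0, d2, n_perm = 99, seed = 1), "constant")
  expect_error(mantel_test(d1, d2, n_perm = 99), "seed")
})

test_that("spearman-method mantel ranks both triangles", {
  set.seed(8)
  d1 <- labeled_dist(matrix(rnorm(16), 8))
  d2 <- labeled_dist(matrix(rnorm(16), 8))
  res <- mantel_test(d1, d2, n_perm = 99, seed = 2, method = "spearman")
  lt <- lower.tri(d1)
  expect_equal(res$r, cor(rank(d1[lt]), rank(d2[lt])))
})

test_that("permanova pseudo-F matches the direct SS decomposition", {
  # 6-sample toy: hand-computable sum-of-squares partition
  set.seed(6)
  x <- c(0, 0.1, 0.2, 5, 5.1, 5.2)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- setNames(rep(c("A", "B"), each = 3), rownames(d))
  res <- permanova(d, g, n_perm = 99, seed = 3)
  d2 <- d^2
  ss_total <- sum(d2[lower.tri(d2)]) / 6
  ss_w <- sum(d2[1:3, 1:3][lower.tri(d2[1:3, 1:3])]) / 3 +
    sum(d2[4:6, 4:6][lower.tri(d2[4:6, 4:6])]) / 3
  f_hand <- ((ss_total - ss_w) / 1) / (ss_w / 4)
  expect_equal(res$pseudo_F, f_hand)
  # with 3+3 samples many relabelings reproduce the same partition, so the
  # attainable minimum p is ~0.11, not the raw permutation floor
  expect_lte(res$p, 0.15)
  # larger perfectly separated clusters do reach the permutation floor
  x2 <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1))
  dbig <- labeled_dist(x2)
  gbig <- setNames(rep(c("A", "B"), each = 8), rownames(dbig))
  expect_equal(permanova(dbig, gbig, n_perm = 99, seed = 5)$p, 1 / 100)
  expect_error(permanova(d, setNames(c("A", "B", "C", "C", "C", "C"), rownames(d)),
                         99, seed = 1), "singleton")
  skip_if_not_installed("vegan")
  vg <- vegan::adonis2(as.dist(d) ~ grp, data = data.frame(grp = g),
                       permutations = 99)
  expect_equal(res$pseudo_F, vg$F[1], tolerance = 1e-12)
})

test_that("permanova p is approximately uniform under exchangeable labels", {
  set.seed(31)
  pv <- vapply(1:60, function(i) {
    d <- labeled_dist(matrix(rnorm(24), 12))
    g <- setNames(rep(c("A", "B"), each = 6), rownames(d))
    permanova(d, g, n_perm = 99, seed = 100 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # order preserving
  p <- c(0.9, 0.001, 0.04)
  expect_equal(order(bh_fdr(p)), order(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("kruskal-wallis H matches rank arithmetic and rank invariance", {
  res <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$H, 2.4)  # 12/(4*5) * (9/2 + 49/2) - 15
  expect_equal(res$df, 1)
  # identical groups -> H = 0
  expect_equal(kruskal_wallis(c(1, 2, 1, 2), c("a", "a", "b", "b"))$H, 0)
  # invariance under a monotone transform
  v <- c(3, 1, 4, 1, 5, 9, 2, 6); g <- rep(c("x", "y"), 4)
  expect_equal(kruskal_wallis(v, g)$H, kruskal_wallis(exp(v), g)$H)
  expect_error(kruskal_wallis(rep(1, 4), c("a", "a", "b", "b")), "identical")
})

test_that("spearman correlation handles monotone and tied inputs", {
  expect_equal(spearman_corr(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_corr(1:6, -(1:6))$rho, -1)
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 5)
  expect_equal(spearman_corr(x, y)$rho, cor(rank(x), rank(y)))
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:3, 1:3), "at least 4")
})
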