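test_that("rarefaction hits depth exactly, drops shallow samples, is seeded", {
  m <- matrix(c(50, 50, 0,
                3000, 1500, 500,
                2, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("f1", "f2", "f3")))
  ft <- feature_table(m)
  r <- rarefy_counts(ft, 10, seed = 1)
  expect_setequal(ft_samples(r), c("a", "b"))  # c has 4 < 10 reads
  expect_true(all(sample_totals(r) == 10))
  # identity at depth == total
  keep <- rarefy_counts(ft["c", ], 4, seed = 1)
  expect_equal(unclass(keep)["c", ], unclass(ft)["c", ])
  # boundary: depth of total + 1 drops the sample
  expect_equal(nrow(rarefy_counts(ft["c", ], 5, seed = 1)), 0)
  # determinism
  expect_identical(unclass(rarefy_counts(ft, 10, seed = 42)),
                   unclass(rarefy_counts(ft, 10, seed = 42)))
})

test_that("rarefaction is measure-preserving in expectation", {
  ft <- feature_table(matrix(c(50, 50), 1, 2,
                             dimnames = list("s", c("A", "B"))))
  draws <- vapply(1:1000, function(i)
    unclass(rarefy_counts(ft, 10, seed = i))["s", "A"], numeric(1))
  # hypergeometric: mean 5, var 10 * .5 * .5 * (90/99)
  sd_mean <- sqrt(10 * 0.25 * 90 / 99 / 1000)
  expect_lt(abs(mean(draws) - 5), 3 * sd_mean)
})

test_that("chao1 handles singleton/doubleton structure", {
  expect_equal(chao1(c(2, 3, 4)), 3)            # no singletons
  expect_equal(chao1(c(1, 1, 2)), 3.5)          # 3 + 2*1/(2*2)
  expect_equal(chao1(c(1, 1, 2, 0, 0)), 3.5)    # zero counts ignored
  expect_equal(chao1(numeric(0)), 0)
  expect_equal(chao1(c(0, 0)), 0)
  # classic form diverges when F2 = 0 with singletons present
  expect_identical(chao1(c(1, 3), bias_corrected = FALSE), Inf)
  expect_equal(chao1(c(1, 1, 2), bias_corrected = FALSE), 3 + 4 / 2)
})

test_that("shannon matches hand values and is maximal at uniformity", {
  expect_equal(shannon(c(1, 1)), log(2))
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_equal(shannon(c(1, 1), base = 2), 1)
  expect_error(shannon(c(0, 0)), "all-zero")
  # property: uniform composition maximizes entropy at fixed richness
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    random <- as.numeric(rmultinom(1, 1000, runif(k)))
    expect_lte(shannon(random), shannon(rep(1, k)) + 1e-12)
  }
})

test_that("faith_pd sums covered branch lengths", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
  expect_equal(faith_pd(c("A", "B"), tree), 3)          # two tips + stem
  expect_equal(faith_pd(c("A", "B", "C", "D"), tree), 6)  # whole tree
  expect_equal(faith_pd("A", tree), 2)                  # root-to-tip path
  expect_warning(v <- faith_pd(c("A", "zzz"), tree), "not in tree")
  expect_equal(v, 2)
  expect_error(suppressWarnings(faith_pd("zzz", tree)), "no present feature")
})

test_that("gamma partition computes exclusive fractions per group", {
  sets <- list(g1 = c("a", "b", "c"), g2 = c("c", "d"), g3 = c("e"))
  res <- gamma_partition(sets)
  expect_equal(res$total, c(3, 2, 1))
  expect_equal(res$exclusive, c(2, 1, 1))
  expect_equal(res$pct_exclusive, c(66.7, 50, 100))
  # disjoint groups are 100% exclusive; identical groups 0%
  expect_equal(gamma_partition(list(x = "a", y = "b"))$pct_exclusive, c(100, 100))
  expect_equal(gamma_partition(list(x = c("a", "b"), y = c("a", "b")))$pct_exclusive,
               c(0, 0))
  empty <- gamma_partition(list(x = character(0), y = "a"))
  expect_true(is.na(empty$pct_exclusive[1]))
})

test_that("accumulation curve equals brute-force union sizes", {
  set.seed(9)
  sets <- lapply(1:5, function(i) sample(letters, sample(3:10, 1)))
  names(sets) <- paste0("u", 1:5)
  curve <- accumulation_curve(sets)
  oracle <- vapply(1:5, function(k)
    length(unique(unlist(sets[1:k]))), numeric(1))
  expect_equal(curve$cumulative, oracle)
  expect_true(all(diff(curve$cumulative) >= 0))
  # disjoint sets of equal size give a linear curve; identical sets a flat one
  dis <- list(a = c("1", "2"), b = c("3", "4"), c = c("5", "6"))
  expect_equal(accumulation_curve(dis)$cumulative, c(2, 4, 6))
  same <- list(a = c("x", "y"), b = c("x", "y"))
  expect_equal(accumulation_curve(same)$cumulative, c(2, 2))
  # final point is ordering-invariant
  perm <- accumulation_curve(sets[c(3, 1, 5, 2, 4)])
  expect_equal(perm$cumulative[5], curve$cumulative[5])
  # permutation mode: band brackets the mean, deterministic under a seed
  rc1 <- accumulation_curve(sets, "random", n_perm = 99, seed = 3)
  rc2 <- accumulation_curve(sets, "random", n_perm = 99, seed = 3)
  expect_equal(rc1$mean, rc2$mean)
  expect_true(all(rc1$lo <= rc1$mean & rc1$mean <= rc1$hi))
  expect_equal(rc1$mean[5], curve$cumulative[5])  # full union regardless of order
})

test_that("saturation fit recovers exact Michaelis-Menten parameters", {
  s <- 1:25
  f <- fit_saturation(s, 100 * s / (10 + s))
  expect_equal(f$Vmax, 100, tolerance = 1e-6)
  expect_equal(f$Km, 10, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_saturation(1:2, c(1, 2)), ">= 3")
})

test_that("feature sets by group pool presence across samples", {
  m <- matrix(c(1, 0, 2,
                0, 0, 1,
                0, 3, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("f1", "f2", "f3")))
  ft <- feature_table(m)
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     sp = c("A", "A", "B"))
  sets <- feature_sets_by_group(ft, meta, "sp")
  expect_setequal(sets$A, c("f1", "f3"))
  expect_setequal(sets$B, "f2")
})
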