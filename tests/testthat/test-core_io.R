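test_that("feature_table validates counts and identifiers", {
  expect_equal(sum(toy_table()), 15)
  m <- matrix(c(1, -2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(feature_table(m), "negative")
  m2 <- matrix(c(1, 2.5, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(feature_table(m2), "non-integer")
  # floats within 1e-6 of an integer are coerced
  m3 <- matrix(c(1 + 1e-8, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(unclass(feature_table(m3))[1, 1], 1)
  m4 <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(feature_table(m4), "duplicate sample")
})

test_that("TSV round-trip is lossless for counts, identifiers and order", {
  ft <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(unclass(back), unclass(ft))
  expect_identical(ft_samples(back), c("s1", "s2"))
  expect_identical(ft_features(back), c("f1", "f2", "f3"))
})

test_that("TSV reader handles both orientations and rejects bad counts", {
  # samples-as-rows (no sentinel)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tf1\tf2", "s1\t1\t2", "s2\t3\t4"), p1)
  t1 <- read_feature_table(p1)
  expect_equal(unname(sample_totals(t1)), c(3, 7))
  # features-as-rows with the #OTU ID sentinel and a leading comment
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# Constructed from biom file", "#OTU ID\ts1\ts2",
               "f1\t1\t3", "f2\t2\t4"), p2)
  t2 <- read_feature_table(p2)
  expect_equal(unclass(t2), unclass(t1)[, c("f1", "f2")], ignore_attr = FALSE)
  # negative count rejected
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tf1", "s1\t-4"), p3)
  expect_error(read_feature_table(p3), "negative")
})

test_that("BIOM input arrives in samples-by-features orientation", {
  skip_if_not_installed("biomformat")
  m <- matrix(1:6, 3, 2, dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  p <- withr::local_tempfile(fileext = ".biom")
  suppressWarnings(biomformat::write_biom(biomformat::make_biom(m), p))
  ft <- read_feature_table(p)
  expect_identical(ft_samples(ft), c("s1", "s2"))
  expect_equal(unclass(ft), t(m), ignore_attr = TRUE)
  expect_equal(unname(sample_totals(ft)), c(6, 15))
})

test_that("taxon filtering removes or keeps lineages case-insensitively", {
  ft <- toy_table()
  tax <- toy_taxonomy()
  filtered <- filter_features_by_taxon(ft, tax, "chloroplast")
  expect_identical(ft_features(filtered), c("f1", "f3"))
  # conservation: filtered totals = totals minus removed-feature reads
  expect_equal(sample_totals(ft) - sample_totals(filtered),
               unclass(ft)[, "f2"])
  # idempotent
  expect_identical(unclass(filter_features_by_taxon(filtered, tax, "chloroplast")),
                   unclass(filtered))
  # no match leaves the table unchanged
  expect_identical(unclass(filter_features_by_taxon(ft, tax, "archaea")),
                   unclass(ft))
  # keep = TRUE retains only matches
  kept <- filter_features_by_taxon(ft, tax, "g__Bacillus", keep = TRUE)
  expect_identical(ft_features(kept), "f1")
  expect_error(filter_features_by_taxon(ft, tax, character(0)), "non-empty")
})

test_that("sample totals are exact row sums, invariant to feature order", {
  ft <- toy_table()
  expect_equal(sample_totals(ft), c(s1 = 3, s2 = 12))
  perm <- ft[, c(3, 1, 2)]
  expect_equal(sample_totals(perm), sample_totals(ft))
  empty <- feature_table(matrix(0, 1, 2, dimnames = list("s", c("a", "b"))))
  expect_equal(unname(sample_totals(empty)), 0)
})

test_that("taxon prevalence counts matching samples per group", {
  m <- matrix(c(5, 5,
                0, 10,
                2, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("bac", "other")))
  ft <- feature_table(m)
  tax <- c(bac = "g__Bacillus", other = "g__Vibrio")
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     site = c("gill", "gill", "gill", "skin"))
  expect_warning(res <- taxon_prevalence(ft, tax, "g__Bacillus", meta, "site"),
                 "skin")
  expect_equal(res$prevalence, 2 / 3)
  expect_equal(res$mean_rel_abundance, mean(c(0.5, 0, 0.2)))
  # all matching -> prevalence 1; none matching -> 0
  expect_equal(suppressWarnings(
    taxon_prevalence(ft, tax, "g__", meta, "site"))$prevalence, 1)
  expect_equal(suppressWarnings(
    taxon_prevalence(ft, tax, "g__Absent", meta, "site"))$prevalence, 0)
})

test_that("metadata reader handles QIIME2 dialect with a types row", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample-id\trole\ttissue_mass", "#q2:types\tcategorical\tnumeric",
               "s1\tbiological\t0.2", "s2\tpositive_control\t0.1"), p)
  md <- read_metadata(p)
  expect_identical(md$sample_id, c("s1", "s2"))
  expect_type(md$tissue_mass, "double")
})

test_that("distance matrix IO validates symmetry and round-trips", {
  m <- labeled_dist(matrix(rnorm(12, 0, 1), 4))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(m, p)
  back <- read_distance_matrix(p)
  expect_equal(back, m, tolerance = 1e-12)
  bad <- m; bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(validate_distance_matrix(bad), "asymmetric")
  bad2 <- m; diag(bad2) <- 0.5
  expect_error(validate_distance_matrix(bad2), "diagonal")
})
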