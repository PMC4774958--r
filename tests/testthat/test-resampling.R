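test_that("exact Mann-Whitney matches the brute-force enumeration oracle", {
  # complete separation of two samples of five: 2 extreme assignments of 252
  expect_equal(exact_mann_whitney(1:5, 6:10), 2 / 252)
  expect_equal(oracle_mann_whitney(1:5, 6:10), 2 / 252)
  # identical pooled multisets: every assignment at least as extreme
  expect_equal(exact_mann_whitney(1:5, 1:5), 1)
  # U = 5 configuration, frozen from the oracle
  expect_equal(exact_mann_whitney(c(1, 2, 3, 4, 10), c(5, 6, 7, 8, 9)),
               38 / 252)
  expect_equal(oracle_mann_whitney(c(1, 2, 3, 4, 10), c(5, 6, 7, 8, 9)),
               38 / 252)

  set.seed(17)
  for (i in 1:500) {
    a <- rnorm(5)
    b <- rnorm(5, mean = runif(1, 0, 2))
    if (i %% 3 == 0) { a <- round(a); b <- round(b) } # force ties
    expect_identical(exact_mann_whitney(a, b), oracle_mann_whitney(a, b))
  }
})

test_that("exact Mann-Whitney handles unequal sizes and rejects bad input", {
  set.seed(4)
  a <- rnorm(3); b <- rnorm(7)
  expect_identical(exact_mann_whitney(a, b), oracle_mann_whitney(a, b))
  expect_error(exact_mann_whitney(c(1, NA, 3, 4, 5), 1:5), "finite")
  expect_error(exact_mann_whitney(numeric(0), 1:5), "non-empty")
  expect_error(exact_mann_whitney(1:11, 1:5), "at most 10")
})

test_that("the exact p-value is invariant under monotone transformation", {
  set.seed(23)
  for (i in 1:25) {
    a <- rnorm(5); b <- rnorm(5, 1)
    p1 <- exact_mann_whitney(a, b)
    p2 <- exact_mann_whitney(exp(a), exp(b))
    p3 <- exact_mann_whitney(2 * a + 7, 2 * b + 7)
    expect_identical(p1, p2)
    expect_identical(p1, p3)
  }
})

test_that("Monte-Carlo comparison handles the degenerate and separated cases", {
  const <- matrix(1, 5, 5)
  r <- mc_comparison(const, const, mc_settings(500, seed = 1))
  expect_equal(r$fraction_significant, 0)
  expect_identical(r$band, "ns")

  lo <- matrix(runif(25, 0, 1), 5)
  hi <- matrix(runif(25, 5, 6), 5)
  r <- mc_comparison(lo, hi, mc_settings(500, seed = 1))
  expect_equal(r$fraction_significant, 1)
  expect_identical(r$band, "***")

  expect_error(mc_comparison(list(), const), "empty|at least one")
  expect_error(mc_comparison(list(1:5, numeric(0), 1:5, 1:5, 1:5), const),
               "at least one")
})

test_that("Monte-Carlo comparisons are reproducible and respect their seed", {
  set.seed(2)
  a <- matrix(rnorm(25), 5); b <- matrix(rnorm(25, 1), 5)
  r1 <- mc_comparison(a, b, mc_settings(400, seed = 9))
  r2 <- mc_comparison(a, b, mc_settings(400, seed = 9))
  expect_identical(r1, r2)
})

test_that("fraction of significant runs grows with the group mean shift", {
  set.seed(6)
  base <- matrix(rnorm(25, sd = 1), 5)
  fr <- vapply(c(0, 1, 2, 4), function(shift) {
    g2 <- matrix(rnorm(25, mean = shift, sd = 1), 5)
    mc_comparison(base, g2, mc_settings(1000, seed = 13))$fraction_significant
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_lt(fr[1], 0.2)
  expect_gt(fr[4], 0.9)
})

test_that("significance banding follows the published thresholds, edges in the lower band", {
  expect_identical(significance_band(0.995), "***")
  expect_identical(significance_band(0.97), "**")
  expect_identical(significance_band(0.80), "*")
  expect_identical(significance_band(0.50), "ns")
  # band edges belong to the lower band ("more than" read strictly)
  expect_identical(significance_band(0.99), "**")
  expect_identical(significance_band(0.95), "*")
  expect_identical(significance_band(0.67), "ns")
  expect_identical(significance_band(c(1, 0)), c("***", "ns"))
  expect_error(significance_band(1.2), "\\[0, 1\\]")
  expect_error(significance_band(-0.1), "\\[0, 1\\]")
})

test_that("comparison schemes enumerate the study's pair counts", {
  st <- species_table()
  expect_equal(nrow(build_comparison_scheme(st, "diff_activity_all")), 24)
  expect_equal(nrow(build_comparison_scheme(st, "diff_activity_diff_size")), 16)
  expect_equal(nrow(build_comparison_scheme(st, "same_activity_diurnal")), 6)
  expect_equal(nrow(build_comparison_scheme(st, "same_activity_nocturnal")), 12)
  expect_equal(nrow(build_comparison_scheme(st, "within_species_positions")), 7)
  expect_error(build_comparison_scheme(st, "no_such_mode"))

  # brute-force check of the different-activity / different-size pairs
  pairs <- t(combn(st$species, 2))
  act <- setNames(st$activity, st$species)
  sz <- setNames(st$size_class, st$species)
  expected <- sum(act[pairs[, 1]] != act[pairs[, 2]] &
                  sz[pairs[, 1]] != sz[pairs[, 2]])
  expect_equal(expected, 8)
  sch <- build_comparison_scheme(st, "diff_activity_diff_size")
  expect_equal(nrow(unique(sch[c("species_a", "species_b")])), expected)
  # no duplicated unordered pairs x positions
  key <- with(sch, paste(pmin(species_a, species_b),
                         pmax(species_a, species_b), position))
  expect_false(any(duplicated(key)))
})

test_that("running a scheme yields one banded result per comparison", {
  d <- generate_dataset(default_parameter_table(), seed = 3)
  st <- species_table()
  sch <- build_comparison_scheme(st, "same_activity_diurnal")
  res <- run_all_comparisons(d, sch, "length_mm", mc_settings(300, seed = 3))
  expect_equal(nrow(res), 6)
  expect_true(all(res$fraction_significant >= 0 & res$fraction_significant <= 1))
  expect_identical(res$band, significance_band(res$fraction_significant))

  # results are independent of other comparisons: substream per pair id
  one <- run_all_comparisons(d, sch[3, ], "length_mm", mc_settings(300, seed = 3))
  expect_equal(one$fraction_significant, res$fraction_significant[3])

  # missing cells are reported with the offending species and position
  d2 <- d[!(d$species == "A. otus" & d$position == 0.2), ]
  sch2 <- build_comparison_scheme(st, "same_activity_nocturnal")
  expect_error(run_all_comparisons(d2, sch2, "length_mm",
                                   mc_settings(50, seed = 1)),
               "A. otus, 0.2")
})

test_that("within-species position comparisons are null when positions share a mean", {
  cfg <- default_parameter_table()
  mt <- cfg$mean_table
  # give every position the species' 0.2 mean: no positional effect at all
  for (i in seq_len(nrow(mt))) {
    mt$mean[i] <- mt$mean[mt$species == mt$species[i] &
                          mt$parameter == mt$parameter[i] &
                          mt$position == 0.2]
  }
  cfg$mean_table <- mt
  d <- generate_dataset(cfg, seed = 21)
  sch <- build_comparison_scheme(species_table(), "within_species_positions")
  res <- run_all_comparisons(d, sch, "inclination_deg",
                             mc_settings(400, seed = 21))
  expect_true(all(res$band == "ns"))
})
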