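test_that("pooled t matches hand arithmetic on the equal-groups case", {
  mat <- tiny_matrix(c(1, 2), c(1, 2))
  st <- pooled_t(mat)
  expect_equal(unname(st$z1), 0)
  expect_equal(unname(exp(st$z2)), sqrt(0.5))
})

test_that("pooled t agrees with an independent scalar implementation", {
  set.seed(42)
  m <- 25
  g1 <- matrix(rnorm(m * 4), m)
  g2 <- matrix(rnorm(m * 6, sd = 2), m)
  mat <- tiny_matrix(g1, g2)
  st <- pooled_t(mat)
  for (i in seq_len(m)) {
    ref <- pooled_t_scalar(g1[i, ], g2[i, ])
    expect_equal(unname(st$z1[i]), ref$t)
    expect_equal(unname(st$z2[i]), log(ref$se))
  }
  # the small worked case from the contract: G1 = (0,2), G2 = (-1,1)
  st2 <- pooled_t(tiny_matrix(c(0, 2), c(-1, 1)))
  ref2 <- pooled_t_scalar(c(0, 2), c(-1, 1))
  expect_equal(unname(st2$z1), ref2$t)
})

test_that("scaling both groups leaves t fixed and shifts log se", {
  set.seed(7)
  mat <- tiny_matrix(matrix(rnorm(40), 10), matrix(rnorm(40), 10))
  st <- pooled_t(mat)
  mat2 <- mat
  mat2$values <- mat$values * 3
  st2 <- pooled_t(mat2)
  expect_equal(st2$z1, st$z1)
  expect_equal(st2$z2, st$z2 + log(3))
})

test_that("swapping group labels negates t and keeps log se", {
  set.seed(8)
  mat <- tiny_matrix(matrix(rnorm(60), 10), matrix(rnorm(60), 10))
  swapped <- mat
  swapped$group <- factor(mat$group,
                          levels = rev(levels(mat$group)))
  st <- pooled_t(mat); st2 <- pooled_t(swapped)
  expect_equal(st2$z1, -st$z1)
  expect_equal(st2$z2, st$z2)
})

test_that("modified t reduces to pooled t at a0 = 0 and damps otherwise", {
  gen <- generate_scenario(scenario_config("basic", m = 300, n_per_group = 8),
                           seed = 5)
  cls <- pooled_t(gen$matrix)
  mod0 <- modified_t(gen$matrix, a0 = 0)
  expect_equal(mod0$z1, cls$z1)
  mod <- modified_t(gen$matrix)
  expect_true(all(abs(mod$z1) <= abs(cls$z1) + 1e-12))
  expect_gte(mod$a0, 0)
  # dominant offset: ordering follows |mean difference|
  big <- modified_t(gen$matrix, a0 = 1e6)
  s <- group_diff <- rowMeans(gen$matrix$values[, 1:8]) -
    rowMeans(gen$matrix$values[, 9:16])
  expect_identical(order(abs(big$z1)), order(abs(group_diff)))
  expect_error(modified_t(gen$matrix, a0_percentile = 120), "a0_percentile")
})

test_that("groups with fewer than two samples are rejected", {
  values <- matrix(rnorm(10), 5)
  mat <- structure(list(values = values,
                        group = factor(c("G1", "G2"))),
                   class = "expression_matrix")
  expect_error(pooled_t(mat), "at least 2 samples")
})

test_that("permutation null scores honor the contract", {
  gen <- generate_scenario(scenario_config("basic", m = 120, n_per_group = 6),
                           seed = 9)
  before <- gen$matrix$values
  ns <- permutation_null_scores(gen$matrix, B = 20, seed = 17)
  expect_identical(dim(ns$z1), c(120L, 20L))
  expect_identical(gen$matrix$values, before) # input never mutated
  ns2 <- permutation_null_scores(gen$matrix, B = 20, seed = 17)
  expect_identical(ns$z1, ns2$z1)
  expect_error(permutation_null_scores(gen$matrix, mode = "sign"),
               "sign permutation")
  # identity permutation reproduces the observed statistics
  id <- matrix(seq_len(12), 12, 2)
  ns_id <- permutation_null_scores(gen$matrix, B = 2, permutations = id)
  obs <- pooled_t(gen$matrix)
  expect_equal(ns_id$z1[, 1], unname(obs$z1))
  expect_equal(ns_id$z2[, 2], unname(obs$z2))
})

test_that("on all-null data permuted and observed |t| distributions agree", {
  mat <- null_matrix(m = 3000, n = 20, seed = 12)
  obs <- pooled_t(mat)
  ns <- permutation_null_scores(mat, B = 5, seed = 13)
  ks <- suppressWarnings(
    stats::ks.test(abs(obs$z1), abs(as.vector(ns$z1)))$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("modified-flavor nulls recompute or freeze a0 as requested", {
  gen <- generate_scenario(scenario_config("basic", m = 200, n_per_group = 6),
                           seed = 19)
  a0_obs <- modified_t(gen$matrix)$a0
  froz <- permutation_null_scores(gen$matrix, B = 3, flavor = "modified",
                                  freeze_a0 = TRUE, seed = 2)
  expect_true(all(froz$a0 == a0_obs))
  rec <- permutation_null_scores(gen$matrix, B = 3, flavor = "modified",
                                 freeze_a0 = FALSE, seed = 2)
  expect_false(all(rec$a0 == a0_obs))
})

test_that("statistics export as TSV with the documented columns", {
  mat <- null_matrix(m = 5, n = 3, seed = 1)
  st <- modified_t(mat)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(st, path)
  df <- read.delim(path)
  expect_identical(names(df), c("feature_id", "t", "log_se", "flavor", "a0"))
  expect_equal(df$t, unname(st$z1))
})
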