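test_that("pi(z) is flat at 1/(1+B) when observed and nulls share f0", {
  mat <- null_matrix(m = 3000, n = 20, seed = 4)
  obs <- pooled_t(mat)
  ns <- permutation_null_scores(mat, B = 20, seed = 5)
  curve <- fit_pi_z(obs$z1, ns)
  central <- abs(curve$grid) < 1.5
  p_expect <- 1 / 21
  # binomial SE with the central per-bin totals
  tot <- curve$n_obs[central] + curve$n_null[central]
  se <- sqrt(p_expect * (1 - p_expect) / pmax(tot, 1))
  expect_true(all(abs(curve$pi_z[central] - p_expect) <= 3 * se + 0.01))
})

test_that("an intercept-only single-bin fit returns the raw proportion", {
  obs <- rep(0, 10)
  ns <- fake_nulls(matrix(0.0001, 10, 19))
  curve <- fit_pi_z(obs, ns, bin_range = c(-1, 1), n_bins = 1,
                    spline_df = 0)
  # 10 observed vs 190 nulls in the one bin: pi = 10/200 (up to the
  # 1e-4 ridge in the fitter)
  expect_equal(curve$pi_z, 0.05, tolerance = 1e-4)
})

test_that("binning range widens to cover extreme statistics", {
  obs <- c(rnorm(50), 12)
  ns <- fake_nulls(matrix(rnorm(50 * 5), 50, 5))
  curve <- fit_pi_z(obs, ns)
  expect_gte(curve$bin_spec$range[2], 12)
  expect_identical(sum(curve$n_obs), 51L)
  expect_error(fit_pi_z(obs, ns, n_bins = 5, spline_df = 7), "n_bins")
})

test_that("interval pi0 estimate is the documented count ratio", {
  # 500 observed and 12000 null values inside A, B = 20 -> 500/600
  obs <- c(rep(0, 500), rep(5, 40))
  ns <- fake_nulls(matrix(0, 600, 20))
  curve <- fit_pi_z(obs, ns)
  expect_equal(estimate_pi0(curve, ns, obs, method = "interval"),
               500 / 600, tolerance = 1e-12)
  ns_far <- fake_nulls(matrix(9, 600, 20))
  expect_error(estimate_pi0(curve, ns_far, obs, method = "interval"),
               "interval A")
})

test_that("both pi0 estimators approach 1 on pure-null data", {
  mat <- null_matrix(m = 3000, n = 20, seed = 6)
  obs <- pooled_t(mat)
  ns <- permutation_null_scores(mat, B = 20, seed = 7)
  curve <- fit_pi_z(obs$z1, ns)
  p_int <- estimate_pi0(curve, ns, obs$z1, method = "interval")
  p_min <- estimate_pi0(curve, ns, obs$z1, method = "min_ratio")
  expect_gt(p_int, 0.9); expect_lte(p_int, 1)
  # the minimum over ~100 noisy bins is biased below 1 by construction;
  # on pure null it still lands well above the pi0 values of real mixtures
  expect_gt(p_min, 0.7); expect_lte(p_min, 1)
})

test_that("pi0 interval bound behaves as an upper bound on mixtures", {
  cfg <- scenario_config("basic", m = 3000)
  p <- vapply(1:8, function(r) {
    gen <- generate_scenario(cfg, seed = child_seed(23, r))
    obs <- modified_t(gen$matrix)
    ns <- permutation_null_scores(gen$matrix, B = 20, flavor = "modified",
                                  seed = child_seed(23, 100 + r))
    curve <- fit_pi_z(obs$z1, ns)
    estimate_pi0(curve, ns, obs$z1)
  }, 0)
  # the bound tracks pi0 = 0.8 from below-ish: label permutation of
  # variance-inflated alternatives biases it low, but never severely
  expect_true(all(p >= 0.65 & p <= 1))
  expect_gt(mean(p), 0.7)
})

test_that("efron_fdr1d obeys range, nesting and order invariance", {
  gen <- generate_scenario(scenario_config("basic", m = 800, n_per_group = 10),
                           seed = 8)
  res <- efron_fdr1d(gen$matrix, seed = 9)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_true(all(which(res$fdr <= 0.05) %in% which(res$fdr <= 0.2)))
  # feature order invariance: permuting rows permutes the fdr identically
  perm <- sample(seq_len(800))
  mat2 <- gen$matrix
  mat2$values <- mat2$values[perm, ]
  res2 <- efron_fdr1d(mat2, seed = 9)
  expect_equal(unname(res2$fdr), unname(res$fdr[perm]), tolerance = 1e-10)
})

test_that("pure-null data with pi0 = 1 yields fdr near 1", {
  mat <- null_matrix(m = 2000, n = 15, seed = 10)
  obs <- pooled_t(mat)
  ns <- permutation_null_scores(mat, B = 20, seed = 11)
  curve <- fit_pi_z(obs$z1, ns)
  curve$pi0_hat <- 1
  fdr <- fdr_from_curve(curve, obs$z1)
  expect_gte(stats::median(fdr), 0.9)
})

test_that("doubling B moves central pi(z) by less than 2 binomial SE", {
  mat <- null_matrix(m = 3000, n = 20, seed = 14)
  obs <- pooled_t(mat)
  ns20 <- permutation_null_scores(mat, B = 20, seed = 15)
  ns40 <- permutation_null_scores(mat, B = 40, seed = 16)
  c20 <- fit_pi_z(obs$z1, ns20)
  c40 <- fit_pi_z(obs$z1, ns40)
  central <- abs(c20$grid) < 1
  # compare both fits through the implied f0/f ratio, which is B-free
  r20 <- c20$ratio_f0_over_f[central]
  r40 <- stats::approx(c40$grid, c40$ratio_f0_over_f,
                       xout = c20$grid[central])$y
  tot <- c20$n_obs[central] + c20$n_null[central]
  se_rel <- 2 / sqrt(pmax(tot * (1 / 21), 1))
  expect_true(all(abs(r20 - r40) / r20 <= 2 * se_rel + 0.05))
})
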