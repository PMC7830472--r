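make_counts <- function(gen_seed = 3, m = 400, n = 10, B = 5, nx = 12,
                        ny = 12) {
  mat <- null_matrix(m = m, n = n, seed = gen_seed)
  obs <- pooled_t(mat)
  ns <- permutation_null_scores(mat, B = B, seed = gen_seed + 100)
  list(obs = obs, nulls = ns,
       counts = bin_lattice(obs, ns, nx = nx, ny = ny))
}

test_that("lattice binning conserves every point", {
  x <- make_counts(m = 10, B = 3, nx = 4, ny = 4)
  expect_identical(sum(x$counts$N), 10L * 4L)
  expect_identical(sum(x$counts$y), 10L * 3L)
  expect_true(all(x$counts$y <= x$counts$N))
})

test_that("a tight cluster collapses into one cell", {
  obs <- structure(list(z1 = rep(0, 9), z2 = rep(0, 9), flavor = "classic"),
                   class = "bivariate_stats")
  # one distant null point stretches the grid; the cluster cell holds the rest
  ns <- fake_nulls(matrix(c(rep(0, 26), 50), 9, 3),
                   matrix(c(rep(0, 26), 50), 9, 3))
  counts <- bin_lattice(obs, ns, nx = 5, ny = 5)
  expect_identical(max(counts$N), 9L + 26L)
  expect_identical(sort(unique(as.vector(counts$N))), c(0L, 1L, 35L))
})

test_that("degenerate constant coordinates are rejected", {
  obs <- structure(list(z1 = rep(1, 5), z2 = 1:5, flavor = "classic"),
                   class = "bivariate_stats")
  ns <- fake_nulls(matrix(1, 5, 2), matrix(1:5, 5, 2))
  expect_error(bin_lattice(obs, ns), "degenerate")
})

test_that("doubling nx halves average cell occupancy", {
  x <- make_counts(m = 2000, B = 5)
  c1 <- bin_lattice(x$obs, x$nulls, nx = 10, ny = 10)
  c2 <- bin_lattice(x$obs, x$nulls, nx = 20, ny = 10)
  occ1 <- mean(c1$N[c1$N > 0]); occ2 <- mean(c2$N[c2$N > 0])
  expect_lt(occ2 / occ1, 0.65)
  expect_gt(occ2 / occ1, 0.35)
})

test_that("infinite penalty flattens gamma to the pooled proportion", {
  x <- make_counts()
  s <- smooth_gamma(x$counts, lambda = 1e8)
  pooled <- sum(x$counts$y) / sum(x$counts$N)
  expect_lt(max(abs(s$gamma - pooled)), 1e-3)
})

test_that("lambda = 0 recovers the saturated per-cell proportion", {
  counts <- structure(
    list(N = matrix(c(40, rep(0, 15)), 4, 4),
         y = matrix(c(10, rep(0, 15)), 4, 4),
         nx = 4, ny = 4, B = 3,
         x_mids = 1:4, y_mids = 1:4,
         x_breaks = 0:4 + 0.5, y_breaks = 0:4 + 0.5),
    class = "lattice_counts")
  s <- smooth_gamma(counts, lambda = 0)
  expect_equal(s$gamma[1, 1], 10 / 40, tolerance = 1e-4)
})

test_that("roughness decreases as lambda grows", {
  x <- make_counts(m = 1000, B = 5, nx = 15, ny = 15)
  rough <- vapply(c(0.1, 1, 10, 100), function(lam) {
    s <- smooth_gamma(x$counts, lambda = lam)
    eta <- stats::qlogis(pmin(pmax(s$gamma, 1e-12), 1 - 1e-12))
    sum((eta[-1, ] - eta[-nrow(eta), ])^2) +
      sum((eta[, -1] - eta[, -ncol(eta)])^2)
  }, 0)
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("smoothed gamma stays strictly inside (0, 1) for lambda > 0", {
  x <- make_counts(B = 3)
  s <- smooth_gamma(x$counts, lambda = 1)
  expect_true(all(s$gamma > 0 & s$gamma < 1))
  expect_true(s$converged)
})

test_that("gamma = B/(B+1) maps to fdr2d = pi0 exactly", {
  for (B in c(20, 100)) {
    expect_equal(fdr2d_from_gamma(B / (B + 1), pi0 = 0.8, B = B), 0.8)
    expect_equal(fdr2d_from_gamma(B / (B + 1), pi0 = 0.35, B = B), 0.35)
  }
  expect_equal(fdr2d_from_gamma(0.999999, pi0 = 0.8, B = 100), 1)
  expect_equal(fdr2d_from_gamma(1, pi0 = 0.8, B = 100), 1)
})

test_that("ploner_fdr2d returns calibrated in-range fdr on mixture data", {
  gen <- generate_scenario(scenario_config("basic", m = 600, n_per_group = 10),
                           seed = 31)
  surf <- ploner_fdr2d(gen$matrix, B = 30, nx = 15, ny = 15, seed = 32)
  expect_true(all(surf$fdr2d >= 0 & surf$fdr2d <= 1))
  expect_true(surf$converged)
  alt <- gen$truth$is_alternative
  expect_lt(stats::median(surf$fdr2d[alt]), 0.3)
  expect_gt(stats::median(surf$fdr2d[!alt]), 0.7)
})

test_that("conditional-expectation reduction averages columns correctly", {
  # constant surface: reduction is the same constant
  gen <- generate_scenario(scenario_config("basic", m = 300, n_per_group = 8,
                                           pi0 = 1), seed = 35)
  surf <- ploner_fdr2d(gen$matrix, B = 10, nx = 8, ny = 8, pi0 = 0.8,
                       lambda = 1e8, seed = 36)
  red <- ploner_fdr1d(surf)
  expect_lt(diff(range(red$fdr)), 0.01)
  # a z1 column holding two equally weighted z2 cells with cell fdr 0 and 1
  # (gamma 1e-6 and 0.99 at B = 1, pi0 = 1) must average to 0.5
  N <- matrix(0, 4, 4); N[1, 1] <- 10; N[1, 2] <- 10
  counts <- structure(
    list(N = N, y = matrix(0, 4, 4), nx = 4, ny = 4, B = 1,
         x_mids = 1:4, y_mids = 1:4, x_breaks = 0:4 + 0.5,
         y_breaks = 0:4 + 0.5),
    class = "lattice_counts")
  g <- matrix(0.5, 4, 4); g[1, 1] <- 1e-6; g[1, 2] <- 0.99
  surf2 <- structure(
    list(gamma = g, counts = counts, lambda = 0, B = 1,
         x_mids = 1:4, y_mids = 1:4, converged = TRUE, pi0_hat = 1),
    class = "fdr2d_surface")
  st <- structure(list(z1 = c(1, 1), z2 = c(1, 2), flavor = "classic"),
                  class = "bivariate_stats")
  red2 <- ploner_fdr1d(surf2, st)
  expect_equal(unname(red2$fdr), c(0.5, 0.5), tolerance = 1e-4)
})

test_that("empty z1 columns borrow the nearest occupied column", {
  x <- make_counts(m = 300, B = 3, nx = 20, ny = 8)
  surf <- smooth_gamma(x$counts, lambda = 1)
  surf$pi0_hat <- 0.9
  red <- ploner_fdr1d(surf, x$obs)
  expect_true(all(is.finite(red$profile$fdr1d)))
  expect_true(all(red$fdr >= 0 & red$fdr <= 1))
})

test_that("Ploner1dE with a0 = 0 equals Ploner1d on the same seed", {
  gen <- generate_scenario(scenario_config("basic", m = 400, n_per_group = 8),
                           seed = 41)
  s_classic <- ploner_fdr2d(gen$matrix, B = 10, nx = 10, ny = 10, seed = 42)
  r_classic <- ploner_fdr1d(s_classic)
  r_e0 <- ploner_fdr1dE(gen$matrix, B = 10, nx = 10, ny = 10, a0 = 0,
                        seed = 42)
  expect_equal(r_e0$fdr, r_classic$fdr, tolerance = 1e-12)
})

test_that("the CV lambda selector returns a grid member with deviances", {
  gen <- generate_scenario(scenario_config("basic", m = 400, n_per_group = 8),
                           seed = 51)
  obs <- pooled_t(gen$matrix)
  ns <- permutation_null_scores(gen$matrix, B = 10, seed = 52)
  sel <- select_lambda_cv(obs, ns, grid = c(1, 10, 100), nx = 10, ny = 10)
  expect_true(sel$lambda %in% c(1, 10, 100))
  expect_identical(length(sel$deviance), 3L)
  expect_true(all(is.finite(sel$deviance)))
})
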