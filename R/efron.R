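#' Binned logistic-spline fit of pi(z) = f(z) / (f(z) + B f0(z))
#'
#' Pools the observed statistics ("successes") with the B permutation null
#' sets ("failures"), bins them on a common grid, and fits a binomial GLM of
#' the per-bin success proportion on a natural-spline basis of the bin
#' midpoints.  The fitted pi(z) gives the density ratio
#' f0/f = (1 - pi) / (B pi) that local fdr estimation needs, without ever
#' estimating f0 and f separately.
#'
#' @param observed numeric vector of per-feature statistics.
#' @param nulls a \code{null_scores} object (its \code{z1} matrix is used).
#' @param bin_range interval to bin over; default [-4, 4], automatically
#'   widened to cover the pooled data range so extreme statistics are never
#'   discarded.
#' @param n_bins number of equal-width bins (default 139).
#' @param spline_df degrees of freedom of the natural-spline basis
#'   (default 7); 0 collapses to an intercept-only fit.
#' @return an \code{fdr1d_curve} with the grid of bin midpoints, fitted
#'   \code{pi_z}, derived \code{ratio_f0_over_f}, bin counts, and \code{B}.
#' @export
fit_pi_z <- function(observed, nulls, bin_range = c(-4, 4), n_bins = 139,
                     spline_df = 7) {
  if (is.null(nulls$z1) || nulls$B < 1) stop("need B >= 1 null score sets",
                                             call. = FALSE)
  stop_field(spline_df >= 0, "spline_df", "must be nonnegative")
  stop_field(n_bins >= spline_df + 1, "n_bins",
             "need more bins than spline degrees of freedom")
  null_vals <- as.vector(nulls$z1)
  rng <- range(bin_range)
  data_rng <- range(observed, null_vals, finite = TRUE)
  rng[1] <- min(rng[1], data_rng[1])
  rng[2] <- max(rng[2], data_rng[2])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2

  bin_of <- function(x) {
    i <- findInterval(x, breaks, rightmost.closed = TRUE)
    clip(i, 1, n_bins)
  }
  n_obs <- tabulate(bin_of(observed), nbins = n_bins)
  n_null <- tabulate(bin_of(null_vals), nbins = n_bins)
  tot <- n_obs + n_null
  if (all(tot == 0)) stop("all bins empty", call. = FALSE)

  keep <- tot > 0
  basis <- if (spline_df >= 1) splines::ns(mids, df = spline_df)
           else matrix(0, length(mids), 0)
  X <- cbind(`(Intercept)` = 1, basis)
  # tail bins holding only observed statistics separate the response and
  # push the tail logits to infinity (plain IRLS can then diverge and
  # wreck the data-rich center too); the Haldane-Anscombe 0.5 correction
  # on zero-cell bins bounds the separated logits, and the step-halved
  # ridge Newton below is monotone in the deviance
  zero_cell <- keep & (n_obs == 0 | n_null == 0)
  succ <- n_obs + 0.5 * zero_cell
  fail <- n_null + 0.5 * zero_cell
  beta <- fit_logistic_ridge(X[keep, , drop = FALSE], succ[keep],
                             fail[keep])
  eta <- X %*% beta
  pi_z <- as.vector(1 / (1 + exp(-eta)))
  B <- nulls$B
  ratio <- (1 - pi_z) / (B * pmax(pi_z, .Machine$double.eps))

  structure(
    list(grid = mids, pi_z = pi_z, ratio_f0_over_f = ratio, B = B,
         n_obs = n_obs, n_null = n_null, breaks = breaks,
         bin_spec = list(range = rng, n_bins = n_bins,
                         spline_df = spline_df),
         pi0_hat = NULL, fdr = NULL),
    class = "fdr1d_curve"
  )
}

# Binomial logistic regression of successes vs failures on design X by
# Newton iterations with step halving and a small L2 ridge.  Guaranteed
# monotone in the penalized deviance, so separation in sparse bins cannot
# corrupt the fit where the counts are large.
fit_logistic_ridge <- function(X, succ, fail, ridge = 1e-4, max_iter = 200,
                               tol = 1e-8) {
  n <- succ + fail
  p <- ncol(X)
  beta <- c(stats::qlogis(clip(sum(succ) / sum(n), 1e-6, 1 - 1e-6)),
            rep(0, p - 1))
  obj <- function(beta) {
    mu <- clip(stats::plogis(as.vector(X %*% beta)), 1e-12, 1 - 1e-12)
    -sum(succ * log(mu) + fail * log(1 - mu)) + ridge * sum(beta^2) / 2
  }
  o <- obj(beta)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(as.vector(X %*% beta))
    w <- n * mu * (1 - mu)
    grad <- as.vector(crossprod(X, succ - n * mu)) - ridge * beta
    H <- crossprod(X * w, X) + diag(ridge, p)
    dir <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-6, p), grad))
    step <- 1
    repeat {
      cand <- beta + step * dir
      o_new <- obj(cand)
      if (o_new <= o + 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    o <- o_new
    if (moved < tol * (1 + max(abs(beta)))) break
  }
  beta
}

#' Upper-bound estimators of the null proportion pi0
#'
#' Two bounds derived from f = pi0 f0 + (1 - pi0) f1 >= pi0 f0:
#' \describe{
#'   \item{min_ratio}{pi0 <= min_z f(z) / f0(z), taken over the fitted grid
#'     (restricted to bins that contain data).}
#'   \item{interval}{pi0 <= (observed count in A) / (null count in A / B)
#'     for an interval A near zero where f1 is assumed negligible;
#'     default A = [-0.5, 0.5].}
#' }
#' Both are clipped to (0, 1].
#'
#' @param curve an \code{fdr1d_curve} from \code{\link{fit_pi_z}}.
#' @param nulls the \code{null_scores} used to fit the curve.
#' @param observed the observed statistics used to fit the curve.
#' @param method \code{"interval"} (default) or \code{"min_ratio"}.
#' @param A interval for the interval bound.
#' @param min_count smallest per-bin total for a bin to enter the
#'   min_ratio search (default 20); sparse tail bins otherwise dominate
#'   the minimum with pure estimation noise.
#' @return pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(curve, nulls, observed,
                         method = c("interval", "min_ratio"),
                         A = c(-0.5, 0.5), min_count = 20) {
  method <- match.arg(method)
  if (method == "min_ratio") {
    occupied <- (curve$n_obs + curve$n_null) >= min_count
    if (!any(occupied)) occupied <- (curve$n_obs + curve$n_null) > 0
    ratio_f_over_f0 <- 1 / curve$ratio_f0_over_f[occupied]
    pi0 <- min(ratio_f_over_f0, na.rm = TRUE)
  } else {
    null_vals <- as.vector(nulls$z1)
    n_obs_A <- sum(observed >= A[1] & observed <= A[2])
    n_null_A <- sum(null_vals >= A[1] & null_vals <= A[2])
    if (n_null_A == 0)
      stop("interval A contains no null scores", call. = FALSE)
    pi0 <- n_obs_A / (n_null_A / nulls$B)
  }
  clip(pi0, .Machine$double.eps, 1)
}

#' Efron's one-dimensional local fdr
#'
#' The full pipeline: modified t statistics (default), B label-permutation
#' null score sets, binned logistic-spline estimation of
#' pi(z) = f/(f + B f0), an upper-bound estimate of pi0, and per-feature
#' fdr1d(z) = clip(pi0 * f0(z)/f(z), 0, 1) read off the fitted curve by
#' linear interpolation at each feature's statistic.
#'
#' @inheritParams pooled_t
#' @param B number of permutations (default 20).
#' @param flavor statistic flavor, \code{"modified"} (default) or
#'   \code{"classic"}.
#' @param pi0_method \code{"interval"} (default) or \code{"min_ratio"}.
#' @param a0_percentile percentile for the modified-t offset.
#' @param bin_range,n_bins,spline_df binning controls, see
#'   \code{\link{fit_pi_z}}.
#' @param A interval for the interval pi0 bound.
#' @param seed RNG seed for the permutations.
#' @return an \code{fdr1d_curve} with \code{pi0_hat} and per-feature
#'   \code{fdr} filled in, plus the observed statistics as \code{z}.
#' @export
efron_fdr1d <- function(mat, B = 20, flavor = c("modified", "classic"),
                        pi0_method = c("interval", "min_ratio"),
                        a0_percentile = 90, bin_range = c(-4, 4),
                        n_bins = 139, spline_df = 7, A = c(-0.5, 0.5),
                        seed = NULL) {
  flavor <- match.arg(flavor)
  pi0_method <- match.arg(pi0_method)
  obs <- if (flavor == "modified") modified_t(mat, a0_percentile)
         else pooled_t(mat)
  nulls <- permutation_null_scores(mat, B = B, flavor = flavor,
                                   a0_percentile = a0_percentile,
                                   seed = seed)
  curve <- fit_pi_z(obs$z1, nulls, bin_range = bin_range, n_bins = n_bins,
                    spline_df = spline_df)
  curve$pi0_hat <- estimate_pi0(curve, nulls, obs$z1, method = pi0_method,
                                A = A)
  curve$z <- obs$z1
  curve$fdr <- fdr_from_curve(curve, obs$z1)
  curve$stats <- obs
  curve
}

#' Read per-feature fdr off a fitted curve
#'
#' Linear interpolation of pi0 * f0/f between grid points, clipped to
#' [0, 1]; statistics beyond the grid take the boundary value.
#' @param curve a fitted \code{fdr1d_curve} with \code{pi0_hat} set.
#' @param z statistics at which to evaluate.
#' @return fdr values in [0, 1].
#' @export
fdr_from_curve <- function(curve, z) {
  if (is.null(curve$pi0_hat)) stop("curve has no pi0_hat", call. = FALSE)
  raw <- curve$pi0_hat * curve$ratio_f0_over_f
  clip(stats::approx(curve$grid, raw, xout = z, rule = 2)$y, 0, 1)
}

#' @export
print.fdr1d_curve <- function(x, ...) {
  cat(sprintf("fdr1d_curve: %d bins over [%.2f, %.2f], B = %d",
              x$bin_spec$n_bins, x$bin_spec$range[1], x$bin_spec$range[2],
              x$B))
  if (!is.null(x$pi0_hat)) cat(sprintf(", pi0_hat = %.3f", x$pi0_hat))
  cat("\n")
  if (!is.null(x$fdr))
    cat(sprintf("  %d features, %d with fdr <= 0.1\n", length(x$fdr),
                sum(x$fdr <= 0.1)))
  invisible(x)
}

#' Export per-feature fdr1d results as TSV
#' @param curve a fitted \code{fdr1d_curve} (from \code{\link{efron_fdr1d}}).
#' @param path output file.
#' @export
write_fdr1d_tsv <- function(curve, path) {
  df <- data.frame(
    feature_id = names(curve$z) %||% paste0("f", seq_along(curve$z)),
    z = curve$z, fdr1d = curve$fdr
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
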