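#' Bin observed and null bivariate statistics on a rectangular lattice
#'
#' The (z1, z2) = (t, log se) plane is cut into an nx x ny grid spanning
#' the pooled range of the observed statistics and all B null score sets.
#' Per cell, \code{N} counts every point (observed + null) and \code{y}
#' counts the null points only — the "successes" of the binomial
#' reformulation y_ij ~ Bin(N_ij, gamma_ij) with
#' gamma = B f0 / (f + B f0).
#'
#' @param observed a \code{bivariate_stats}.
#' @param nulls a \code{null_scores} of the same flavor.
#' @param nx,ny number of bins per axis (default 30 each, >= 4).
#' @return a \code{lattice_counts}: breaks and midpoints per axis, count
#'   matrices \code{N} and \code{y} (nx x ny), per-feature cell indices.
#' @export
bin_lattice <- function(observed, nulls, nx = 30, ny = 30) {
  stop_field(nx >= 4 && ny >= 4, "nx/ny", "need at least 4 bins per axis")
  if (!identical(observed$flavor, nulls$flavor))
    stop("observed and null statistics have different flavors",
         call. = FALSE)
  x_all <- c(observed$z1, as.vector(nulls$z1))
  y_all <- c(observed$z2, as.vector(nulls$z2))
  if (diff(range(x_all, finite = TRUE)) == 0 ||
      diff(range(y_all, finite = TRUE)) == 0)
    stop("degenerate (constant) statistic coordinate", call. = FALSE)
  bx <- seq(min(x_all), max(x_all), length.out = nx + 1)
  by <- seq(min(y_all), max(y_all), length.out = ny + 1)
  cell <- function(v, breaks, nb) clip(findInterval(v, breaks,
                                                    rightmost.closed = TRUE),
                                       1, nb)
  ix_obs <- cell(observed$z1, bx, nx); iy_obs <- cell(observed$z2, by, ny)
  ix_nul <- cell(as.vector(nulls$z1), bx, nx)
  iy_nul <- cell(as.vector(nulls$z2), by, ny)

  tab <- function(ix, iy) {
    m <- matrix(0L, nx, ny)
    t2 <- table(factor(ix, levels = seq_len(nx)),
                factor(iy, levels = seq_len(ny)))
    m + as.matrix(t2)
  }
  y <- tab(ix_nul, iy_nul)
  N <- y + tab(ix_obs, iy_obs)
  structure(
    list(x_breaks = bx, y_breaks = by,
         x_mids = (bx[-1] + bx[-length(bx)]) / 2,
         y_mids = (by[-1] + by[-length(by)]) / 2,
         N = N, y = y, nx = nx, ny = ny, B = nulls$B,
         obs_cell = cbind(ix_obs, iy_obs)),
    class = "lattice_counts"
  )
}

# Sparse graph Laplacian of the nx x ny 4-neighbor lattice (column-major
# cell order); the roughness penalty lambda * sum (eta_ij - eta_kl)^2 over
# primary neighbors equals lambda * eta' L eta.
lattice_laplacian <- function(nx, ny) {
  idx <- matrix(seq_len(nx * ny), nx, ny)
  from <- c(idx[-nx, , drop = FALSE], idx[, -ny, drop = FALSE])
  to <- c(idx[-1, , drop = FALSE], idx[, -1, drop = FALSE])
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                            dims = c(nx * ny, nx * ny))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Penalized-likelihood smoothing of gamma on the lattice
#'
#' Minimizes the penalized binomial deviance
#' -sum_ij [ y_ij log gamma_ij + (N_ij - y_ij) log(1 - gamma_ij) ]
#' + lambda * sum_neighbors (eta_ij - eta_kl)^2
#' over the cell logits eta = logit(gamma), by iteratively reweighted least
#' squares: each step solves (W + 2 lambda L) eta = W zeta with working
#' weights W = N gamma (1 - gamma) and working response
#' zeta = eta + (y - N gamma) / W.  Empty cells carry zero weight and are
#' filled in purely by the neighbor penalty.
#'
#' @param counts a \code{lattice_counts}.
#' @param lambda penalty weight (>= 0; default 1, the value the
#'   held-out-permutation deviance criterion selects on data of this size).
#' @param tol convergence tolerance on max |delta eta| (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return an \code{fdr2d_surface} with the smoothed \code{gamma} matrix
#'   (strictly inside (0, 1)), the lattice geometry, \code{lambda},
#'   \code{B} and convergence diagnostics.
#' @export
smooth_gamma <- function(counts, lambda = 1, tol = 1e-6, max_iter = 100) {
  stop_field(lambda >= 0, "lambda", "must be nonnegative")
  nx <- counts$nx; ny <- counts$ny
  N <- as.vector(counts$N); y <- as.vector(counts$y)
  L <- lattice_laplacian(nx, ny)
  p0 <- (sum(y) + 0.5) / (sum(N) + 1)
  eta <- rep(log(p0 / (1 - p0)), nx * ny)
  ridge <- Matrix::Diagonal(nx * ny, 1e-8)
  pen_obj <- function(eta) {
    g <- 1 / (1 + exp(-eta))
    g <- clip(g, 1e-12, 1 - 1e-12)
    -sum(y * log(g) + (N - y) * log(1 - g)) +
      lambda * as.numeric(eta %*% (L %*% eta))
  }
  converged <- FALSE
  iters <- 0L
  obj <- pen_obj(eta)
  eta_cap <- 20 # |logit| clamp; saturated pure-null / pure-alt regions
  for (it in seq_len(max_iter)) {
    iters <- it
    g <- 1 / (1 + exp(-eta))
    w <- N * g * (1 - g)
    # working response on the linear scale; cells with w = 0 contribute
    # nothing to the likelihood part and are driven by the penalty alone
    Wz <- w * eta + (y - N * g)
    H <- Matrix::Diagonal(x = w) + 2 * lambda * L + ridge
    eta_new <- clip(as.vector(Matrix::solve(H, Wz)), -eta_cap, eta_cap)
    # step-halving keeps the Newton update inside the decreasing region
    step <- 1
    repeat {
      cand <- eta + step * (eta_new - eta)
      obj_new <- pen_obj(cand)
      if (obj_new <= obj + 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    delta <- max(abs(cand - eta))
    eta <- cand
    obj <- obj_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(eta)) < eta_cap - 1e-6)
    warning(sprintf("IWLS did not converge in %d iterations (last delta %.2e)",
                    max_iter, delta), call. = FALSE)
  gamma <- matrix(1 / (1 + exp(-eta)), nx, ny)
  structure(
    list(gamma = gamma, counts = counts, lambda = lambda, B = counts$B,
         x_mids = counts$x_mids, y_mids = counts$y_mids,
         converged = converged, iterations = iters,
         pi0_hat = NULL, fdr2d = NULL),
    class = "fdr2d_surface"
  )
}

#' Choose the smoothing penalty by held-out permutation deviance
#'
#' Splits the B permutation null sets into two halves, fits the gamma
#' surface on the first half for every candidate lambda, and scores each
#' fit by the binomial deviance of the counts built from the second half
#' (both halves share the observed statistics, so gamma has the same
#' meaning on either side).  Returns the candidate with the smallest
#' held-out deviance.
#'
#' @param observed a \code{bivariate_stats}.
#' @param nulls a \code{null_scores} with an even B >= 2.
#' @param grid candidate lambda values.
#' @param nx,ny lattice resolution.
#' @return list with \code{lambda} (the winner) and the \code{deviance}
#'   per candidate.
#' @export
select_lambda_cv <- function(observed, nulls,
                             grid = c(0.5, 1, 2, 5, 10, 20, 50),
                             nx = 30, ny = 30) {
  half <- nulls$B %/% 2
  if (half < 1) stop("need at least 2 permutations for CV", call. = FALSE)
  split_nulls <- function(cols) {
    structure(list(z1 = nulls$z1[, cols, drop = FALSE],
                   z2 = nulls$z2[, cols, drop = FALSE],
                   B = length(cols), mode = nulls$mode,
                   flavor = nulls$flavor),
              class = "null_scores")
  }
  c_fit <- bin_lattice(observed, split_nulls(seq_len(half)), nx, ny)
  c_val <- bin_lattice(observed, split_nulls(seq(half + 1, 2 * half)),
                       nx, ny)
  grid_pts_x <- rep(c_val$x_mids, times = c_val$ny)
  grid_pts_y <- rep(c_val$y_mids, each = c_val$nx)
  dev <- vapply(grid, function(lam) {
    s <- smooth_gamma(c_fit, lambda = lam)
    g <- interp2(s$x_mids, s$y_mids, s$gamma, grid_pts_x, grid_pts_y)
    g <- clip(g, 1e-10, 1 - 1e-10)
    -2 * sum(c_val$y * log(g) + (c_val$N - c_val$y) * log(1 - g))
  }, 0)
  list(lambda = grid[which.min(dev)], grid = grid, deviance = dev)
}

# Bilinear interpolation of a cell-center field at arbitrary points;
# points beyond the outer cell centers take the boundary value.
interp2 <- function(x_mids, y_mids, field, x, y) {
  fx <- stats::approx(x_mids, seq_along(x_mids), xout = clip(x, x_mids[1],
                      x_mids[length(x_mids)]), rule = 2)$y
  fy <- stats::approx(y_mids, seq_along(y_mids), xout = clip(y, y_mids[1],
                      y_mids[length(y_mids)]), rule = 2)$y
  i0 <- pmin(floor(fx), length(x_mids) - 1); j0 <- pmin(floor(fy),
                                                        length(y_mids) - 1)
  tx <- fx - i0; ty <- fy - j0
  f00 <- field[cbind(i0, j0)]; f10 <- field[cbind(i0 + 1, j0)]
  f01 <- field[cbind(i0, j0 + 1)]; f11 <- field[cbind(i0 + 1, j0 + 1)]
  (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
}

#' Ploner's two-dimensional local fdr
#'
#' Computes classic (t, log se) statistics, B label-permutation null sets,
#' bins everything on the lattice, smooths gamma = B f0 / (f + B f0) by
#' penalized IWLS, and converts to
#' fdr2d(z) = clip(pi0 * gamma(z) / (B (1 - gamma(z))), 0, 1),
#' with gamma evaluated at each feature's (z1, z2) by bilinear
#' interpolation between cell centers.  pi0 defaults to Efron's interval
#' upper bound computed on the t coordinate; a fixed \code{pi0} can be
#' supplied instead (the plug-in used for real data).
#'
#' @inheritParams pooled_t
#' @param B number of label permutations (default 100).
#' @param flavor statistic flavor for the t coordinate, \code{"classic"}
#'   (default) or \code{"modified"} (used by Ploner1dE).
#' @param nx,ny lattice resolution (default 30 x 30).
#' @param lambda smoothing penalty: a nonnegative number (default 1) or
#'   \code{"cv"} to pick it from a coarse grid by binomial deviance on
#'   held-out permutation halves (see \code{\link{select_lambda_cv}}).
#' @param pi0 optional fixed null proportion; when \code{NULL} the interval
#'   bound with A = [-0.5, 0.5] is used.
#' @param a0_percentile offset percentile when \code{flavor = "modified"}.
#' @param a0 optional fixed offset for the modified flavor (overrides the
#'   percentile rule in both the observed statistics and every permutation).
#' @param seed RNG seed for the permutations.
#' @return an \code{fdr2d_surface} with per-feature \code{fdr2d},
#'   \code{pi0_hat} and the underlying statistics attached.
#' @export
ploner_fdr2d <- function(mat, B = 100, flavor = c("classic", "modified"),
                         nx = 30, ny = 30, lambda = 1, pi0 = NULL,
                         a0_percentile = 90, a0 = NULL, seed = NULL) {
  flavor <- match.arg(flavor)
  obs <- if (flavor == "modified") modified_t(mat, a0_percentile, a0 = a0)
         else pooled_t(mat)
  nulls <- permutation_null_scores(mat, B = B, flavor = flavor,
                                   a0_percentile = a0_percentile, a0 = a0,
                                   seed = seed)
  if (identical(lambda, "cv"))
    lambda <- select_lambda_cv(obs, nulls, nx = nx, ny = ny)$lambda
  counts <- bin_lattice(obs, nulls, nx = nx, ny = ny)
  surf <- smooth_gamma(counts, lambda = lambda)
  if (is.null(pi0)) {
    pi0 <- estimate_pi0_counts(obs$z1, nulls)
  }
  surf$pi0_hat <- clip(pi0, .Machine$double.eps, 1)
  g <- interp2(surf$x_mids, surf$y_mids, surf$gamma, obs$z1, obs$z2)
  surf$fdr2d <- fdr2d_from_gamma(g, surf$pi0_hat, B)
  surf$gamma_at_features <- g
  surf$stats <- obs
  surf
}

# Efron interval upper bound for pi0 from raw counts in A = [-0.5, 0.5].
estimate_pi0_counts <- function(observed, nulls, A = c(-0.5, 0.5)) {
  null_vals <- as.vector(nulls$z1)
  n_null_A <- sum(null_vals >= A[1] & null_vals <= A[2])
  if (n_null_A == 0) stop("interval A contains no null scores",
                          call. = FALSE)
  clip(sum(observed >= A[1] & observed <= A[2]) / (n_null_A / nulls$B),
       .Machine$double.eps, 1)
}

#' Convert gamma to fdr2d
#'
#' fdr2d = clip(pi0 * gamma / (B (1 - gamma)), 0, 1); gamma = B/(B+1)
#' (the pure-null value where f = f0) maps to exactly pi0.
#' @param gamma gamma values in (0, 1).
#' @param pi0 null proportion.
#' @param B permutation count.
#' @return fdr values in [0, 1].
#' @export
fdr2d_from_gamma <- function(gamma, pi0, B) {
  clip(pi0 * gamma / (B * pmax(1 - gamma, .Machine$double.eps)), 0, 1)
}

#' @export
print.fdr2d_surface <- function(x, ...) {
  cat(sprintf("fdr2d_surface: %d x %d lattice, lambda = %g, B = %d%s\n",
              x$counts$nx, x$counts$ny, x$lambda, x$B,
              if (x$converged) "" else " (IWLS not converged)"))
  if (!is.null(x$pi0_hat)) cat(sprintf("  pi0_hat = %.3f\n", x$pi0_hat))
  if (!is.null(x$fdr2d))
    cat(sprintf("  %d features, %d with fdr2d <= 0.1\n", length(x$fdr2d),
                sum(x$fdr2d <= 0.1)))
  invisible(x)
}

#' Conditional-expectation 1D reduction of a fitted fdr2d surface
#'
#' For each z1 column of the lattice, fdr1d(z1) is the average of the
#' cell-level fdr2d over the z2 cells of that column, weighted by the
#' observed point counts so it estimates E[fdr2d(z1, Z2) | z1] under the
#' observed mixture (weighting by observed + null counts would let the B
#' permutation sets swamp the conditional z2 law); each feature then takes
#' the value of its z1 bin.  Empty z1 columns borrow the nearest nonempty
#' column (flagged).
#'
#' @param surface a fitted \code{fdr2d_surface} (with \code{pi0_hat}).
#' @param stats the \code{bivariate_stats} the surface was fitted on;
#'   defaults to the statistics attached to the surface.
#' @return list with per-feature \code{fdr} values, the per-column
#'   \code{profile} (z1 midpoint, fdr1d), and a \code{borrowed} flag per
#'   column.
#' @export
ploner_fdr1d <- function(surface, stats = NULL) {
  stats <- stats %||% surface$stats
  if (is.null(surface$pi0_hat)) stop("surface has no pi0_hat", call. = FALSE)
  counts <- surface$counts
  cell_fdr <- fdr2d_from_gamma(surface$gamma, surface$pi0_hat, surface$B)
  Nw <- counts$N - counts$y # observed points only
  col_tot <- rowSums(Nw) # rows of the matrices index z1 bins
  prof <- rowSums(Nw * cell_fdr)
  prof <- ifelse(col_tot > 0, prof / col_tot, NA_real_)
  borrowed <- !is.finite(prof)
  if (any(borrowed)) {
    good <- which(!borrowed)
    if (length(good) == 0) stop("no occupied z1 column", call. = FALSE)
    for (i in which(borrowed)) {
      prof[i] <- prof[good[which.min(abs(good - i))]]
    }
  }
  ix <- clip(findInterval(stats$z1, counts$x_breaks,
                          rightmost.closed = TRUE), 1, counts$nx)
  list(fdr = clip(prof[ix], 0, 1),
       profile = data.frame(z1 = counts$x_mids, fdr1d = clip(prof, 0, 1)),
       borrowed = borrowed)
}

#' Ploner1dE: the 1D reduction on modified-t statistics
#'
#' Identical to the Ploner1d reduction but with the modified (offset) t
#' replacing the classic t throughout — in the observed statistics and in
#' every permutation null set.
#'
#' @inheritParams ploner_fdr2d
#' @return as \code{\link{ploner_fdr1d}}, with the fitted surface attached
#'   as \code{surface}.
#' @export
ploner_fdr1dE <- function(mat, B = 100, nx = 30, ny = 30, lambda = 1,
                          pi0 = NULL, a0_percentile = 90, a0 = NULL,
                          seed = NULL) {
  surf <- ploner_fdr2d(mat, B = B, flavor = "modified", nx = nx, ny = ny,
                       lambda = lambda, pi0 = pi0,
                       a0_percentile = a0_percentile, a0 = a0, seed = seed)
  out <- ploner_fdr1d(surf)
  out$surface <- surf
  out
}

#' Export a fitted fdr2d surface as a dense grid TSV
#' @param surface a fitted \code{fdr2d_surface}.
#' @param path output file.
#' @export
write_surface_tsv <- function(surface, path) {
  cell_fdr <- fdr2d_from_gamma(surface$gamma, surface$pi0_hat %||% 1,
                               surface$B)
  df <- expand.grid(z1_mid = surface$x_mids, z2_mid = surface$y_mids)
  df$gamma <- as.vector(surface$gamma)
  df$fdr2d <- as.vector(cell_fdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
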