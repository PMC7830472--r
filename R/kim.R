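# Univariate Gaussian mixture by EM with BIC model selection.  Used to
# identify the null component (weight, mean, sd) of a marginal statistic
# distribution; kept internal and deliberately simple: k-means start,
# variance floor, 500-iteration cap.
fit_gaussian_mixture <- function(x, G, max_iter = 300, tol = 1e-7) {
  n <- length(x)
  if (G == 1) {
    mu <- mean(x); sd0 <- stats::sd(x)
    ll <- sum(stats::dnorm(x, mu, sd0, log = TRUE))
    return(list(G = 1, weight = 1, mean = mu, sd = sd0, loglik = ll,
                bic = -2 * ll + 2 * log(n)))
  }
  km <- suppressWarnings(stats::kmeans(x, centers = G, nstart = 2,
                                       iter.max = 50))
  mu <- as.vector(km$centers)
  sd_ <- vapply(seq_len(G), function(g) {
    s <- stats::sd(x[km$cluster == g]); if (!is.finite(s) || s < 1e-3) 1e-1
    else s
  }, 0)
  w <- as.vector(table(factor(km$cluster, levels = seq_len(G)))) / n
  w <- pmax(w, 1e-6); w <- w / sum(w)
  ll_old <- -Inf
  sd_floor <- max(stats::sd(x) * 1e-3, 1e-6)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(G),
                   function(g) w[g] * stats::dnorm(x, mu[g], sd_[g]), x)
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd_ <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sd_ <- pmax(sd_, sd_floor)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  npar <- 3 * G - 1
  list(G = G, weight = w, mean = mu, sd = sd_, loglik = ll,
       bic = -2 * ll + npar * log(n))
}

select_gaussian_mixture <- function(x, G_max = 5, seed = NULL) {
  with_seed(seed, {
    fits <- lapply(seq_len(G_max), function(G)
      tryCatch(fit_gaussian_mixture(x, G), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  })
}

#' Marginal local fdr for one coordinate of the bivariate statistic
#'
#' Fits a univariate Gaussian mixture (components chosen by BIC, up to
#' \code{G_max}) to the statistic values, takes the null component as the
#' one with the largest mixing weight (ties broken toward the smallest
#' |mean|), estimates the full density f by kernel smoothing
#' (\code{stats::density} with its default bandwidth rule), and returns
#' fdr_m(z) = clip(pi0_m * dnorm(z; mu0, sigma0) / f_hat(z), 0, 1).
#'
#' For \code{side = "right"} only the right tail is a rejection direction
#' (the non-null direction for the log-se coordinate is large se), so
#' fdr_m is forced to 1 for values below the null mean.
#'
#' @param values per-feature statistic values for one coordinate.
#' @param side \code{"two_sided"} or \code{"right"}.
#' @param G_max maximum number of mixture components tried (default 5).
#' @param seed RNG seed for the k-means initialization.
#' @return a \code{marginal_fdr_fit}: null component (pi0_m, mu0, sigma0),
#'   the chosen mixture, and per-feature \code{fdr_m}.
#' @export
fit_marginal_fdr <- function(values, side = c("two_sided", "right"),
                             G_max = 5, seed = NULL) {
  side <- match.arg(side)
  if (length(values) < 50)
    stop("need at least 50 features to fit the marginal mixture",
         call. = FALSE)
  mix <- select_gaussian_mixture(values, G_max = G_max, seed = seed)
  w <- mix$weight
  best_w <- max(w)
  cand <- which(w >= best_w - 1e-9)
  null_comp <- cand[which.min(abs(mix$mean[cand]))]
  pi0_m <- w[null_comp]; mu0 <- mix$mean[null_comp]
  sigma0 <- mix$sd[null_comp]
  if (sigma0 < 1e-8)
    stop("degenerate null component (sigma -> 0) in mixture fit",
         call. = FALSE)
  dens <- stats::density(values)
  f_hat <- stats::approx(dens$x, dens$y, xout = values, rule = 2)$y
  f_hat <- pmax(f_hat, .Machine$double.xmin)
  fdr_m <- clip(pi0_m * stats::dnorm(values, mu0, sigma0) / f_hat, 0, 1)
  if (side == "right") fdr_m[values < mu0] <- 1
  structure(
    list(side = side, pi0_m = pi0_m, mu0 = mu0, sigma0 = sigma0,
         mixture = mix, fdr_m = fdr_m, values = values),
    class = "marginal_fdr_fit"
  )
}

#' @export
print.marginal_fdr_fit <- function(x, ...) {
  cat(sprintf(
    "marginal_fdr_fit (%s): %d components, null pi0 = %.3f, N(%.3f, %.3f^2)\n",
    x$side, x$mixture$G, x$pi0_m, x$mu0, x$sigma0))
  invisible(x)
}

#' Combine two marginal fdr fits into a composite-null decision
#'
#' Marginal rejection regions are R_c = \{fdr_c <= alpha_c\}.  For the
#' intersection null (H01 and H02 both true) the rejection region is
#' R1 union R2 with the Bonferroni split alpha1 = alpha2 = alpha / 2.  For
#' the union null the region is R1 intersect R2 and (alpha1, alpha2) are
#' chosen on a finite grid \{alpha/200, 2 alpha/200, ..., alpha\} to
#' maximize |R1 intersect R2| subject to the calibration
#' max(alpha1, alpha2) * (1 + min(n1/n12, n2/n12)) <= alpha,
#' where n1, n2, n12 count features in R1, R2, R1 intersect R2.  When
#' n12 = 0 the pair is feasible with factor 1 only if n1 = n2 = 0,
#' otherwise it must satisfy max(alpha1, alpha2) <= alpha.
#'
#' @param fit1,fit2 \code{marginal_fdr_fit}s on the same feature set.
#' @param null_type \code{"intersection"} or \code{"union"}.
#' @param alpha target fdr level in (0, 1).
#' @param grid_steps grid resolution for the union-null search
#'   (default 200).
#' @return a \code{kim_decision}: per-feature logicals \code{R1},
#'   \code{R2}, \code{reject}; \code{alpha1}, \code{alpha2}; counts
#'   \code{n1}, \code{n2}, \code{n12}; and a \code{degenerate} flag for the
#'   n12 = 0 guard.
#' @export
kim_reject <- function(fit1, fit2,
                       null_type = c("intersection", "union"),
                       alpha = 0.1, grid_steps = 200) {
  null_type <- match.arg(null_type)
  stop_field(alpha > 0 && alpha < 1, "alpha", "must lie in (0, 1)")
  f1 <- fit1$fdr_m; f2 <- fit2$fdr_m
  if (length(f1) != length(f2))
    stop("marginal fits cover different feature sets", call. = FALSE)

  if (null_type == "intersection") {
    a1 <- a2 <- alpha / 2
    R1 <- f1 <= a1; R2 <- f2 <= a2
    reject <- R1 | R2
    degenerate <- FALSE
  } else {
    grid <- alpha * seq_len(grid_steps) / grid_steps
    # cumulative 2D count table so every (alpha1, alpha2) pair is scored in
    # O(grid_steps^2) total rather than O(grid_steps^2 * m)
    b1 <- pmax(ceiling(f1 * grid_steps / alpha - 1e-12), 1)
    b2 <- pmax(ceiling(f2 * grid_steps / alpha - 1e-12), 1)
    inside <- b1 <= grid_steps & b2 <= grid_steps
    joint <- matrix(0, grid_steps, grid_steps)
    if (any(inside)) {
      tab <- table(factor(b1[inside], levels = seq_len(grid_steps)),
                   factor(b2[inside], levels = seq_len(grid_steps)))
      joint <- apply(apply(unclass(tab), 2, cumsum), 1, cumsum)
      joint <- t(joint) # joint[i, j] = #{f1 <= grid[i] & f2 <= grid[j]}
    }
    n1_g <- cumsum(tabulate(pmin(b1, grid_steps + 1), grid_steps + 1)
                   )[seq_len(grid_steps)]
    n2_g <- cumsum(tabulate(pmin(b2, grid_steps + 1), grid_steps + 1)
                   )[seq_len(grid_steps)]
    amax <- outer(grid, grid, pmax)
    n1m <- matrix(n1_g, grid_steps, grid_steps)
    n2m <- matrix(n2_g, grid_steps, grid_steps, byrow = TRUE)
    factor_ <- 1 + pmin(n1m / joint, n2m / joint) # Inf/NaN where n12 = 0
    feasible <- ifelse(joint > 0, amax * factor_ <= alpha, amax <= alpha)
    degenerate <- FALSE
    if (any(feasible)) {
      n12_feas <- ifelse(feasible, joint, -1)
      pick <- which(n12_feas == max(n12_feas), arr.ind = TRUE)
      # among maximizers prefer the largest alphas (widest calibrated pair)
      pick <- pick[order(pick[, 1] + pick[, 2], decreasing = TRUE)[1], ,
                   drop = FALSE]
      a1 <- grid[pick[1, 1]]; a2 <- grid[pick[1, 2]]
      degenerate <- joint[pick[1, 1], pick[1, 2]] == 0
    } else {
      a1 <- a2 <- alpha / 2
      degenerate <- TRUE
    }
    R1 <- f1 <= a1; R2 <- f2 <= a2
    reject <- R1 & R2
  }
  structure(
    list(null_type = null_type, alpha = alpha, alpha1 = a1, alpha2 = a2,
         R1 = R1, R2 = R2, reject = reject,
         n1 = sum(R1), n2 = sum(R2), n12 = sum(R1 & R2),
         degenerate = degenerate),
    class = "kim_decision"
  )
}

#' @export
print.kim_decision <- function(x, ...) {
  cat(sprintf(
    "kim_decision (%s null, alpha = %g): %d rejections\n",
    x$null_type, x$alpha, sum(x$reject)))
  cat(sprintf("  alpha1 = %.4g, alpha2 = %.4g; n1 = %d, n2 = %d, n12 = %d%s\n",
              x$alpha1, x$alpha2, x$n1, x$n2, x$n12,
              if (x$degenerate) " (degenerate guard hit)" else ""))
  invisible(x)
}

#' Kim's two-stage composite-null fdr procedure
#'
#' Stage one fits a marginal local fdr independently on each coordinate of
#' the bivariate statistic (z1 = classic pooled t, z2 = log pooled se):
#' Gaussian-mixture null component plus kernel-density f.  Stage two
#' combines the two marginal rejection regions Bonferroni-style according
#' to the composite null type (see \code{\link{kim_reject}}).  The z2
#' marginal is always right-sided: a large log se is the non-null
#' direction for the zero-variance null.
#'
#' @inheritParams pooled_t
#' @param null_type \code{"intersection"} or \code{"union"}.
#' @param alpha target fdr level.
#' @param side alternative type for the t coordinate: \code{"two_sided"}
#'   (default) or \code{"right"} for one-sided scenarios.
#' @param flavor statistic flavor (default classic pooled t).
#' @param seed RNG seed (mixture initialization).
#' @return a \code{kim_decision} with the two marginal fits attached as
#'   \code{fit1}, \code{fit2} and the statistics as \code{stats}.
#' @export
kim_fdr2d <- function(mat, null_type = c("intersection", "union"),
                      alpha = 0.1, side = c("two_sided", "right"),
                      flavor = c("classic", "modified"), seed = NULL) {
  null_type <- match.arg(null_type)
  side <- match.arg(side)
  flavor <- match.arg(flavor)
  obs <- if (flavor == "modified") modified_t(mat) else pooled_t(mat)
  fit1 <- fit_marginal_fdr(obs$z1, side = side,
                           seed = if (is.null(seed)) NULL
                                  else child_seed(seed, 1))
  fit2 <- fit_marginal_fdr(obs$z2, side = "right",
                           seed = if (is.null(seed)) NULL
                                  else child_seed(seed, 2))
  dec <- kim_reject(fit1, fit2, null_type = null_type, alpha = alpha)
  dec$fit1 <- fit1
  dec$fit2 <- fit2
  dec$stats <- obs
  dec
}

#' Export a Kim decision as TSV
#'
#' Columns: feature_id, z1, z2, fdr_m1, fdr_m2, reject.
#' @param decision a \code{kim_decision} from \code{\link{kim_fdr2d}}.
#' @param path output file.
#' @export
write_kim_tsv <- function(decision, path) {
  st <- decision$stats
  df <- data.frame(
    feature_id = names(st$z1) %||% paste0("f", seq_along(st$z1)),
    z1 = st$z1, z2 = st$z2,
    fdr_m1 = decision$fit1$fdr_m, fdr_m2 = decision$fit2$fdr_m,
    reject = decision$reject
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
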