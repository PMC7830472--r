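#' Scenario configuration for the two-group Gaussian mixture generator
#'
#' Describes one simulation scenario for an m-feature, two-group expression
#' matrix under the two-component mixture f(z) = pi0 f0(z) + (1 - pi0) f1(z).
#' Null features are N(0, 1) in both groups; alternative features keep
#' N(0, 1) in group 2 and draw group 1 from N(+/- mu_eff, k * sigma_alt^2).
#'
#' Three scenarios are supported:
#' \describe{
#'   \item{basic}{well-separated alternatives, mu_eff = 2.5, k = 1.}
#'   \item{mean_shift}{mu_eff = \code{mu} (typically 1, 1.5 or 2), k = 1.}
#'   \item{scale_change}{mu_eff = 2.5 with inflated variance k * sigma_alt^2,
#'     k typically 2, 3 or 4.}
#' }
#' A two-sided scenario splits the alternative mass equally between the
#' +mu_eff and -mu_eff components (pi11 = pi12 = (1 - pi0) / 2); a one-sided
#' scenario puts all alternative mass on the positive side.
#'
#' @param scenario one of \code{"basic"}, \code{"mean_shift"},
#'   \code{"scale_change"}.
#' @param side \code{"two_sided"} (default) or \code{"one_sided"}.
#' @param m number of features (default 3000).
#' @param n_per_group samples per group (default 20).
#' @param pi0 proportion of true nulls in [0, 1] (default 0.8).
#' @param mu alternative mean magnitude; defaults to 2.5 for basic and
#'   scale_change, and must be supplied for mean_shift.
#' @param k variance multiplier for the alternative component (default 1;
#'   meaningful for scale_change).
#' @param sigma_alt alternative standard deviation base (default 1.5).
#' @param fix_counts if \code{TRUE}, the number of alternatives is fixed to
#'   round((1 - pi0) * m) (split equally between signs when two-sided)
#'   instead of being drawn per-feature.
#' @param seed optional RNG seed stored in the config and used by
#'   \code{\link{generate_scenario}}.
#' @return an object of class \code{scenario_config}.
#' @seealso \code{\link{generate_scenario}}, \code{\link{true_fdr1d}}
#' @export
scenario_config <- function(scenario = c("basic", "mean_shift", "scale_change"),
                            side = c("two_sided", "one_sided"),
                            m = 3000, n_per_group = 20, pi0 = 0.8,
                            mu = NULL, k = 1, sigma_alt = 1.5,
                            fix_counts = FALSE, seed = NULL) {
  scenario <- match.arg(scenario)
  side <- match.arg(side)
  if (is.null(mu)) {
    if (scenario == "mean_shift")
      stop("invalid `mu`: mean_shift scenario requires an explicit mu",
           call. = FALSE)
    mu <- 2.5
  }
  stop_field(is.numeric(m) && length(m) == 1 && m >= 1, "m", "need m >= 1")
  stop_field(is.numeric(n_per_group) && n_per_group >= 2, "n_per_group",
             "need at least 2 samples per group")
  stop_field(is.numeric(pi0) && pi0 >= 0 && pi0 <= 1, "pi0",
             "must lie in [0, 1]")
  stop_field(is.numeric(mu) && mu >= 0, "mu", "must be nonnegative")
  stop_field(is.numeric(k) && k >= 1, "k", "must be >= 1")
  stop_field(is.numeric(sigma_alt) && sigma_alt > 0, "sigma_alt",
             "must be positive")
  structure(
    list(scenario = scenario, side = side, m = as.integer(m),
         n_per_group = as.integer(n_per_group), pi0 = pi0, mu = mu, k = k,
         sigma_alt = sigma_alt, fix_counts = isTRUE(fix_counts), seed = seed),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config: %s (%s)\n", x$scenario, x$side))
  cat(sprintf("  m = %d features, %d + %d samples\n", x$m, x$n_per_group,
              x$n_per_group))
  cat(sprintf("  pi0 = %g, mu = %g, k = %g, sigma_alt = %g\n",
              x$pi0, x$mu, x$k, x$sigma_alt))
  invisible(x)
}

#' Generate one expression matrix under a scenario
#'
#' Draws an m x (2 n) matrix: null rows are i.i.d. N(0, 1) across all
#' samples; alternative rows keep group 2 at N(0, 1) and draw group 1 from
#' N(sign * mu_eff, k * sigma_alt^2).  Alternative membership is Bernoulli
#' per feature (probability 1 - pi0) unless \code{fix_counts} was set, in
#' which case exactly round((1 - pi0) m) rows are alternative.  For a
#' two-sided scenario the alternatives are split equally between signs.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param seed RNG seed; overrides \code{config$seed} when supplied.
#' @return a list with components
#'   \item{matrix}{an \code{expression_matrix}: \code{values} (m x 2n) and
#'     \code{group} (factor with levels G1, G2).}
#'   \item{truth}{a \code{truth_labels} data.frame with per-feature
#'     \code{is_alternative} and \code{direction} (none/positive/negative).}
#' @export
generate_scenario <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    m <- config$m
    n <- config$n_per_group
    mu_eff <- if (config$scenario == "mean_shift") config$mu else 2.5
    sd_alt <- sqrt(config$k) * config$sigma_alt

    if (config$fix_counts) {
      n_alt <- round((1 - config$pi0) * m)
      is_alt <- logical(m)
      is_alt[sample.int(m, n_alt)] <- TRUE
    } else {
      is_alt <- stats::runif(m) < (1 - config$pi0)
      n_alt <- sum(is_alt)
    }
    direction <- rep("none", m)
    if (n_alt > 0) {
      if (config$side == "two_sided") {
        # equal split of the alternative mass; odd leftover assigned at random
        signs <- rep(c(1, -1), length.out = n_alt)
        signs <- sample(signs)
      } else {
        signs <- rep(1, n_alt)
      }
      direction[is_alt] <- ifelse(signs > 0, "positive", "negative")
    }

    values <- matrix(stats::rnorm(m * 2L * n), nrow = m)
    if (n_alt > 0) {
      alt_idx <- which(is_alt)
      signed_mu <- ifelse(direction[alt_idx] == "positive", mu_eff, -mu_eff)
      values[alt_idx, seq_len(n)] <-
        stats::rnorm(n_alt * n, mean = rep(signed_mu, n), sd = sd_alt)
    }
    group <- factor(rep(c("G1", "G2"), each = n), levels = c("G1", "G2"))
    colnames(values) <- paste0(rep(c("G1_", "G2_"), each = n), rep(seq_len(n), 2))
    rownames(values) <- paste0("f", seq_len(m))

    mat <- structure(list(values = values, group = group),
                     class = "expression_matrix")
    truth <- structure(
      data.frame(feature = rownames(values), is_alternative = is_alt,
                 direction = factor(direction,
                                    levels = c("none", "positive", "negative")),
                 stringsAsFactors = FALSE),
      class = c("truth_labels", "data.frame")
    )
    list(matrix = mat, truth = truth)
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(table(x$group), collapse = " + ")))
  invisible(x)
}

#' Monte-Carlo oracle for the true local fdr of the pooled t-statistic
#'
#' Simulates \code{n_mc} t-statistics under the null component and
#' \code{n_mc} under the full mixture of \code{config}, forms kernel density
#' estimates f0 and f, and returns pi0 * f0(z) / f(z) on \code{z_grid},
#' clipped to [0, 1].  This stands in for an analytic true-fdr curve; its
#' accuracy is limited only by Monte-Carlo error at the chosen \code{n_mc}.
#'
#' @param z_grid statistic values at which to evaluate the true fdr.
#' @param config a \code{\link{scenario_config}}.
#' @param n_mc number of simulated features per component (>= 1e5).
#' @param seed RNG seed.
#' @return numeric vector of true fdr values in [0, 1] along \code{z_grid}.
#' @export
true_fdr1d <- function(z_grid, config, n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(z_grid) == 0) stop("empty z_grid", call. = FALSE)
  stop_field(n_mc >= 1e5, "n_mc", "need at least 1e5 Monte-Carlo draws")
  if (config$pi0 == 0) {
    # no null mass anywhere f > 0
    return(rep(0, length(z_grid)))
  }
  if (config$pi0 == 1) {
    # degenerate mixture: f == f0 identically
    return(rep(1, length(z_grid)))
  }
  with_seed(seed, {
    n <- config$n_per_group
    mu_eff <- if (config$scenario == "mean_shift") config$mu else 2.5
    sd_alt <- sqrt(config$k) * config$sigma_alt

    sim_t <- function(m, alt) {
      g2 <- matrix(stats::rnorm(m * n), m)
      if (alt) {
        if (config$side == "two_sided") {
          sgn <- sample(rep(c(1, -1), length.out = m))
        } else sgn <- rep(1, m)
        g1 <- matrix(stats::rnorm(m * n, mean = rep(sgn * mu_eff, n),
                                  sd = sd_alt), m)
      } else {
        g1 <- matrix(stats::rnorm(m * n), m)
      }
      m1 <- rowMeans(g1); m2 <- rowMeans(g2)
      s1 <- rowSums((g1 - m1)^2) / (n - 1)
      s2 <- rowSums((g2 - m2)^2) / (n - 1)
      se <- sqrt(((n - 1) * s1 + (n - 1) * s2) / (2 * n - 2)) * sqrt(2 / n)
      tt <- (m1 - m2) / se
      list(t = tt, se = se)
    }

    m0 <- as.integer(n_mc)
    null_draw <- sim_t(m0, alt = FALSE)
    n_alt <- round((1 - config$pi0) * m0)
    mix_t <- c(null_draw$t[seq_len(m0 - n_alt)],
               if (n_alt > 0) sim_t(n_alt, alt = TRUE)$t)
    # fresh null draw for f0 so the mixture's null half is not reused
    z0 <- sim_t(m0, alt = FALSE)$t

    rng <- range(z_grid, z0, mix_t)
    d0 <- stats::density(z0, from = rng[1], to = rng[2], n = 1024)
    d1 <- stats::density(mix_t, from = rng[1], to = rng[2], n = 1024)
    f0 <- stats::approx(d0$x, d0$y, xout = z_grid, rule = 2)$y
    f <- stats::approx(d1$x, d1$y, xout = z_grid, rule = 2)$y
    clip(config$pi0 * f0 / pmax(f, .Machine$double.eps), 0, 1)
  })
}

#' Read a scenario configuration from a plain key-value file
#'
#' Accepts lines of the form \code{key: value} or \code{key = value};
#' blank lines and lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return a \code{\link{scenario_config}}.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  cfg <- as.list(vals)
  names(cfg) <- keys
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  scenario_config(
    scenario = cfg$scenario %||% "basic",
    side = cfg$side %||% "two_sided",
    m = num(cfg$m) %||% 3000,
    n_per_group = num(cfg$n_per_group) %||% 20,
    pi0 = num(cfg$pi0) %||% 0.8,
    mu = num(cfg$mu),
    k = num(cfg$k) %||% 1,
    sigma_alt = num(cfg$sigma_alt) %||% 1.5,
    fix_counts = isTRUE(tolower(cfg$fix_counts %||% "false") %in%
                          c("true", "yes", "1")),
    seed = if (!is.null(cfg$seed)) as.integer(num(cfg$seed)) else NULL
  )
}
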