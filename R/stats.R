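#' Per-feature two-sample summaries
#'
#' @param values m x n numeric matrix.
#' @param group factor/character of length n with exactly two levels.
#' @return list of per-group means, variances and sizes.
#' @noRd
group_summaries <- function(values, group) {
  group <- as.factor(group)
  lev <- levels(group)
  if (length(lev) != 2)
    stop("group must have exactly two levels", call. = FALSE)
  i1 <- which(group == lev[1]); i2 <- which(group == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  g1 <- values[, i1, drop = FALSE]; g2 <- values[, i2, drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  list(mean1 = m1, mean2 = m2, var1 = v1, var2 = v2, n1 = n1, n2 = n2)
}

pooled_se <- function(s) {
  sqrt(((s$n1 - 1) * s$var1 + (s$n2 - 1) * s$var2) / (s$n1 + s$n2 - 2)) *
    sqrt(1 / s$n1 + 1 / s$n2)
}

bivariate_from_summaries <- function(s, flavor, a0 = NULL,
                                     a0_percentile = NULL) {
  se <- pooled_se(s)
  diff <- s$mean1 - s$mean2
  zero_var <- se <= 0
  if (any(zero_var)) {
    # zero-variance features: t := 0 and log(se) := log of the smallest
    # positive se so downstream binning never sees -Inf
    min_se <- suppressWarnings(min(se[!zero_var]))
    if (!is.finite(min_se)) min_se <- .Machine$double.eps
    se[zero_var] <- min_se
    diff[zero_var] <- 0
  }
  if (flavor == "modified") {
    if (is.null(a0)) a0 <- stats::quantile(se, a0_percentile / 100,
                                           names = FALSE)
    z1 <- diff / (se + a0)
  } else {
    a0 <- NULL
    z1 <- diff / se
  }
  structure(
    list(z1 = z1, z2 = log(se), flavor = flavor, a0 = a0, se = se,
         zero_variance = zero_var, summaries = s),
    class = "bivariate_stats"
  )
}

#' Classic pooled-variance two-sample t and log standard error
#'
#' Computes, per feature, t = (mean(G1) - mean(G2)) / se with the pooled
#' standard error
#' se = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)) * sqrt(1/n1 + 1/n2),
#' and the second coordinate z2 = log(se).  Features with zero variance in
#' both groups get t = 0 and the log of the smallest positive se (flagged
#' in \code{zero_variance}).
#'
#' @param mat an \code{expression_matrix} (list with \code{values},
#'   \code{group}) as returned by \code{\link{generate_scenario}} or
#'   \code{\link{load_matrix}}.
#' @return a \code{bivariate_stats} object with \code{z1} (t), \code{z2}
#'   (log se), \code{flavor = "classic"}.
#' @export
pooled_t <- function(mat) {
  s <- group_summaries(mat$values, mat$group)
  bivariate_from_summaries(s, "classic")
}

#' Modified (offset) t-statistic
#'
#' t = (mean(G1) - mean(G2)) / (se + a0) where a0 is the
#' \code{a0_percentile}-th percentile of the per-feature pooled standard
#' errors.  The offset damps the inflation of t for features whose standard
#' error happens to be tiny.
#'
#' @inheritParams pooled_t
#' @param a0_percentile percentile (0-100) of the se distribution used for
#'   the offset; default 90.
#' @param a0 optional fixed offset overriding the percentile rule.
#' @return a \code{bivariate_stats} object with \code{flavor = "modified"}
#'   and the realized \code{a0}.
#' @export
modified_t <- function(mat, a0_percentile = 90, a0 = NULL) {
  stop_field(a0_percentile >= 0 && a0_percentile <= 100, "a0_percentile",
             "must lie in [0, 100]")
  s <- group_summaries(mat$values, mat$group)
  bivariate_from_summaries(s, "modified", a0 = a0,
                           a0_percentile = a0_percentile)
}

#' @export
print.bivariate_stats <- function(x, ...) {
  cat(sprintf("bivariate_stats (%s): %d features", x$flavor, length(x$z1)))
  if (!is.null(x$a0)) cat(sprintf(", a0 = %.4g", x$a0))
  cat("\n")
  invisible(x)
}

#' Permutation null scores
#'
#' Generates B replicate statistic sets under the null by permuting the
#' column group labels uniformly at random (mode \code{"label"}; the only
#' mode valid for unpaired two-group matrices).  Statistics are recomputed
#' with the requested flavor.  For the modified flavor the offset a0 is by
#' default frozen at the observed-data value, so the permuted datasets are
#' scored by exactly the same statistic function as the observed one (the
#' permutation-test principle; freezing also preserves the upper-bound
#' behavior of the interval pi0 estimate).  \code{freeze_a0 = FALSE}
#' re-derives a0 within each permutation instead.
#'
#' @inheritParams pooled_t
#' @param B number of permutations (>= 1).
#' @param mode \code{"label"}; \code{"sign"} is reserved for paired
#'   differences and rejected for two-group matrices.
#' @param flavor \code{"classic"} or \code{"modified"}.
#' @param a0_percentile percentile for the modified flavor.
#' @param freeze_a0 reuse the observed-data a0 inside permutations.
#' @param a0 optional fixed offset for the modified flavor, overriding both
#'   the percentile rule and per-permutation recomputation.
#' @param seed RNG seed.
#' @param permutations optional integer matrix (ncol(values) x B) of column
#'   orders, overriding random draws — used for testing (e.g. injecting the
#'   identity permutation).
#' @return a \code{null_scores} object: matrices \code{z1}, \code{z2}
#'   (m x B), the mode, flavor and per-permutation \code{a0}.
#' @export
permutation_null_scores <- function(mat, B = 20,
                                    mode = c("label", "sign"),
                                    flavor = c("classic", "modified"),
                                    a0_percentile = 90, freeze_a0 = TRUE,
                                    a0 = NULL, seed = NULL,
                                    permutations = NULL) {
  mode <- match.arg(mode)
  flavor <- match.arg(flavor)
  stop_field(B >= 1, "B", "need at least one permutation")
  if (mode == "sign")
    stop("sign permutation requires paired-difference input; ",
         "use mode = \"label\" for two-group matrices", call. = FALSE)
  values <- mat$values
  group <- mat$group
  nc <- ncol(values)
  m <- nrow(values)
  a0_fixed <- a0
  if (flavor == "modified" && freeze_a0 && is.null(a0_fixed)) {
    a0_fixed <- modified_t(mat, a0_percentile)$a0
  }
  with_seed(seed, {
    z1 <- matrix(NA_real_, m, B)
    z2 <- matrix(NA_real_, m, B)
    a0s <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      ord <- if (!is.null(permutations)) permutations[, b] else sample.int(nc)
      s <- group_summaries(values, group[ord])
      st <- bivariate_from_summaries(s, flavor, a0 = a0_fixed,
                                     a0_percentile = a0_percentile)
      z1[, b] <- st$z1
      z2[, b] <- st$z2
      if (!is.null(st$a0)) a0s[b] <- st$a0
    }
    structure(
      list(z1 = z1, z2 = z2, B = B, mode = mode, flavor = flavor, a0 = a0s),
      class = "null_scores"
    )
  })
}

#' @export
print.null_scores <- function(x, ...) {
  cat(sprintf("null_scores: B = %d %s permutations, flavor %s, m = %d\n",
              x$B, x$mode, x$flavor, nrow(x$z1)))
  invisible(x)
}

#' Export per-feature statistics as TSV
#'
#' Columns: feature_id, t, log_se, flavor, a0.
#' @param stats a \code{bivariate_stats}.
#' @param path output file.
#' @export
write_stats_tsv <- function(stats, path) {
  df <- data.frame(
    feature_id = names(stats$z1) %||% paste0("f", seq_along(stats$z1)),
    t = stats$z1, log_se = stats$z2, flavor = stats$flavor,
    a0 = if (is.null(stats$a0)) NA_real_ else stats$a0
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
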