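#' Confusion counts against known truth labels
#'
#' @param reject logical per-feature rejection decision.
#' @param truth a \code{truth_labels} data.frame (or logical
#'   \code{is_alternative} vector).
#' @return a \code{confusion_counts}: m, m0, V (false rejections), R
#'   (rejections), T (false non-rejections).
#' @export
confusion <- function(reject, truth) {
  is_alt <- if (is.data.frame(truth)) truth$is_alternative else truth
  if (length(reject) != length(is_alt))
    stop("reject and truth have different lengths", call. = FALSE)
  reject <- as.logical(reject)
  m <- length(reject)
  m0 <- sum(!is_alt)
  V <- sum(reject & !is_alt)
  R <- sum(reject)
  structure(
    list(m = m, m0 = m0, V = V, R = R, T = sum(!reject & is_alt)),
    class = "confusion_counts"
  )
}

#' Classification metrics from confusion counts
#'
#' sensitivity = (R - V) / (m - m0); specificity = (m0 - V) / m0;
#' accuracy = (true decisions) / m; F1 = harmonic mean of precision
#' (R - V)/R and sensitivity; fdp = V / R with the 0/0 = 0 convention.
#' Undefined ratios (m0 = 0, no alternatives, R = 0) are reported as the
#' conventional values noted per field.
#'
#' @param cc a \code{confusion_counts}.
#' @return named list: sensitivity, specificity, accuracy, f1, fdp,
#'   precision.
#' @export
metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  m1 <- cc$m - cc$m0
  tp <- cc$R - cc$V
  sens <- if (m1 > 0) tp / m1 else NA_real_
  spec <- if (cc$m0 > 0) (cc$m0 - cc$V) / cc$m0 else NA_real_
  acc <- ((cc$m0 - cc$V) + tp) / cc$m
  prec <- if (cc$R > 0) tp / cc$R else NA_real_
  f1 <- if (cc$R > 0 && is.finite(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else 0
  fdp <- if (cc$R > 0) cc$V / cc$R else 0
  list(sensitivity = if (is.na(sens)) NA_real_ else sens,
       specificity = spec, accuracy = acc, f1 = f1, fdp = fdp,
       precision = prec)
}

# All five procedures on one generated dataset; Ploner1d shares the
# classic-flavor surface with Ploner2d and Ploner1dE refits with the
# modified flavor, so a full run costs two smoothing fits, one Efron fit
# and one Kim fit.
method_registry <- function() {
  c("efron", "ploner1d", "ploner1dE", "ploner2d", "kim_intersection",
    "kim_union")
}

run_methods_once <- function(mat, methods, side, seed,
                             B_efron = 20, B_ploner = 100,
                             nx = 30, ny = 30, lambda = 1) {
  kim_side <- if (side == "one_sided") "right" else "two_sided"
  out <- list()
  errors <- list()
  try_method <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) errors[[name]] <<- conditionMessage(res)
    else out[[name]] <<- res
  }
  if ("efron" %in% methods)
    try_method("efron",
               efron_fdr1d(mat, B = B_efron, seed = child_seed(seed, 101))$fdr)
  if (any(c("ploner2d", "ploner1d") %in% methods)) {
    try_method("ploner2d_surface",
               ploner_fdr2d(mat, B = B_ploner, nx = nx, ny = ny,
                            lambda = lambda, seed = child_seed(seed, 102)))
    surf <- out$ploner2d_surface
    if (!is.null(surf)) {
      if ("ploner2d" %in% methods) out$ploner2d <- surf$fdr2d
      if ("ploner1d" %in% methods)
        try_method("ploner1d", ploner_fdr1d(surf)$fdr)
    }
    out$ploner2d_surface <- NULL
  }
  if ("ploner1dE" %in% methods)
    try_method("ploner1dE",
               ploner_fdr1dE(mat, B = B_ploner, nx = nx, ny = ny,
                             lambda = lambda,
                             seed = child_seed(seed, 103))$fdr)
  # Kim produces decisions, not an fdr vector: one decision per cutoff is
  # taken downstream, so here we return the marginal fits
  if (any(startsWith(methods, "kim")))
    try_method("kim_fits", {
      obs <- pooled_t(mat)
      list(fit1 = fit_marginal_fdr(obs$z1, side = kim_side,
                                   seed = child_seed(seed, 104)),
           fit2 = fit_marginal_fdr(obs$z2, side = "right",
                                   seed = child_seed(seed, 105)))
    })
  list(fdr = out, errors = errors)
}

reject_at_cutoff <- function(method, once, cutoff) {
  if (startsWith(method, "kim")) {
    fits <- once$fdr$kim_fits
    if (is.null(fits)) return(NULL)
    type <- sub("kim_", "", method)
    dec <- kim_reject(fits$fit1, fits$fit2, null_type = type,
                      alpha = cutoff)
    dec$reject
  } else {
    f <- once$fdr[[method]]
    if (is.null(f)) return(NULL)
    f <= cutoff
  }
}

#' Repetition benchmark over scenarios, methods and cutoffs
#'
#' For each repetition: generate a dataset from each scenario config, run
#' every requested method once, threshold the fdr (or run the Kim decision)
#' at every cutoff, and accumulate confusion counts.  Reports the mean and
#' standard error (sd / sqrt(reps)) of the realized false-discovery
#' proportion V/R per (scenario, method, cutoff) cell, rejection counts per
#' repetition, and an FWER estimate (fraction of repetitions with V >= 1).
#' Method failures on individual repetitions are recorded and excluded from
#' that method's aggregates.
#'
#' @param configs list of \code{\link{scenario_config}}s (or a single one).
#' @param methods character vector among \code{"efron"}, \code{"ploner1d"},
#'   \code{"ploner1dE"}, \code{"ploner2d"}, \code{"kim_intersection"},
#'   \code{"kim_union"}.
#' @param cutoffs numeric vector of fdr cutoffs (default 0.05, 0.1, 0.2).
#' @param reps repetitions (default 100).
#' @param master_seed master RNG seed; repetition r uses
#'   \code{child_seed(master_seed, r)}.
#' @param B_efron,B_ploner,nx,ny,lambda method controls passed through.
#' @param verbose emit per-repetition progress to stderr.
#' @return a \code{benchmark_result}: a long data.frame \code{cells} with
#'   columns scenario, method, cutoff, mean_fdp, se_fdp, fwer, reps_used;
#'   a data.frame \code{rejections} of per-repetition rejection counts; and
#'   the per-repetition confusion tallies in \code{raw}.
#' @export
run_benchmark <- function(configs, methods = method_registry(),
                          cutoffs = c(0.05, 0.1, 0.2), reps = 100,
                          master_seed = 1, B_efron = 20, B_ploner = 100,
                          nx = 30, ny = 30, lambda = 1, verbose = FALSE) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  stop_field(reps >= 1, "reps", "need at least one repetition")
  methods <- match.arg(methods, method_registry(), several.ok = TRUE)
  scen_names <- vapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    nm <- names(configs)[i]
    if (!is.null(nm) && nzchar(nm)) nm
    else sprintf("%s_%s_mu%g_k%g", cfg$scenario, cfg$side, cfg$mu, cfg$k)
  }, "")

  raw <- list()
  for (s in seq_along(configs)) {
    cfg <- configs[[s]]
    for (r in seq_len(reps)) {
      seed_r <- child_seed(master_seed, (s - 1) * 100000 + r)
      gen <- generate_scenario(cfg, seed = seed_r)
      once <- run_methods_once(gen$matrix, methods, cfg$side,
                               seed = seed_r, B_efron = B_efron,
                               B_ploner = B_ploner, nx = nx, ny = ny,
                               lambda = lambda)
      if (verbose)
        message(sprintf("[%s] rep %d/%d%s", scen_names[s], r, reps,
                        if (length(once$errors))
                          paste0(" (failed: ",
                                 paste(names(once$errors), collapse = ", "),
                                 ")") else ""))
      for (meth in methods) {
        for (cu in cutoffs) {
          rej <- reject_at_cutoff(meth, once, cu)
          if (is.null(rej)) next
          cc <- confusion(rej, gen$truth)
          raw[[length(raw) + 1]] <- data.frame(
            scenario = scen_names[s], method = meth, cutoff = cu, rep = r,
            V = cc$V, R = cc$R, m = cc$m, m0 = cc$m0,
            fdp = if (cc$R > 0) cc$V / cc$R else 0
          )
        }
      }
    }
  }
  raw <- do.call(rbind, raw)
  agg <- do.call(rbind, lapply(
    split(raw, list(raw$scenario, raw$method, raw$cutoff), drop = TRUE),
    function(d) {
      data.frame(
        scenario = d$scenario[1], method = d$method[1], cutoff = d$cutoff[1],
        mean_fdp = mean(d$fdp),
        se_fdp = if (nrow(d) > 1) stats::sd(d$fdp) / sqrt(nrow(d))
                 else NA_real_,
        fwer = mean(d$V >= 1), mean_R = mean(d$R), reps_used = nrow(d)
      )
    }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$scenario, agg$method, agg$cutoff), ]
  structure(
    list(cells = agg,
         rejections = raw[, c("scenario", "method", "cutoff", "rep", "R")],
         raw = raw, reps = reps, master_seed = master_seed),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d reps, master seed %d\n", x$reps,
              x$master_seed))
  cells <- x$cells
  cells$mean_fdp <- sprintf("%.4f", cells$mean_fdp)
  cells$se_fdp <- sprintf("%.5f", cells$se_fdp)
  print(cells[, c("scenario", "method", "cutoff", "mean_fdp", "se_fdp",
                  "reps_used")], row.names = FALSE)
  invisible(x)
}

#' ROC points over an fdr-cutoff grid
#'
#' @param fdr_values per-feature fdr (or, for Kim, a function of cutoff —
#'   see \code{reject_fun}).
#' @param truth a \code{truth_labels} or logical vector.
#' @param cutoffs cutoff grid (default 0 to 1 in steps of 0.05).
#' @param reject_fun optional function(cutoff) -> logical rejection vector,
#'   overriding thresholding of \code{fdr_values}.
#' @return data.frame with cutoff, fpr, tpr, sorted by cutoff.
#' @export
roc_curve <- function(fdr_values, truth, cutoffs = seq(0, 1, by = 0.05),
                      reject_fun = NULL) {
  is_alt <- if (is.data.frame(truth)) truth$is_alternative else truth
  if (is.null(reject_fun) && length(fdr_values) != length(is_alt))
    stop("fdr_values and truth have different lengths", call. = FALSE)
  pts <- lapply(cutoffs, function(cu) {
    rej <- if (is.null(reject_fun)) fdr_values <= cu else reject_fun(cu)
    cc <- confusion(rej, is_alt)
    m1 <- cc$m - cc$m0
    data.frame(cutoff = cu,
               fpr = if (cc$m0 > 0) cc$V / cc$m0 else NA_real_,
               tpr = if (m1 > 0) (cc$R - cc$V) / m1 else NA_real_)
  })
  out <- do.call(rbind, pts)
  out[order(out$cutoff), ]
}

#' Load an expression matrix from TSV
#'
#' Expects a header row of sample labels of the form \code{<group>_<idx>}
#' (e.g. G1_1 ... G2_20) or arbitrary labels plus an explicit \code{group}
#' argument; rows are features, the first column may hold feature ids.
#'
#' @param path TSV file.
#' @param group optional explicit per-column group labels overriding the
#'   header-derived ones.
#' @return an \code{expression_matrix}.
#' @export
load_matrix <- function(path, group = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a header and >= 2 columns",
                         call. = FALSE)
  if (!is.numeric(df[[1]])) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
  } else rn <- paste0("f", seq_len(nrow(df)))
  non_num <- !vapply(df, is.numeric, TRUE)
  if (any(non_num))
    stop(sprintf("non-numeric cells in column(s): %s",
                 paste(names(df)[non_num], collapse = ", ")), call. = FALSE)
  values <- as.matrix(df)
  rownames(values) <- rn
  if (is.null(group)) group <- sub("_[^_]*$", "", colnames(values))
  group <- factor(group)
  if (nlevels(group) != 2)
    stop(sprintf("expected 2 groups in header, found %d (%s)",
                 nlevels(group),
                 paste(utils::head(levels(group), 5), collapse = ", ")),
         call. = FALSE)
  structure(list(values = values, group = group),
            class = "expression_matrix")
}

#' Write an expression matrix as TSV
#'
#' Header row holds \code{<group>_<idx>} sample labels so the file
#' round-trips through \code{\link{load_matrix}}.
#' @param mat an \code{expression_matrix}.
#' @param path output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  values <- mat$values
  if (is.null(colnames(values))) {
    idx <- stats::ave(seq_along(mat$group), mat$group, FUN = seq_along)
    colnames(values) <- paste0(as.character(mat$group), "_", idx)
  }
  df <- data.frame(feature_id = rownames(values) %||%
                     paste0("f", seq_len(nrow(values))),
                   values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
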