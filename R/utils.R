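# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip a numeric vector into an interval
#' @noRd
clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Restores (or removes) the global `.Random.seed` afterwards so callers
#' never perturb the session RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and a counter
#'
#' Deterministic Lehmer-style mixing so that repetition `r` of a seeded run
#' is reproducible in isolation; result always lies in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param r nonnegative integer counter (repetition index).
#' @return an integer seed.
#' @export
child_seed <- function(master, r) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(master) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + as.double(r) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 1) + 1)
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
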