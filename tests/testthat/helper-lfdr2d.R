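# Shared fixtures: everything is generated in code, no stored data.

# A small all-null matrix (every row N(0,1) in both groups).
null_matrix <- function(m = 200, n = 10, seed = 1) {
  gen <- generate_scenario(
    scenario_config("basic", m = m, n_per_group = n, pi0 = 1),
    seed = seed
  )
  gen$matrix
}

# A tiny two-group matrix from explicit values (rows = features).
tiny_matrix <- function(g1, g2) {
  g1 <- rbind(g1); g2 <- rbind(g2)
  values <- cbind(g1, g2)
  colnames(values) <- c(paste0("G1_", seq_len(ncol(g1))),
                        paste0("G2_", seq_len(ncol(g2))))
  rownames(values) <- paste0("f", seq_len(nrow(values)))
  structure(
    list(values = values,
         group = factor(rep(c("G1", "G2"), c(ncol(g1), ncol(g2))))),
    class = "expression_matrix"
  )
}

# Scalar reference implementation of the pooled-t / log-se formulas,
# independent of the vectorized production path.
pooled_t_scalar <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  se <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
               (n1 + n2 - 2)) * sqrt(1 / n1 + 1 / n2)
  list(t = (mean(x1) - mean(x2)) / se, se = se)
}

# Hand-built null_scores object from an m x B matrix of z1 (and optional z2).
fake_nulls <- function(z1, z2 = NULL, flavor = "classic") {
  z1 <- as.matrix(z1)
  structure(
    list(z1 = z1, z2 = if (is.null(z2)) z1 else as.matrix(z2),
         B = ncol(z1), mode = "label", flavor = flavor),
    class = "null_scores"
  )
}

# Hand-built marginal fit carrying an arbitrary fdr vector.
fake_marginal <- function(fdr_m) {
  structure(list(side = "two_sided", pi0_m = 0.8, mu0 = 0, sigma0 = 1,
                 fdr_m = fdr_m, values = seq_along(fdr_m)),
            class = "marginal_fdr_fit")
}
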