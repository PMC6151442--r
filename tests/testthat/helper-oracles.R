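# Independent plain-R oracle for the cassette model: concentration
# addition within cassettes, response addition across them. Kept separate
# from the package's compiled kernel on purpose.
olmstead_oracle <- function(conc, ec50, power, labels) {
  if (!is.matrix(conc)) conc <- matrix(conc, nrow = 1)
  apply(conc, 1, function(cr) {
    surv <- 1
    for (g in seq_len(max(labels))) {
      s <- sum(cr[labels == g] / ec50[labels == g])
      e <- if (s > 0) s^power[g] / (1 + s^power[g]) else 0
      surv <- surv * (1 - e)
    }
    1 - surv
  })
}

# Exhaustive log-spaced grid search over (ec50s, powers); the brute-force
# oracle for the multi-start fit on small instances. Vectorized over all
# potency combinations, looping only over the power grid.
grid_fit_oracle <- function(X, y, labels, n_grid = 51) {
  m <- max(labels); p <- ncol(X); n <- nrow(X)
  ec_grid <- 10^seq(-3, 3, length.out = n_grid)
  pw_grid <- 10^seq(-1, 1, length.out = n_grid)
  combos <- as.matrix(expand.grid(rep(list(seq_len(n_grid)), p)))
  S <- lapply(seq_len(m), function(g) {
    out <- matrix(0, n, nrow(combos))
    for (j in which(labels == g))
      out <- out + X[, j] %o% (1 / ec_grid)[combos[, j]]
    out
  })
  pw_combos <- as.matrix(expand.grid(rep(list(pw_grid), m)))
  best <- Inf
  for (k in seq_len(nrow(pw_combos))) {
    surv <- matrix(1, n, nrow(combos))
    for (g in seq_len(m))
      surv <- surv / (1 + S[[g]]^pw_combos[k, g])   # 1 - E_g
    rmse <- sqrt(colMeans(((1 - surv) - y)^2))
    best <- min(best, rmse)
  }
  best
}

# Do two labellings describe the same partition (up to relabelling)?
same_partition <- function(a, b) {
  tab <- table(a, b)
  sum(apply(tab, 1, max)) == length(a) && sum(apply(tab, 2, max)) == length(a)
}

# Small random joint-action instance used by property loops.
random_instance <- function(n_feat, n_samp = 5) {
  list(conc = matrix(runif(n_samp * n_feat, 0, 3), n_samp, n_feat),
       ec50 = runif(n_feat, 0.2, 5),
       power = NULL)
}
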