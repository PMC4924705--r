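# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops and grid searches only.

# Brute-force topological overlap via the explicit triple loop.
tom_brute_force <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      u <- setdiff(seq_len(n), c(i, j))
      l_ij <- sum(a[i, u] * a[u, j])
      k_i <- sum(a[i, -i])
      k_j <- sum(a[j, -j])
      out[i, j] <- (l_ij + a[i, j]) / (min(k_i, k_j) + 1 - a[i, j])
    }
  }
  out
}

# Random valid adjacency matrix (symmetric, unit diagonal, entries in [0,1]).
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Grid-search maximization of the Breslow log partial likelihood,
# vectorized over the grid.
cox_grid_oracle <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  ord <- order(-time)
  t_s <- time[ord]; e_s <- event[ord]; xs <- x[ord]
  r <- rle(t_s)
  ri <- rep(cumsum(r$lengths), r$lengths)
  ev <- which(e_s == 1)
  E <- exp(outer(grid, xs))                        # grid x n
  S0 <- t(apply(E, 1L, cumsum))[, ri, drop = FALSE]
  ll <- grid * sum(xs[ev]) - rowSums(log(S0[, ev, drop = FALSE]))
  grid[which.max(ll)]
}

# Small random survival dataset guaranteed to have an interior, converged
# Cox maximum (regenerates until the fit is usable for oracle comparison).
random_cox_dataset <- function() {
  repeat {
    n <- sample(8:12, 1)
    x <- stats::rnorm(n)
    time <- stats::rexp(n, exp(0.5 * x))
    event <- stats::rbinom(n, 1, 0.8)
    if (sum(event) < 2) next
    fit <- fit_cox(time, event, x)
    if (fit$converged && abs(fit$beta) < 4.5)
      return(list(time = time, event = event, x = x, fit = fit))
  }
}

# Planted two-layer development data used by several modules.
planted_development <- function(seed = 1, rho = 0.9, agreement = 0.6) {
  spec <- development_sim_spec(c(40, 40, 40),
                               c("early", "middle", "late"),
                               rho = rho, mrna_agreement = agreement)
  simulate_development(spec, seed = seed)
}

expect_no_error <- function(expr) expect_error(expr, NA)
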