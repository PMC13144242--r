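# Independent oracles used by the tests. The grid-search polychoric below
# recomputes the bivariate-normal cell probabilities directly (per-cell
# rectangle integrals, a different construction from the package's CDF
# differencing) and maximises the likelihood by brute force.

oracle_cell_probs <- function(tx, ty, rho) {
  a <- c(-Inf, tx, Inf)
  b <- c(-Inf, ty, Inf)
  corr <- matrix(c(1, rho, rho, 1), 2)
  P <- matrix(0, length(a) - 1, length(b) - 1)
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      P[i, j] <- mvtnorm::pmvnorm(lower = c(a[i], b[j]),
                                  upper = c(a[i + 1], b[j + 1]),
                                  corr = corr, keepAttr = FALSE)
    }
  }
  P
}

oracle_loglik <- function(rho, tab, tx, ty) {
  sum(tab * log(pmax(oracle_cell_probs(tx, ty, rho), 1e-300)))
}

# brute-force ML over rho: coarse pass at 0.01, then an exhaustive fine grid
# at step 1e-4 around the coarse maximum
grid_polychoric <- function(tab, tx, ty) {
  coarse <- seq(-0.99, 0.99, by = 0.01)
  ll <- vapply(coarse, oracle_loglik, numeric(1), tab = tab, tx = tx, ty = ty)
  best <- coarse[which.max(ll)]
  fine <- seq(max(-0.9999, best - 0.012), min(0.9999, best + 0.012),
              by = 1e-4)
  llf <- vapply(fine, oracle_loglik, numeric(1), tab = tab, tx = tx, ty = ty)
  fine[which.max(llf)]
}

# margin thresholds of a contingency table (shared input for both routes)
margin_thresholds <- function(counts) {
  qnorm(cumsum(counts)[-length(counts)] / sum(counts))
}

# grid-row lookup used by the Monte Carlo acceptance checks
grid_condition <- function(grid, pattern, slope, categories, n) {
  grid[grid$pattern == pattern & grid$slope == slope &
         grid$categories == categories & grid$n == n, , drop = FALSE]
}
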