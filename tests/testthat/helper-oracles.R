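# independent brute-force oracles for the exact tests

# two-sided Mann-Whitney p by explicit enumeration of all group assignments
enumerate_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  rk <- rank(pooled, ties.method = "average")
  idx <- utils::combn(n, n1)
  W_all <- apply(idx, 2, function(i) sum(rk[i]))
  W_obs <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# two-sided Spearman p by explicit enumeration of all orderings
enumerate_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho_obs <- stats::cor(rx, ry)
  perms <- syndrs:::permutations(n)
  rho_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}
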