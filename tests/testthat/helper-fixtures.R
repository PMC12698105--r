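# Shared fixtures: milk-phantom optical properties and small helpers.

phantom_props <- function() optical_properties(mu_a = 0.0025, mu_s_prime = 1.0,
                                               n0 = 1.33, wavelength = 785)

# least-squares fit of 1 + beta * exp(-2 Gamma tau) to an estimated curve
fit_exponential_g2 <- function(curve, beta0 = 0.5, Gamma0 = 3000) {
  fit <- minpack.lm::nls.lm(
    par = c(beta = beta0, Gamma = Gamma0),
    fn = function(p) 1 + p[1] * exp(-2 * p[2] * curve$tau) - curve$g2)
  list(beta = fit$par[[1]], Gamma = fit$par[[2]])
}

# direct O(N*L) multi-tau estimator, written independently of the package
# internals: re-bins by plain loops and uses the same symmetric normalization
brute_force_multitau <- function(counts, scheme) {
  lags <- multi_tau_lags(scheme)
  g2 <- numeric(nrow(lags))
  cb <- counts
  for (b in seq_len(scheme$n_blocks)) {
    if (b > 1) {
      f <- scheme$widening_factor
      n_full <- length(cb) %/% f
      nb <- numeric(n_full)
      for (j in seq_len(n_full)) nb[j] <- sum(cb[((j - 1) * f + 1):(j * f)])
      cb <- nb
    }
    for (i in which(lags$block == b)) {
      k <- lags$lag_index[i]
      n <- length(cb)
      acc <- 0
      for (t in seq_len(n - k)) acc <- acc + cb[t] * cb[t + k]
      g2[i] <- (acc / (n - k)) /
        (mean(cb[seq_len(n - k)]) * mean(cb[(k + 1):n]))
    }
  }
  g2
}
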