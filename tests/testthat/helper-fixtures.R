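# shared generators and independent oracles for the test suite

# random valid sensor parameters over the default sampled bias windows
random_params <- function(n = NULL, N = 100L) {
  if (is.null(n)) n <- sample(c(1L, 2L, 4L, 8L), 1L)
  sensor_params(K = 10^runif(1, 0, 6), c = 10^runif(1, -6, -1e-3),
                n = n, N = N)
}

# independent threshold oracle: bracketed root search on the monotone
# activity curve (never the closed-form inversion used by the package)
threshold_oracle <- function(params) {
  bs <- basal_saturation(params)
  m <- (bs[["basal"]] + bs[["saturation"]]) / 2
  f <- function(x) equilibrium_activity(params, x) - m
  hi <- params$K^(1 / params$n)
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, lower = 0, upper = hi, tol = 1e-13 * max(hi, 1))$root
}

# centred finite-difference logit slope of the normalized response in log x
hill_oracle <- function(params, rel_h = 1e-5) {
  x0 <- threshold_oracle(params)
  bs <- basal_saturation(params)
  r <- bs[["saturation"]] - bs[["basal"]]
  ghat <- function(x) (equilibrium_activity(params, x) - bs[["basal"]]) / r
  logit <- function(g) log(g / (1 - g))
  (logit(ghat(x0 * exp(rel_h))) - logit(ghat(x0 * exp(-rel_h)))) / (2 * rel_h)
}

# the printed high-basal tetramer rate set (K = 2, c = 0.1)
rates_high_basal <- function() {
  kinetic_rates(f_R = 0.01, b_R = 10, f_T = 0.01, b_T = 100,
                f_L = sqrt(2), b_L = 1 / sqrt(2))
}

# the printed small-pool tetramer rate set (K = 100, c = 0.01)
rates_small_pool <- function() {
  kinetic_rates(f_R = 0.01, b_R = 1, f_T = 0.01, b_T = 100,
                f_L = 10, b_L = 0.1)
}

# a generic random rate set consistent with given biases (f_R != f_T almost
# surely, avoiding the degenerate relative-degree case)
random_rates <- function(K, c, n = 1L, topology = "L_only", seed = NULL) {
  complete_rates(K, c, n = n, topology = topology, seed = seed)
}
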