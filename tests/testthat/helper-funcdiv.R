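# Shared helpers: small random states and quiet parameter construction.

rand_tally <- function(d_max = 12, k_max = 30) {
  d <- sample.int(d_max, 1)
  function_tally(sample.int(k_max, d, replace = TRUE))
}

quiet_params <- function(p0 = 1, theta = 0, gamma = 1) {
  model_params(p0 = p0, theta = theta, gamma = gamma, quiet = TRUE)
}

# Exact expected diversity for theta = 1: increments are independent
# Bernoulli(min(1, p0/n)) at pre-arrival sizes n = n0..N-1.
exact_mean_diversity_theta1 <- function(n_final, n0 = 1, d0 = 1, p0 = 1) {
  n <- seq.int(n0, n_final - 1)
  d0 + sum(pmin(1, p0 / n))
}
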