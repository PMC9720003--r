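# Shared fixtures and independent oracles for the test suite.

# Measured growth parameters of the reference plasmid-host pair.
measured_intraday <- function(gamma = exp(0.435435 * 6.074089)) {
  intraday_params(r = 0.435435, rho_n = 0.052334, sigma = 6.074089, n = 19,
                  gamma = gamma)
}

# Interday parameters at the published (rounded) precision.
measured_params <- function(alpha = 0) {
  model_params(n = 19, kappa_n = 0.272313, mu_n = 5.938e-6, alpha = alpha)
}

# Fixed-point iteration oracle: run the pulsed day map to numerical
# convergence, independent of the closed-form steady state.
iterate_to_fixed_point <- function(params, x0 = 0.5, tol = 1e-12,
                                   max_iter = 1e6) {
  x <- x0
  for (i in seq_len(max_iter)) {
    x_new <- pulsed_day_map(x, params, method = "closed")
    if (abs(x_new - x) < tol) return(x_new)
    x <- x_new
  }
  x
}

# Random valid parameter draws for property tests.
rand_model_params <- function(alpha = stats::runif(1, -0.5, 1)) {
  model_params(n = sample(1:60, 1),
               kappa_n = stats::runif(1, 0, 0.8),
               mu_n = stats::runif(1, 0, 0.3),
               alpha = alpha)
}

rand_intraday_params <- function() {
  intraday_params(r = stats::runif(1, 0.1, 1.5),
                  rho_n = stats::runif(1, 0, 0.3),
                  sigma = stats::runif(1, 2, 12),
                  n = sample(1:40, 1))
}
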