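# Shared fixtures: small noiseless/noisy anatomy sets and short simulations.

# Observations lying exactly on a known plane per response.
make_plane_observations <- function(coefs = NULL, n_per_cat = 3) {
  if (is.null(coefs)) {
    coefs <- rbind(intercept = c(0.09, 1000, 450, 0.2),
                   ccfn = c(0.0025, 12, 20, 0.07),
                   ccs = c(-1e-4, -0.3, -0.2, 8e-4))
    colnames(coefs) <- c("respiration", "optimum_n", "minimum_n", "diameter")
  }
  spec <- anatomy_generator_spec(seed = 42, coefficients = coefs,
                                 noise_sd = c(0, 0, 0, 0),
                                 genotypes_per_category = n_per_cat)
  list(obs = generate_anatomy_dataset(spec), coefs = coefs, spec = spec)
}

# Normal-equation OLS, independent of stats::lm.
ols_oracle <- function(y, ccfn, ccs) {
  X <- cbind(1, ccfn, ccs)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

quick_config <- function(duration = 15, stochasticity = 0.05, ...) {
  sim_config(duration = duration, stochasticity = stochasticity, ...)
}
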