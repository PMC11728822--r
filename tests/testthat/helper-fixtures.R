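# Shared fixture builders (everything is generated in code; no stored data
# beyond the package's bundled summary table).

# A small, well-behaved summary dataset from known linear truth.
linear_sim_data <- function(a = 10, b = 0.5, sigma = 3, n_reps = 6,
                            doses = c(0, 0.5, 1, 4, 10, 20, 50, 80, 100,
                                      120, 150),
                            seed = 42, endpoint = "sim") {
  des <- simulation_design("linear", c(a = a, b = b), doses = doses,
                           n_reps = n_reps, sigma = sigma, seed = seed)
  simulate_summary(des, endpoint = endpoint)
}

# Random raw replicate data for ANOVA identity checks.
random_raw_data <- function(seed, k = 4, n = 5) {
  set.seed(seed)
  doses <- c(0, sort(runif(k - 1, 1, 100)))
  do.call(rbind, lapply(doses, function(d) {
    data.frame(dose = d,
               response = pmin(pmax(rnorm(n, 10 + 0.3 * d, 8), 0), 100))
  }))
}

# Random valid natural-scale parameter draws for one model, shaped like the
# `draws` element of a fit (used to exercise the bisection solver without
# an MCMC run).
random_theta_draws <- function(model, n, dmax = 300, seed = 1) {
  set.seed(seed)
  a <- runif(n, 2, 30)
  g <- runif(n, 1, 5)
  out <- switch(model,
    exp2 = data.frame(a = a, b = runif(n, 1e-4, log(150 / 2) / dmax)),
    exp3 = data.frame(a = a, b = runif(n, 1e-4, 2) / dmax^g, g = g),
    exp4 = data.frame(a = a, b = runif(n, 0.2, 20) / dmax,
                      c = runif(n, 1.2, 8)),
    exp5 = data.frame(a = a, b = runif(n, 0.2, 20) / dmax^g,
                      c = runif(n, 1.2, 8), g = g),
    hill = data.frame(a = a, b = runif(n, 30, 150), c = runif(n, 5, 300),
                      g = g),
    power = data.frame(a = a, b = runif(n, 30, 150) / dmax^g, g = g),
    michaelis_menten = data.frame(a = a, b = runif(n, 30, 150),
                                  c = runif(n, 5, 300)),
    linear = data.frame(a = a, b = runif(n, 30, 150) / dmax))
  out$sigma <- runif(n, 0.05, 0.4)
  out
}

# Minimal fit-shaped object for solver-level tests.
fake_fit <- function(model, draws, dmax = 300, likelihood = "lognormal") {
  data <- dose_response_data(c(0, dmax / 2, dmax), 3, c(10, 40, 80),
                             c(2, 4, 6), "fake")
  structure(list(model = model, draws = draws, data = data,
                 likelihood = likelihood, n_draws = nrow(draws)),
            class = "bmc_fit")
}

fast_mcmc <- function(iterations = 3000, seed = 7) {
  mcmc_config(iterations = iterations, seed = seed)
}
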