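test_that("model weights follow the pseudo-BMA softmax contract", {
  d <- fluoride_table3("cm_1dpf")
  mc <- fast_mcmc(seed = 41)
  f1 <- fit_model("linear", d, mc)
  expect_equal(as.numeric(model_weights(list(f1))), 1)

  # two fits with identical pointwise log-likelihood draws split evenly
  w <- model_weights(list(f1, f1), gate = FALSE)
  expect_equal(as.numeric(w), c(0.5, 0.5))

  f2 <- fit_model("michaelis_menten", d, mc)
  w <- suppressWarnings(model_weights(list(f1, f2)))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))

  # shift invariance: adding a constant to every elpd leaves weights unchanged
  g1 <- f1; g2 <- f2
  g1$loo$elpd <- g1$loo$elpd + 1000
  g2$loo$elpd <- g2$loo$elpd + 1000
  expect_equal(as.numeric(model_weights(list(g1, g2), gate = FALSE)),
               as.numeric(model_weights(list(f1, f2), gate = FALSE)),
               tolerance = 1e-12)
})

test_that("the diagnostics gate excludes failing fits and renormalizes", {
  d <- fluoride_table3("cm_1dpf")
  mc <- fast_mcmc(seed = 42)
  f1 <- fit_model("linear", d, mc)
  f2 <- fit_model("exp2", d, mc)
  bad <- f2
  bad$rhat["b"] <- 1.5
  expect_warning(w <- model_weights(list(f1, bad)), "excluded")
  expect_equal(as.numeric(w), c(1, 0))
  bad1 <- f1; bad1$ppp <- 0.999
  bad2 <- f2; bad2$rhat["b"] <- 2
  expect_error(suppressWarnings(model_weights(list(bad1, bad2))), "every fit")
})

test_that("mixture resampling reproduces degenerate and two-atom cases", {
  draws1 <- rep(2, 500)
  draws2 <- rep(4, 500)
  mx <- mix_draws(c(m1 = 0.5, m2 = 0.5), list(m1 = draws1, m2 = draws2),
                  total_draws = 10000, seed = 3)
  expect_true(median(mx) %in% c(2, 4))
  expect_equal(unname(quantile(mx, 0.05)), 2)
  expect_equal(unname(quantile(mx, 0.95)), 4)

  set.seed(10)
  big <- rlnorm(15000, 1, 0.5) # one fit's worth of posterior draws
  mx1 <- mix_draws(c(only = 1), list(only = big), total_draws = 100000,
                   seed = 4)
  q <- quantile(big, c(0.05, 0.5, 0.95))
  qm <- quantile(mx1, c(0.05, 0.5, 0.95))
  expect_true(all(abs(qm / q - 1) < 0.01))

  # mixture reproducibility
  expect_identical(mix_draws(c(a = 0.3, b = 0.7),
                             list(a = draws1, b = big[1:500]), 1000, 9),
                   mix_draws(c(a = 0.3, b = 0.7),
                             list(a = draws1, b = big[1:500]), 1000, 9))
})

test_that("resampled mixture quantiles match the pooling oracle", {
  set.seed(22)
  dl <- list(m1 = rlnorm(4000, 0, 0.4), m2 = rlnorm(4000, 1.2, 0.3),
             m3 = rlnorm(4000, 0.5, 0.6))
  w <- c(m1 = 0.5, m2 = 0.3, m3 = 0.2)
  mx <- mix_draws(w, dl, total_draws = 100000, seed = 8)
  pooled <- c(rep(dl$m1, 50), rep(dl$m2, 30), rep(dl$m3, 20))
  for (p in c(0.05, 0.5, 0.95))
    expect_lt(abs(quantile(mx, p) / quantile(pooled, p) - 1), 0.02)
})

test_that("model-averaged summaries stay inside the per-model envelope", {
  d <- fluoride_table3("cm_1dpf")
  mc <- fast_mcmc(seed = 44)
  fits <- lapply(c("linear", "michaelis_menten", "power"), fit_model,
                 data = d, mcmc = mc)
  avg <- suppressWarnings(average_models(fits, seed = 5))
  inc <- avg$weights > 0
  lo <- min(vapply(avg$bmc[inc], function(b) b$summary[["q05"]], 0))
  hi <- max(vapply(avg$bmc[inc], function(b) b$summary[["q95"]], 0))
  expect_true(avg$bmc_summary[["median"]] >= lo &
                avg$bmc_summary[["median"]] <= hi)
  expect_true(avg$bmc_summary[["q05"]] <= avg$bmc_summary[["median"]])
  expect_true(avg$bmc_summary[["median"]] <= avg$bmc_summary[["q95"]])
})

test_that("weights concentrate on the generating model family at large n", {
  # michaelis-menten truth with many replicates. The models are nested
  # (hill reduces to michaelis-menten at g = 1), so the mimicking family
  # {mm, hill, exp4, exp5} -- saturating curves -- is the recoverable unit;
  # the non-saturating models must be driven out.
  hits <- 0
  for (r in 1:5) {
    des <- simulation_design("michaelis_menten", c(a = 10, b = 85, c = 30),
                             n_reps = 30, sigma = 4, seed = 700 + r)
    d <- simulate_summary(des, "wrec")
    fits <- lapply(dr_models(), fit_model, data = d,
                   mcmc = mcmc_config(iterations = 4000, seed = 800 + r))
    w <- suppressWarnings(model_weights(fits))
    fam <- sum(w[c("michaelis_menten", "hill", "exp4", "exp5")])
    if (fam > 0.5) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("species extrapolation follows the log-LC50 ratio formula", {
  r <- species_extrapolation(10, c(100, 100), c(100, 100), noael_humans = 4)
  expect_equal(r$log_ratio, 1)
  expect_equal(r$uf_zebrafish, 1)
  expect_equal(r$hbgv, 4)

  r2 <- species_extrapolation(10, 100, 10)
  expect_equal(r2$log_ratio, 2)
  expect_equal(r2$uf_zebrafish, 0.1)
  expect_true(is.na(r2$hbgv))

  # a pair with equal LC50s halves a mammalian UF of 20 down to 2,
  # giving HBGV = 4 / 2
  r3 <- species_extrapolation(20, 10, 10, noael_humans = 4)
  expect_equal(r3$uf_zebrafish, 2)
  expect_equal(r3$hbgv, 2)
  expect_error(species_extrapolation(10, 5, 1), "log10")
  expect_error(species_extrapolation(10, c(1, 2), c(3, 4, 5)))
})
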