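test_that("split-chain Rhat matches the textbook formula and edge cases", {
  # independent implementation of split-R-hat for a single chain
  rhat_oracle <- function(x) {
    n <- length(x) %/% 2
    h <- cbind(x[1:n], x[(n + 1):(2 * n)])
    W <- mean(apply(h, 2, var))
    B <- n * var(colMeans(h))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(1000) + cumsum(rnorm(1000, 0, 0.05))
    expect_equal(unname(compute_rhat(x)), rhat_oracle(x), tolerance = 1e-12)
  }

  # two identical halves with internal variance: B = 0, Rhat -> 1 from below
  h <- rnorm(5000)
  expect_equal(unname(compute_rhat(c(h, h))), 1, tolerance = 1e-3)

  # halves offset by 10 SDs diverge clearly
  expect_gt(compute_rhat(c(rnorm(500), rnorm(500) + 10)), 1.5)

  expect_warning(r0 <- compute_rhat(rep(3, 100)), "zero-variance")
  expect_equal(unname(r0), 1)
})

test_that("fits are bit-reproducible for a given seed", {
  d <- linear_sim_data(seed = 4)
  f1 <- fit_model("linear", d, fast_mcmc(seed = 11))
  f2 <- fit_model("linear", d, fast_mcmc(seed = 11))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$ppp, f2$ppp)
  f3 <- fit_model("linear", d, fast_mcmc(seed = 12))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior mean of the linear slope matches the WLS oracle", {
  d <- linear_sim_data(a = 12, b = 0.4, sigma = 4, seed = 8)
  fit <- fit_model("linear", d, mcmc_config(iterations = 20000, seed = 3),
                   likelihood = "normal")
  # weighted least squares with weights n_i (constant variance across obs)
  w <- d$n
  xb <- sum(w * d$dose) / sum(w)
  yb <- sum(w * d$mean) / sum(w)
  b_wls <- sum(w * (d$dose - xb) * (d$mean - yb)) / sum(w * (d$dose - xb)^2)
  b_draws <- fit$draws$b
  # Monte-Carlo SE from batch means
  nb <- 50
  bm <- colMeans(matrix(b_draws[1:(nb * (length(b_draws) %/% nb))],
                        ncol = nb))
  mcse <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(b_draws) - b_wls), 3 * mcse + 1e-4)
})

test_that("stored per-draw log-likelihoods agree with the R-side formula", {
  d <- fluoride_table3("cm_1dpf")
  for (lik in c("lognormal", "normal")) {
    fit <- fit_model("hill", d, fast_mcmc(seed = 5), likelihood = lik)
    i <- c(1, 57, 1400)
    manual <- vapply(i, function(j)
      dr_loglik("hill", as.list(fit$draws[j, ]), d, fit$draws$sigma[j],
                likelihood = lik), 0)
    expect_equal(fit$loglik[i], manual, tolerance = 1e-6)
  }
})

test_that("PPP is calibrated near 0.5 for data simulated from the model", {
  ppps <- vapply(1:20, function(r) {
    d <- linear_sim_data(a = 15, b = 0.4, sigma = 5, seed = 300 + r)
    fit <- fit_model("linear", d, fast_mcmc(iterations = 2000,
                                            seed = 400 + r))
    fit$ppp
  }, 0)
  expect_lt(abs(mean(ppps) - 0.5), 0.15)
  expect_true(all(ppps > 0.01 & ppps < 0.99))
})

test_that("the mean-discrepancy PPP flags a grossly misspecified mean function", {
  # steep saturating data vs the unbounded exponential growth model
  d <- fluoride_table3("cm_5dpf")
  fit <- fit_model("exp2", d, fast_mcmc(seed = 6), likelihood = "normal",
                   ppp_stat = "means")
  expect_lt(fit$ppp, 0.05)
  # while the omnibus statistic lets sigma absorb residual misfit
  omni <- fit_model("exp2", d, fast_mcmc(seed = 6), likelihood = "normal",
                    ppp_stat = "omnibus")
  expect_true(omni$ppp > 0.05 & omni$ppp < 0.95)
})

test_that("importance-sampling LOO matches brute-force refits on a small dataset", {
  d <- linear_sim_data(doses = c(0, 20, 60, 100, 150), n_reps = 6, sigma = 4,
                       seed = 31)
  mc <- mcmc_config(iterations = 10000, seed = 77)
  fit <- fit_model("linear", d, mc)
  is_pw <- fit$loo$pointwise
  exact_pw <- is_pw
  for (i in 2:nrow(d)) { # control group must stay (dose 0 is required)
    di <- d[-i, ]
    class(di) <- class(d)
    attr(di, "endpoint") <- "loo"
    fi <- fit_model("linear", di, mcmc_config(iterations = 10000,
                                              seed = 77 + i))
    w <- bayesbmc:::.work_stats(d, fi$likelihood)
    mu <- bayesbmc:::.mu_matrix("linear", fi$draws, d$dose[i])[, 1]
    sig <- fi$draws$sigma
    n <- d$n[i]
    ll <- -n * log(sig) - n / 2 * log(2 * pi) -
      ((n - 1) * w$s2[i] + n * (w$y[i] - log(mu))^2) / (2 * sig^2)
    exact_pw[i] <- bayesbmc:::.logsumexp(ll) - log(length(ll))
  }
  expect_lt(abs(sum(is_pw) - sum(exact_pw)), 1)
})

test_that("a pure-noise parameter does not raise the LOO score materially", {
  # power nests linear at g = 1; on linear truth its extra parameter is noise
  worse <- 0
  for (r in 1:3) {
    d <- linear_sim_data(seed = 500 + r)
    mc <- mcmc_config(iterations = 6000, seed = 600 + r)
    lin <- fit_model("linear", d, mc)
    pow <- fit_model("power", d, mc)
    expect_lt(pow$loo$elpd, lin$loo$elpd + 1.5)
  }
})

test_that("diagnostics gate separates converged from non-converged fits", {
  d <- fluoride_table3("cm_1dpf")
  fit <- fit_model("linear", d, fast_mcmc(seed = 2))
  expect_true(passes_diagnostics(fit))
  broken <- fit
  broken$rhat["b"] <- 1.2
  expect_false(passes_diagnostics(broken))
  broken2 <- fit
  broken2$ppp <- 0.99
  expect_false(passes_diagnostics(broken2))
})
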