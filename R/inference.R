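#' MCMC configuration
#'
#' @param iterations Total iterations including warmup (default 30000).
#' @param n_chains Number of chains (default 1; convergence is assessed by
#'   splitting each chain in half).
#' @param warmup_fraction Fraction of iterations discarded as warmup
#'   (default 0.5). Warmup draws are discarded, never thinned.
#' @param seed Integer seed making every draw reproducible (default 65323).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 30000, n_chains = 1,
                        warmup_fraction = 0.5, seed = 65323) {
  stopifnot(iterations >= 1000, n_chains >= 1,
            warmup_fraction > 0, warmup_fraction < 1)
  structure(list(iterations = as.integer(iterations),
                 n_chains = as.integer(n_chains),
                 warmup_fraction = warmup_fraction,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Back-transform draws from the rescaled problem (dose/dmax, response/100)
# to natural units (mg/L, %). `theta` is the keep x 5 matrix (a,b,c,g,sigma).
.natural_draws <- function(model, theta, dmax, likelihood = "lognormal") {
  a <- 100 * theta[, 1]
  b <- theta[, 2]
  c <- theta[, 3]
  g <- theta[, 4]
  # the lognormal residual SD is dimensionless (log scale)
  sigma <- if (likelihood == "lognormal") theta[, 5] else 100 * theta[, 5]
  b <- switch(model,
    exp2 = b / dmax,
    exp3 = b / dmax^g,
    exp4 = b / dmax,
    exp5 = b / dmax^g,
    hill = 100 * b,
    power = 100 * b / dmax^g,
    michaelis_menten = 100 * b,
    linear = 100 * b / dmax)
  c <- switch(model,
    hill = c * dmax,
    michaelis_menten = c * dmax,
    c)
  out <- data.frame(a = a, b = b, c = c, g = g, sigma = sigma)
  out[, c(.model_pars[[model]], "sigma")]
}

# Posterior mean-response matrix: draws x dose groups, natural scale (%).
.mu_matrix <- function(model, draws, dose) {
  a <- draws$a; b <- draws$b
  c <- if ("c" %in% names(draws)) draws$c else NULL
  g <- if ("g" %in% names(draws)) draws$g else NULL
  out <- matrix(NA_real_, nrow(draws), length(dose))
  for (i in seq_along(dose))
    out[, i] <- .eval_vec(model, a, b, c, g, dose[i])
  out
}

#' Fit one dose-response model by MCMC
#'
#' Samples the posterior of one of the eight dose-response models on a
#' summary dataset using a componentwise adaptive random-walk Metropolis
#' sampler (step sizes adapted during warmup only). The chain is
#' initialized at a posterior mode found from the best of 200 prior draws
#' refined by BFGS; if the posterior is non-finite there, further random
#' starts are tried before failing. Draws are bit-reproducible for a given
#' seed.
#'
#' The likelihood is a constant-variance normal on the response scale,
#' evaluated from per-group sufficient statistics (see [dr_loglik()]).
#' Diagnostics attached to the fit: split-chain Rhat per parameter
#' ([compute_rhat()]), posterior predictive p-value ([compute_ppp()]), and
#' leave-one-group-out expected log predictive density ([compute_loo()]).
#'
#' @param model Model name (see [dr_models()]).
#' @param data A [dose_response_data()] object.
#' @param mcmc An [mcmc_config()].
#' @param prior A [prior_config()].
#' @param likelihood Error model: `"lognormal"` (default; the mean function
#'   parameterizes the median response and `sigma` is the log-scale SD) or
#'   `"normal"` (constant variance on the response scale). The lognormal
#'   default matches how the printed group SDs scale with the mean in
#'   toxicological percent-response data; see the methods vignette.
#' @param ppp_stat Discrepancy statistic for the posterior predictive check,
#'   see [compute_ppp()].
#' @return An object of class `bmc_fit`: list with `model`, `data`, `draws`
#'   (data frame of post-warmup parameter draws in mg/L / % units, plus
#'   `sigma`), `loglik` (per-draw, constant omitted), `mu` (draws x groups
#'   posterior mean-response matrix), `rhat`, `ppp`, `loo` (list with
#'   `elpd`, `pointwise`, `method`), `accept`, `mcmc`, `prior`.
#' @examples
#' \donttest{
#' d <- fluoride_table3("cm_1dpf")
#' fit <- fit_model("linear", d, mcmc_config(iterations = 4000, seed = 1))
#' fit
#' }
#' @export
fit_model <- function(model, data, mcmc = mcmc_config(),
                      prior = prior_config(),
                      likelihood = c("lognormal", "normal"),
                      ppp_stat = c("omnibus", "means")) {
  model <- match.arg(model, dr_models())
  stopifnot(inherits(data, "dr_data"), inherits(mcmc, "mcmc_config"),
            inherits(prior, "bmc_prior"))
  likelihood <- match.arg(likelihood)
  ppp_stat <- match.arg(ppp_stat)
  bb <- .prior_bounds(prior, data, likelihood)
  x <- data$dose / bb$dmax
  n <- data$n
  lnflag <- as.integer(likelihood == "lognormal")
  if (lnflag) {
    w <- .work_stats(data, likelihood)
    # log response is shift-invariant under the internal /100 rescaling
    y <- w$y - log(100)
    ss <- (n - 1) * w$s2
  } else {
    y <- data$mean / 100
    ss <- (n - 1) * (data$sd / 100)^2
  }
  id <- .model_id[[model]]
  k <- length(.model_pars[[model]]) + 1L

  lp_fun <- function(z) {
    cw_logpost(id, z, x, y, n, ss, bb$amax, bb$bmax, bb$cmax, bb$gmin,
               bb$gmax, bb$plateau, bb$sig_scale, lnflag)
  }

  run_chain <- function(seed) {
    with_seed(seed, {
      # initialization: best of 200 prior-ish draws, refined by BFGS
      best_z <- NULL
      best_lp <- -Inf
      for (i in 1:200) {
        z <- stats::rnorm(k, 0, 1.5)
        z[k] <- stats::rnorm(1, log(0.1), 1) # log sigma near the prior scale
        lp <- lp_fun(z)
        if (lp > best_lp) { best_lp <- lp; best_z <- z }
      }
      if (best_lp <= -1e9)
        stop("non-finite posterior density at initialization")
      opt <- try(stats::optim(best_z, function(z) -lp_fun(z),
                              method = "BFGS",
                              control = list(maxit = 200)), silent = TRUE)
      if (!inherits(opt, "try-error") && -opt$value > best_lp)
        best_z <- opt$par
      cw_sampler(id, best_z, x, y, n, ss, bb$amax, bb$bmax, bb$cmax,
                 bb$gmin, bb$gmax, bb$plateau, bb$sig_scale, lnflag,
                 mcmc$iterations, mcmc$warmup_fraction)
    })
  }

  chains <- lapply(seq_len(mcmc$n_chains),
                   function(i) run_chain(mcmc$seed + (i - 1L)))
  theta <- do.call(rbind, lapply(chains, `[[`, "theta"))
  loglik <- unlist(lapply(chains, `[[`, "loglik"), use.names = FALSE)
  if (!lnflag) {
    # rescaled -> natural log-likelihood differs by the constant N log 100
    loglik <- loglik - sum(n) * log(100)
  } # log-scale residuals are invariant under the rescaling

  draws <- .natural_draws(model, theta, bb$dmax, likelihood)
  mu <- .mu_matrix(model, draws, data$dose)

  fit <- structure(list(
    model = model, data = data, draws = draws, loglik = loglik, mu = mu,
    likelihood = likelihood, accept = chains[[1]]$accept, mcmc = mcmc,
    prior = prior, n_draws = nrow(draws)), class = "bmc_fit")

  fit$rhat <- compute_rhat(fit)
  fit$ppp <- with_seed(mcmc$seed + 10000L,
                       compute_ppp(fit, data, stat = ppp_stat))
  fit$loo <- compute_loo(fit, data)
  fit
}

#' @export
print.bmc_fit <- function(x, ...) {
  cat("<bmc_fit>", x$model, "on", endpoint_label(x$data), "-", x$n_draws,
      "post-warmup draws\n")
  cat("  posterior medians:",
      paste(names(x$draws),
            format(vapply(x$draws, stats::median, 0), digits = 4),
            sep = "=", collapse = "  "), "\n")
  cat("  max Rhat:", format(max(x$rhat), digits = 4),
      "  PPP:", format(x$ppp, digits = 3),
      "  LOO elpd:", format(x$loo$elpd, digits = 5), "\n")
  invisible(x)
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Computes the potential scale reduction factor per parameter. A single
#' chain is split into two halves (the only coherent reading of a
#' convergence diagnostic on one chain); multiple chains are each split,
#' giving `2 * n_chains` segments. Parameters with zero total variance get
#' Rhat 1 with a warning.
#'
#' @param fit A `bmc_fit`, or a numeric vector / one-column-per-parameter
#'   matrix of draws from a single chain.
#' @return Named numeric vector of Rhat values (one per parameter).
#' @export
compute_rhat <- function(fit) {
  draws <- if (inherits(fit, "bmc_fit")) as.matrix(fit$draws) else
    as.matrix(fit)
  apply(draws, 2, .rhat_one)
}

.rhat_one <- function(x) {
  m2 <- length(x) %/% 2
  if (m2 < 2) return(NA_real_)
  halves <- list(x[1:m2], x[(m2 + 1):(2 * m2)])
  W <- mean(vapply(halves, stats::var, 0))
  if (!is.finite(W) || W <= 0) {
    if (stats::var(x) == 0) {
      warning("zero-variance draws: Rhat reported as 1")
      return(1)
    }
    return(Inf)
  }
  B <- m2 * stats::var(vapply(halves, mean, 0))
  var_plus <- (m2 - 1) / m2 * W + B / m2
  sqrt(var_plus / W)
}

#' Posterior predictive p-value
#'
#' Computes the tail probability of a chi-square-type discrepancy under
#' replicated data: for each posterior draw a replicate dataset is
#' simulated from the fitted model and the PPP is the fraction of draws
#' whose replicated discrepancy is at least the observed one. Values near
#' 0 or 1 indicate misfit; the acceptance band used for model gating is
#' \[0.05, 0.95\].
#'
#' Two discrepancy statistics are available:
#' \describe{
#'   \item{`"omnibus"` (default)}{`T = sum_i [(n_i-1) s_i^2 + n_i (m_i -
#'     f(d_i))^2] / sigma^2`, the total sum of squares of all observations
#'     via sufficient statistics; replicated groups regenerate both the
#'     group mean and the within-group scatter. This is the statistic used
#'     for the model-gating band: residual variance absorbed into `sigma`
#'     does not count against the model, matching how benchmark-dose
#'     systems report tightly clustered PPP values across models.}
#'   \item{`"means"`}{`T = sum_i n_i (m_i - f(d_i))^2 / sigma^2` with only
#'     the group means replicated. Sensitive to mean misfit: a grossly
#'     misspecified mean function drives the PPP toward 0.}
#' }
#'
#' @param fit A `bmc_fit` with at least 100 draws.
#' @param data The dataset the fit was computed on (defaults to
#'   `fit$data`).
#' @param stat Discrepancy statistic, see above.
#' @return PPP value in \[0, 1\].
#' @export
compute_ppp <- function(fit, data = fit$data, stat = c("omnibus", "means")) {
  stopifnot(inherits(fit, "bmc_fit"))
  stat <- match.arg(stat)
  S <- fit$n_draws
  if (S < 100) stop("need at least 100 draws")
  n <- data$n
  w <- .work_stats(data, fit$likelihood %||% "normal")
  muw <- if ((fit$likelihood %||% "normal") == "lognormal") log(fit$mu)
         else fit$mu
  sigma <- fit$draws$sigma
  resid_obs <- sweep(muw, 2, w$y)       # f - m per draw x group (work scale)
  mean_ss_obs <- resid_obs^2 %*% n      # sum_i n_i (m_i - f_i)^2
  within_ss <- sum((n - 1) * w$s2)

  # replicated group means ~ N(f_i, sigma/sqrt(n_i)) per draw
  z <- matrix(stats::rnorm(S * length(n)), S, length(n))
  mean_ss_rep <- (sweep(z, 2, sqrt(n), "/") * sigma)^2 %*% n
  if (stat == "means") {
    t_obs <- mean_ss_obs / sigma^2
    t_rep <- mean_ss_rep / sigma^2
  } else {
    # replicated within-group sums of squares ~ sigma^2 * chi^2_{n_i - 1}
    within_rep <- matrix(0, S, 1)
    for (i in seq_along(n)) {
      if (n[i] > 1)
        within_rep <- within_rep + sigma^2 * stats::rchisq(S, n[i] - 1)
    }
    t_obs <- (mean_ss_obs + within_ss) / sigma^2
    t_rep <- (mean_ss_rep + within_rep) / sigma^2
  }
  mean(t_rep >= t_obs)
}

# Per-draw, per-group log-likelihood contributions on the working scale
# (normal constants included; the lognormal data Jacobian, a data-only
# constant shared by all models, is omitted).
.pointwise_loglik <- function(fit, data = fit$data) {
  n <- data$n
  sigma <- fit$draws$sigma
  lik <- fit$likelihood %||% "normal"
  w <- .work_stats(data, lik)
  muw <- if (lik == "lognormal") log(fit$mu) else fit$mu
  resid <- sweep(muw, 2, w$y)
  out <- matrix(NA_real_, fit$n_draws, length(n))
  for (i in seq_along(n)) {
    out[, i] <- -n[i] * log(sigma) - n[i] / 2 * log(2 * pi) -
      ((n[i] - 1) * w$s2[i] + n[i] * resid[, i]^2) / (2 * sigma^2)
  }
  out
}

#' Leave-one-group-out expected log predictive density
#'
#' Estimates the leave-one-dose-group-out expected log predictive density
#' (elpd) by importance sampling from the full posterior, with the raw
#' importance weights truncated at `sqrt(S)` times their mean (truncated
#' importance sampling) for stability. If any pointwise contribution is
#' non-finite the function falls back to WAIC with a warning.
#'
#' @param fit A `bmc_fit`.
#' @param data The dataset the fit was computed on (defaults to
#'   `fit$data`).
#' @return List with `elpd` (total), `pointwise` (per group), and `method`
#'   (`"loo"` or `"waic"`).
#' @export
compute_loo <- function(fit, data = fit$data) {
  ll <- .pointwise_loglik(fit, data)
  S <- nrow(ll)
  logS <- log(S)
  pointwise <- vapply(seq_len(ncol(ll)), function(i) {
    lli <- ll[, i]
    lw <- -lli
    lw <- lw - max(lw)
    # truncate at log(mean raw weight) + 0.5 log S
    cap <- (.logsumexp(lw) - logS) + 0.5 * logS
    lw <- pmin(lw, cap)
    .logsumexp(lw + lli) - .logsumexp(lw)
  }, 0)
  if (any(!is.finite(pointwise))) {
    warning("unstable importance weights: falling back to WAIC")
    pointwise <- vapply(seq_len(ncol(ll)), function(i) {
      lli <- ll[, i]
      .logsumexp(lli) - logS - stats::var(lli)
    }, 0)
    method <- "waic"
  } else method <- "loo"
  list(elpd = sum(pointwise), pointwise = pointwise, method = method)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Diagnostics gate
#'
#' A fit passes when every parameter's Rhat is at most `rhat_max` and the
#' posterior predictive p-value lies in `ppp_band`.
#'
#' @param fit A `bmc_fit`.
#' @param rhat_max Maximum acceptable Rhat (default 1.05).
#' @param ppp_band Acceptable PPP interval (default `c(0.05, 0.95)`).
#' @return Logical scalar.
#' @export
passes_diagnostics <- function(fit, rhat_max = 1.05,
                               ppp_band = c(0.05, 0.95)) {
  max(fit$rhat) <= rhat_max && fit$ppp >= ppp_band[1] && fit$ppp <= ppp_band[2]
}
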