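#' Predictive-fit model weights
#'
#' Pseudo-Bayesian-model-averaging weights from the leave-one-group-out
#' expected log predictive density: `w_m` is proportional to
#' `exp(elpd_m - max_m elpd_m)`, normalized (computed through log-sum-exp
#' for stability, and therefore invariant to adding a constant to every
#' model's elpd). Fits failing the diagnostics gate (Rhat > 1.05 or PPP
#' outside \[0.05, 0.95\]) are excluded with a warning and the weights of
#' the remaining models renormalized. With `method = "waic"` the WAIC elpd
#' is used instead (sensitivity option).
#'
#' @param fits List of `bmc_fit` objects on the same dataset.
#' @param method `"loo"` (default) or `"waic"`.
#' @param gate Apply the diagnostics gate (default TRUE).
#' @param rhat_max,ppp_band Gate thresholds, see [passes_diagnostics()].
#' @return Named weights summing to 1 over the included models; excluded
#'   models get weight 0. Attribute `excluded` lists gated-out models.
#' @export
model_weights <- function(fits, method = c("loo", "waic"), gate = TRUE,
                          rhat_max = 1.05, ppp_band = c(0.05, 0.95)) {
  method <- match.arg(method)
  stopifnot(length(fits) >= 1)
  nm <- vapply(fits, function(f) f$model, "")
  names(fits) <- nm
  elpd <- vapply(fits, function(f) {
    if (method == "loo") f$loo$elpd
    else {
      ll <- .pointwise_loglik(f)
      sum(vapply(seq_len(ncol(ll)), function(i)
        .logsumexp(ll[, i]) - log(nrow(ll)) - stats::var(ll[, i]), 0))
    }
  }, 0)
  ok <- rep(TRUE, length(fits))
  if (gate) {
    ok <- vapply(fits, passes_diagnostics, TRUE, rhat_max = rhat_max,
                 ppp_band = ppp_band)
    if (!any(ok)) stop("every fit failed the diagnostics gate")
    if (any(!ok))
      warning("excluded from averaging (failed diagnostics): ",
              paste(nm[!ok], collapse = ", "))
  }
  w <- numeric(length(fits))
  le <- elpd[ok] - max(elpd[ok])
  w[ok] <- exp(le - .logsumexp(le))
  names(w) <- nm
  attr(w, "excluded") <- nm[!ok]
  attr(w, "elpd") <- elpd
  w
}

#' Combine per-model draws into a weighted mixture
#'
#' Resamples `total_draws` values, drawing from model `m` with probability
#' `w_m` and uniformly among that model's defined draws. Seed-deterministic
#' and independent of the MCMC seed stream.
#'
#' @param weights Named weights (summing to 1) as from [model_weights()].
#' @param draws_list Named list of numeric draw vectors (or
#'   `benchmark_draws` objects), matching `names(weights)`.
#' @param total_draws Size of the mixture sample (default 15000).
#' @param seed Integer seed.
#' @return Numeric vector of mixture draws. If every positively weighted
#'   model has only undefined draws, a vector of NA (the averaged quantity
#'   is undefined).
#' @export
mix_draws <- function(weights, draws_list, total_draws = 15000, seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  draws_list <- lapply(draws_list, function(d)
    if (inherits(d, "benchmark_draws")) d$draws else d)
  draws_list <- draws_list[names(weights)]
  defined <- lapply(draws_list, function(d) d[!is.na(d)])
  usable <- vapply(defined, length, 0L) >= 100
  if (any(weights > 0 & !usable)) {
    drop <- weights > 0 & !usable
    warning("model(s) with < 100 defined draws dropped from the mixture: ",
            paste(names(weights)[drop], collapse = ", "))
    weights[drop] <- 0
    if (sum(weights) == 0) return(rep(NA_real_, total_draws))
    weights <- weights / sum(weights)
  }
  with_seed(seed, {
    idx <- sample.int(length(weights), total_draws, replace = TRUE,
                      prob = weights)
    out <- numeric(total_draws)
    for (m in which(weights > 0)) {
      pick <- idx == m
      if (any(pick))
        out[pick] <- defined[[m]][sample.int(length(defined[[m]]),
                                             sum(pick), replace = TRUE)]
    }
    out
  })
}

#' Model-averaged benchmark estimates
#'
#' Weights the fitted models by predictive fit ([model_weights()]),
#' computes per-model BMC and LC50/EC50 draws, and combines them into
#' model-averaged mixtures. The model-average BMC/BMCL/BMCU are the
#' median/5th/95th percentiles of the weighted BMC mixture; the
#' model-average LC50 is the median (5th, 95th) of the weighted LC50
#' mixture, with the arithmetic mean of the per-model medians also
#' reported for comparison.
#'
#' @param fits List of `bmc_fit` objects on the same dataset.
#' @param config A [benchmark_config()].
#' @param total_draws Mixture sample size (default 15000).
#' @param seed Seed for the mixture resampling (independent of the MCMC
#'   seeds).
#' @param weights Optional precomputed weights (skips [model_weights()]).
#' @param ... Passed to [model_weights()].
#' @return An object of class `bma_result`: list with `endpoint`,
#'   `weights`, per-model `bmc` and `lc50` (`benchmark_draws`), mixture
#'   draw vectors `bmc_mix` / `lc50_mix`, and summaries `bmc_summary` /
#'   `lc50_summary` (median, q05, q95), plus `lc50_mean_of_medians`.
#' @export
average_models <- function(fits, config = benchmark_config(),
                           total_draws = 15000, seed = 1, weights = NULL,
                           ...) {
  nm <- vapply(fits, function(f) f$model, "")
  names(fits) <- nm
  if (is.null(weights)) weights <- model_weights(fits, ...)
  bmc <- lapply(fits, bmc_draws, config = config)
  lc50 <- lapply(fits, lc50_draws, config = config)
  bmc_mix <- mix_draws(weights, bmc, total_draws, seed)
  lc50_mix <- mix_draws(weights, lc50, total_draws, seed + 1L)
  lc50_med <- vapply(lc50, function(d) d$summary[["median"]], 0)
  structure(list(
    endpoint = endpoint_label(fits[[1]]$data),
    weights = weights, bmc = bmc, lc50 = lc50,
    bmc_mix = bmc_mix, lc50_mix = lc50_mix,
    bmc_summary = summarize_draws(bmc_mix),
    lc50_summary = summarize_draws(lc50_mix),
    lc50_mean_of_medians = mean(lc50_med[weights > 0]),
    config = config, total_draws = total_draws, seed = seed),
    class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("<bma_result>", x$endpoint, "\n  weights (%):\n")
  print(round(100 * x$weights, 2))
  cat("  BMC (median [BMCL, BMCU]):",
      sprintf("%.3g [%.3g, %.3g]", x$bmc_summary[["median"]],
              x$bmc_summary[["q05"]], x$bmc_summary[["q95"]]), "mg/L\n")
  cat("  LC50/EC50 (median [5th, 95th]):",
      sprintf("%.4g [%.4g, %.4g]", x$lc50_summary[["median"]],
              x$lc50_summary[["q05"]], x$lc50_summary[["q95"]]), "mg/L\n")
  invisible(x)
}

#' Zebrafish-to-human uncertainty-factor extrapolation
#'
#' Converts a mammalian uncertainty factor to a zebrafish-based one using
#' paired LC50 values, and derives a health-based guidance value:
#' \deqn{UF_{zf} = UF_{mam} / 10^{\mathrm{mean}(\log_{10} LC50_{zf} /
#'   \log_{10} LC50_{mam})}}
#' \deqn{HBGV = NOAEL_{hum} / UF_{zf}}
#'
#' @param uf_mammals Mammalian uncertainty factor (> 0).
#' @param lc50_zebrafish,lc50_mammal Paired LC50 vectors (same length,
#'   all positive; mammalian values must not equal 1, whose log is 0).
#' @param noael_humans Human NOAEL (same units as the HBGV), optional.
#' @return List with `log_ratio` (the averaged log-LC50 ratio),
#'   `uf_zebrafish`, and `hbgv` (NA when `noael_humans` is missing).
#' @examples
#' species_extrapolation(10, 100, 10, noael_humans = 4)
#' @export
species_extrapolation <- function(uf_mammals, lc50_zebrafish, lc50_mammal,
                                  noael_humans = NULL) {
  stopifnot(uf_mammals > 0, length(lc50_zebrafish) == length(lc50_mammal),
            all(lc50_zebrafish > 0), all(lc50_mammal > 0))
  if (any(lc50_mammal == 1))
    stop("lc50_mammal of 1 gives log10 = 0: ratio undefined")
  log_ratio <- mean(log10(lc50_zebrafish) / log10(lc50_mammal))
  uf_z <- uf_mammals / 10^log_ratio
  hbgv <- if (is.null(noael_humans)) NA_real_ else noael_humans / uf_z
  list(log_ratio = log_ratio, uf_zebrafish = uf_z, hbgv = hbgv)
}
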