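#' Benchmark configuration
#'
#' @param bmr Benchmark response as a fraction (default 0.10, i.e. a 10%
#'   change in the mean response).
#' @param bmr_type How the BMR defines the target response. `"relative"`
#'   (default): `f(BMC) = f(0) * (1 + bmr)`, a relative change from the
#'   background mean, the continuous-data default. `"absolute"`:
#'   `f(BMC) = f(0) + 100 * bmr` (percentage points). `"sd"`:
#'   `f(BMC) = f(0) + bmr_sd_mult * sigma` per draw.
#' @param bmr_sd_mult SD multiplier when `bmr_type = "sd"` (default 1).
#' @param lc50_level Absolute response (%) defining the LC50/EC50 (default
#'   50); the solve includes background (not background-corrected extra
#'   risk).
#' @param search_upper_mult Upper bracket for root finding as a multiple of
#'   the maximum observed dose (default 10).
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(bmr = 0.1, bmr_type = c("relative", "absolute",
                                                     "sd"),
                             bmr_sd_mult = 1, lc50_level = 50,
                             search_upper_mult = 10) {
  bmr_type <- match.arg(bmr_type)
  stopifnot(bmr > 0, bmr < 1, lc50_level > 0, lc50_level < 100,
            search_upper_mult > 0)
  structure(list(bmr = bmr, bmr_type = bmr_type, bmr_sd_mult = bmr_sd_mult,
                 lc50_level = lc50_level,
                 search_upper_mult = search_upper_mult),
            class = "benchmark_config")
}

# Vectorized bisection: smallest dose with f(d) = target, per draw.
# All model parameterizations produced by the sampler are non-decreasing in
# dose, so the root is unique when it exists. Draws whose response never
# reaches the target within [0, upper] are NA.
.solve_dose <- function(model, draws, target, upper, iters = 80L) {
  a <- draws$a; b <- draws$b
  c <- if ("c" %in% names(draws)) draws$c else NULL
  g <- if ("g" %in% names(draws)) draws$g else NULL
  S <- length(a)
  target <- rep_len(target, S)
  f_up <- .eval_vec(model, a, b, c, g, rep(upper, S))
  f0 <- .eval_vec(model, a, b, c, g, rep(0, S))
  defined <- f_up >= target
  at_zero <- defined & f0 >= target # background already at/above target
  lo <- numeric(S)
  hi <- rep(upper, S)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- .eval_vec(model, a, b, c, g, mid)
    below <- fm < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[at_zero] <- 0
  out[!defined] <- NA_real_
  out
}

#' Per-draw benchmark concentration
#'
#' Solves `f(d) = target` for each posterior draw by bisection on
#' `[0, search_upper_mult x max dose]`, where the target is set by the BMR
#' type (default: relative change, `f(0)(1 + BMR)`). Draws whose curve
#' never reaches the target in the bracket are undefined (NA) and counted.
#'
#' @param fit A `bmc_fit` from [fit_model()].
#' @param config A [benchmark_config()].
#' @return An object of class `benchmark_draws`: list with `model`,
#'   `quantity = "bmc"`, `draws` (mg/L, NA where undefined),
#'   `undefined_frac`, and `summary` (see [summarize_draws()]).
#' @export
bmc_draws <- function(fit, config = benchmark_config()) {
  stopifnot(inherits(fit, "bmc_fit"), inherits(config, "benchmark_config"))
  d <- fit$draws
  target <- switch(config$bmr_type,
    relative = d$a * (1 + config$bmr),
    absolute = d$a + 100 * config$bmr,
    sd = if ((fit$likelihood %||% "normal") == "lognormal")
      d$a * exp(config$bmr_sd_mult * d$sigma) # log-scale SD shift of the median
    else d$a + config$bmr_sd_mult * d$sigma)
  upper <- config$search_upper_mult * max(fit$data$dose)
  x <- .solve_dose(fit$model, d, target, upper)
  .benchmark_draws(fit$model, "bmc", x)
}

#' Per-draw LC50/EC50
#'
#' Solves `f(d) = lc50_level` (absolute response percent, including
#' background) for each posterior draw by bisection on the same bracket as
#' [bmc_draws()]. Draws whose curve stays below the level over the bracket
#' (e.g. a saturating model with asymptote below 50%) are undefined; the
#' undefined fraction is reported, not an error.
#'
#' @inheritParams bmc_draws
#' @return An object of class `benchmark_draws` with `quantity = "lc50"`.
#' @export
lc50_draws <- function(fit, config = benchmark_config()) {
  stopifnot(inherits(fit, "bmc_fit"), inherits(config, "benchmark_config"))
  upper <- config$search_upper_mult * max(fit$data$dose)
  x <- .solve_dose(fit$model, fit$draws, config$lc50_level, upper)
  .benchmark_draws(fit$model, "lc50", x)
}

.benchmark_draws <- function(model, quantity, x) {
  structure(list(model = model, quantity = quantity, draws = x,
                 undefined_frac = mean(is.na(x)),
                 summary = summarize_draws(x)),
            class = "benchmark_draws")
}

#' @export
print.benchmark_draws <- function(x, ...) {
  cat("<benchmark_draws>", x$model, toupper(x$quantity), "\n")
  print(x$summary)
  if (x$undefined_frac > 0)
    cat("  undefined draws:", format(100 * x$undefined_frac, digits = 3),
        "%\n")
  invisible(x)
}

#' Summarize benchmark draws
#'
#' Empirical median and 5th/95th percentiles over the defined draws
#' (linear interpolation between order statistics, `stats::quantile`
#' type 7). For the BMC these are the BMC/BMCL/BMCU; for the LC50 the
#' median and its 90% interval. A warning is emitted when more than 1% of
#' draws are undefined; with fewer than 100 defined draws all summaries
#' are NA.
#'
#' @param x A `benchmark_draws` object or a numeric vector of draws (NA =
#'   undefined).
#' @return Named vector: `median`, `q05`, `q95`, `undefined_frac`,
#'   `n_defined`.
#' @export
summarize_draws <- function(x) {
  if (inherits(x, "benchmark_draws")) x <- x$draws
  und <- mean(is.na(x))
  ok <- x[!is.na(x)]
  if (und > 0.01)
    warning(format(100 * und, digits = 3), "% of draws undefined")
  if (length(ok) < 100)
    return(c(median = NA_real_, q05 = NA_real_, q95 = NA_real_,
             undefined_frac = und, n_defined = length(ok)))
  q <- stats::quantile(ok, c(0.5, 0.05, 0.95), names = FALSE, type = 7)
  c(median = q[1], q05 = q[2], q95 = q[3], undefined_frac = und,
    n_defined = length(ok))
}

#' Closed-form benchmark concentration
#'
#' Analytic inversion of `f(d) = a (1 + bmr)` (relative-change BMR) for a
#' single parameter vector. Serves as an independent cross-check of the
#' bisection solver. Returns NA when the model cannot reach the target
#' (e.g. a saturating asymptote below it).
#'
#' @param model Model name.
#' @param theta Named parameter vector/list.
#' @param bmr Benchmark response fraction (default 0.1).
#' @return BMC in mg/L, or NA.
#' @export
bmc_closed_form <- function(model, theta, bmr = 0.1) {
  model <- match.arg(model, dr_models())
  theta <- as.list(theta)
  .check_theta(model, theta)
  a <- theta$a; b <- theta$b; c <- theta$c; g <- theta$g
  B <- bmr
  out <- switch(model,
    linear = a * B / b,
    exp2 = log(1 + B) / b,
    power = (a * B / b)^(1 / g),
    exp3 = (log(1 + B) / b)^(1 / g),
    michaelis_menten = if (b > a * B) a * B * c / (b - a * B) else NA_real_,
    exp4 = if (c - 1 > B) -log((c - 1 - B) / (c - 1)) / b else NA_real_,
    exp5 = if (c - 1 > B) (-log((c - 1 - B) / (c - 1)) / b)^(1 / g)
           else NA_real_,
    hill = if (b > a * B) c * (a * B / (b - a * B))^(1 / g) else NA_real_)
  unname(out)
}

#' Closed-form LC50/EC50
#'
#' Analytic inversion of `f(d) = level` (absolute response %) for a single
#' parameter vector; the cross-check oracle for [lc50_draws()]. NA when
#' the model never reaches the level.
#'
#' @param model Model name.
#' @param theta Named parameter vector/list.
#' @param level Absolute response percent (default 50).
#' @return Dose in mg/L, or NA.
#' @export
lc50_closed_form <- function(model, theta, level = 50) {
  model <- match.arg(model, dr_models())
  theta <- as.list(theta)
  .check_theta(model, theta)
  a <- theta$a; b <- theta$b; c <- theta$c; g <- theta$g
  L <- level
  if (a >= L) return(0)
  out <- switch(model,
    linear = (L - a) / b,
    exp2 = log(L / a) / b,
    power = ((L - a) / b)^(1 / g),
    exp3 = (log(L / a) / b)^(1 / g),
    michaelis_menten = if (a + b > L) (L - a) * c / (a + b - L) else NA_real_,
    exp4 = if (a * c > L) -log((c - L / a) / (c - 1)) / b else NA_real_,
    exp5 = if (a * c > L) (-log((c - L / a) / (c - 1)) / b)^(1 / g)
           else NA_real_,
    hill = if (a + b > L) c * ((L - a) / (a + b - L))^(1 / g) else NA_real_)
  unname(out)
}
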