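#' The eight continuous dose-response models
#'
#' Returns the names of the dose-response mean functions available for
#' fitting: four exponential variants, the Hill model, a power model, the
#' Michaelis-Menten model, and a linear model. All are parameterized so that
#' the response at dose 0 equals the background parameter `a` and the mean
#' response is non-decreasing in dose for valid parameters (`b > 0`,
#' `c > 1` for exp4/exp5, `g > 0`).
#'
#' Mean functions (dose `d`, response in percent):
#' \describe{
#'   \item{exp2}{`a * exp(b d)`}
#'   \item{exp3}{`a * exp(b d^g)`}
#'   \item{exp4}{`a * (c - (c-1) exp(-b d))`}
#'   \item{exp5}{`a * (c - (c-1) exp(-b d^g))`}
#'   \item{hill}{`a + b d^g / (c^g + d^g)`}
#'   \item{power}{`a + b d^g`}
#'   \item{michaelis_menten}{`a + b d / (c + d)`}
#'   \item{linear}{`a + b d`}
#' }
#'
#' @return Character vector of the eight model names.
#' @export
dr_models <- function() {
  c("exp2", "exp3", "exp4", "exp5", "hill", "power", "michaelis_menten",
    "linear")
}

# internal integer ids used by the compiled sampler
.model_id <- c(exp2 = 1L, exp3 = 2L, exp4 = 3L, exp5 = 4L, hill = 5L,
               power = 6L, michaelis_menten = 7L, linear = 8L)

# parameter names per model (sigma is handled separately)
.model_pars <- list(
  exp2 = c("a", "b"),
  exp3 = c("a", "b", "g"),
  exp4 = c("a", "b", "c"),
  exp5 = c("a", "b", "c", "g"),
  hill = c("a", "b", "c", "g"),
  power = c("a", "b", "g"),
  michaelis_menten = c("a", "b", "c"),
  linear = c("a", "b")
)

#' Model specification
#'
#' Builds a model specification: the mean-function name, its parameter set
#' and the parameter constraints under which the curve is finite,
#' non-negative and non-decreasing over the observed dose range.
#'
#' @param name One of [dr_models()].
#' @return An object of class `dr_model_spec`.
#' @export
dr_model_spec <- function(name) {
  name <- match.arg(name, dr_models())
  structure(list(name = name, parameters = .model_pars[[name]]),
            class = "dr_model_spec")
}

#' @export
print.dr_model_spec <- function(x, ...) {
  cat("<dr_model_spec>", x$name, "(", paste(x$parameters, collapse = ", "),
      ")\n")
  invisible(x)
}

.check_theta <- function(name, theta) {
  pars <- .model_pars[[name]]
  missing <- setdiff(pars, names(theta))
  if (length(missing))
    stop("model '", name, "' needs parameter(s): ",
         paste(missing, collapse = ", "))
  if ("g" %in% pars && theta[["g"]] <= 0)
    stop("parameter g must be > 0")
  if (name %in% c("hill", "michaelis_menten") && theta[["c"]] <= 0)
    stop("parameter c must be > 0 for ", name)
  if (name %in% c("exp4", "exp5") && theta[["c"]] <= 1)
    stop("parameter c must be > 1 for ", name)
  invisible(TRUE)
}

#' Evaluate a dose-response mean function
#'
#' @param model Model name (see [dr_models()]) or a `dr_model_spec`.
#' @param theta Named list or vector with entries among `a`, `b`, `c`, `g`
#'   (response-percent and mg/L scales). `0^g` is 0 for `g > 0`.
#' @param dose Numeric vector of doses (mg/L, `>= 0`).
#' @return Mean response (%) at each dose.
#' @examples
#' dr_evaluate("hill", c(a = 10, b = 90, c = 60, g = 2), c(0, 60, 300))
#' @export
dr_evaluate <- function(model, theta, dose) {
  if (inherits(model, "dr_model_spec")) model <- model$name
  model <- match.arg(model, dr_models())
  if (any(dose < 0)) stop("dose must be >= 0")
  theta <- as.list(theta)
  .check_theta(model, theta)
  a <- theta$a; b <- theta$b; c <- theta$c; g <- theta$g
  switch(model,
    exp2 = a * exp(b * dose),
    exp3 = a * exp(b * dose^g),
    exp4 = a * (c - (c - 1) * exp(-b * dose)),
    exp5 = a * (c - (c - 1) * exp(-b * dose^g)),
    hill = a + b * dose^g / (c^g + dose^g),
    power = a + b * dose^g,
    michaelis_menten = a + b * dose / (c + dose),
    linear = a + b * dose)
}

# Elementwise evaluation: theta components are equal-length vectors (one entry
# per posterior draw), dose is a scalar or a vector of the same length.
# Used by the vectorized bisection solver. No validation (hot path).
.eval_vec <- function(model, a, b, c, g, dose) {
  switch(model,
    exp2 = a * exp(b * dose),
    exp3 = a * exp(b * dose^g),
    exp4 = a * (c - (c - 1) * exp(-b * dose)),
    exp5 = a * (c - (c - 1) * exp(-b * dose^g)),
    hill = a + b * dose^g / (c^g + dose^g),
    power = a + b * dose^g,
    michaelis_menten = a + b * dose / (c + dose),
    linear = a + b * dose)
}

#' Summary-statistic log-likelihood
#'
#' Log-likelihood evaluated from per-group sufficient statistics
#' `(n_i, m_i, s_i)`. For the constant-variance normal error model:
#' \deqn{\sum_i \left[-n_i \log\sigma -
#'   \frac{(n_i-1)s_i^2 + n_i(m_i - f(d_i))^2}{2\sigma^2}\right]}
#' The additive constant \eqn{-(N/2)\log 2\pi} is omitted consistently.
#' When raw replicates are reduced to these sufficient statistics the value
#' equals the sum of per-observation normal log-densities up to that
#' constant.
#'
#' For the lognormal error model the same form is applied to log-scale
#' moments matched from the printed summaries
#' (`slog_i^2 = log(1 + s_i^2/m_i^2)`, `mlog_i = log m_i - slog_i^2/2`),
#' with `f` parameterizing the median response and `sigma` the log-scale
#' SD; the per-observation Jacobian term (a data-only constant) is
#' omitted.
#'
#' @param model Model name.
#' @param theta Named parameter vector/list (see [dr_evaluate()]).
#' @param data A [dose_response_data()] object.
#' @param sigma Residual SD (`> 0`): response percent for `"normal"`,
#'   log-response for `"lognormal"`.
#' @param likelihood Error model (default `"normal"`).
#' @return Scalar log-likelihood (constant omitted).
#' @export
dr_loglik <- function(model, theta, data, sigma,
                      likelihood = c("normal", "lognormal")) {
  stopifnot(inherits(data, "dr_data"))
  likelihood <- match.arg(likelihood)
  if (sigma <= 0) stop("sigma must be > 0")
  f <- dr_evaluate(model, theta, data$dose)
  w <- .work_stats(data, likelihood)
  fw <- if (likelihood == "lognormal") log(f) else f
  n <- data$n
  sum(-n * log(sigma) -
        ((n - 1) * w$s2 + n * (w$y - fw)^2) / (2 * sigma^2))
}

#' Default priors for a dose-response model fit
#'
#' Weakly-informative box priors defined on an internally rescaled problem
#' (dose divided by the maximum observed dose, response divided by 100):
#' background `a` is uniform on (0, 2 x max observed mean response]; the
#' increment/rate parameters are constrained jointly with `a` so that the
#' prior mean response stays within (0, `plateau_max` x 100]% over the
#' observed dose range (e.g. for the Hill model `b | a` is uniform on
#' (0, `plateau_max` - a')); the exponent `g` is uniform on (0, `g_max`];
#' the half-saturation dose `c` for hill/michaelis_menten is uniform on
#' (0, `c_dose_factor` x max dose]; for exp4/exp5 the fold-range `c` spans
#' (1, plateau/a]; the residual SD has a half-Cauchy prior with scale
#' `sigma_scale` x 100 (%).
#'
#' @param a_upper_factor Upper bound of `a` as a multiple of the maximum
#'   observed mean response (default 2).
#' @param b_rate_max Upper bound of the exp4/exp5 rate parameter on the
#'   rescaled dose axis (default 50).
#' @param c_dose_factor Upper bound of `c` (hill/michaelis_menten) as a
#'   multiple of the maximum dose (default 10).
#' @param g_min,g_max Bounds of the exponent `g` (defaults 1 and 15). The
#'   default `g_min = 1` is the standard benchmark-dose restriction
#'   excluding curves with infinite slope at dose 0, which otherwise
#'   produce degenerate near-zero benchmark concentrations; set
#'   `g_min = 0` for the unrestricted supralinear mode.
#' @param plateau_max Cap of the prior mean response as a fraction of 100%
#'   (default 2, i.e. 200%).
#' @param sigma_scale Half-Cauchy scale for the residual SD: on the
#'   rescaled response for the normal likelihood, on the log-response for
#'   the lognormal likelihood. `NULL` (default) resolves to 0.1 (normal)
#'   or 0.25 (lognormal).
#' @return An object of class `bmc_prior` (a list of the above).
#' @export
prior_config <- function(a_upper_factor = 2, b_rate_max = 50,
                         c_dose_factor = 10, g_min = 1, g_max = 15,
                         plateau_max = 2, sigma_scale = NULL) {
  stopifnot(a_upper_factor > 0, b_rate_max > 0, c_dose_factor > 0,
            g_min >= 0, g_max > g_min, plateau_max > 0,
            is.null(sigma_scale) || sigma_scale > 0)
  structure(list(a_upper_factor = a_upper_factor, b_rate_max = b_rate_max,
                 c_dose_factor = c_dose_factor, g_min = g_min,
                 g_max = g_max, plateau_max = plateau_max,
                 sigma_scale = sigma_scale),
            class = "bmc_prior")
}

# Realized prior bounds for one dataset on the rescaled problem.
.prior_bounds <- function(prior, data, likelihood = "lognormal") {
  rmax <- max(data$mean) / 100
  sig_scale <- prior$sigma_scale %||%
    if (likelihood == "lognormal") 0.25 else 0.1
  list(amax = max(prior$a_upper_factor * rmax, 0.1),
       bmax = prior$b_rate_max,
       cmax = prior$c_dose_factor,
       gmin = prior$g_min,
       gmax = prior$g_max,
       plateau = prior$plateau_max,
       sig_scale = sig_scale,
       dmax = max(data$dose))
}

# Per-group response summaries on the likelihood's working scale: the
# response scale itself for the normal model, log-scale moments matched
# from (mean, sd) for the lognormal model (in which the mean function
# parameterizes the median response).
.work_stats <- function(data, likelihood) {
  if (likelihood == "lognormal") {
    if (any(data$mean <= 0))
      stop("lognormal likelihood requires all group means > 0 ",
           "(use likelihood = \"normal\")")
    s2 <- log(1 + (data$sd / data$mean)^2)
    list(y = log(data$mean) - s2 / 2, s2 = s2)
  } else {
    list(y = data$mean, s2 = data$sd^2)
  }
}
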