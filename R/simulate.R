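#' Simulation design
#'
#' Describes a synthetic dose-response study: the true mean function and
#' parameters, the dose ladder (default: the 14-level 0-300 mg/L design of
#' the bundled fluoride study), replicates per dose, residual SD, and an
#' optional well-level mode with a fixed number of embryos per replicate.
#'
#' @param model True model name (see [dr_models()]).
#' @param theta True named parameter vector (natural units).
#' @param doses Dose ladder in mg/L, non-negative, including 0 (default
#'   `c(0, 0.5, 1, 4, 10, 20, 50, 80, 100, 120, 150, 200, 250, 300)`).
#' @param n_reps Replicates per dose (default 6).
#' @param sigma Residual SD of replicate responses in percent (default 8,
#'   the typical within-group SD of the bundled fluoride summaries).
#' @param seed Integer seed.
#' @param embryos Embryos per replicate for the well-level mode (default
#'   40).
#' @param hatch_prob Probability that a surviving embryo hatches (well
#'   mode, default 0.9).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(model, theta,
                              doses = c(0, 0.5, 1, 4, 10, 20, 50, 80, 100,
                                        120, 150, 200, 250, 300),
                              n_reps = 6, sigma = 8, seed = 1, embryos = 40,
                              hatch_prob = 0.9) {
  model <- match.arg(model, dr_models())
  .check_theta(model, as.list(theta))
  stopifnot(all(doses >= 0), 0 %in% doses, n_reps >= 1, sigma >= 0,
            embryos >= 1, hatch_prob > 0, hatch_prob <= 1)
  structure(list(model = model, theta = theta, doses = sort(unique(doses)),
                 n_reps = as.integer(n_reps), sigma = sigma,
                 seed = as.integer(seed), embryos = as.integer(embryos),
                 hatch_prob = hatch_prob),
            class = "simulation_design")
}

#' Simulate a summary dose-response dataset
#'
#' Per-dose replicate responses are drawn as Normal(f(d), sigma) truncated
#' to \[0, 100\] (responses are percentages; the truncation bias at the
#' boundaries is a documented property of the generator), then summarized
#' to `(n, mean, sd)` per group. Seed-deterministic; `sigma = 0` returns
#' group means exactly equal to `f(d)` with SD 0.
#'
#' @param design A [simulation_design()].
#' @param endpoint Endpoint label for the result.
#' @return A [dose_response_data()] object.
#' @examples
#' d <- simulation_design("linear", c(a = 10, b = 0.5), sigma = 3, seed = 7)
#' simulate_summary(d)
#' @export
simulate_summary <- function(design, endpoint = "synthetic") {
  stopifnot(inherits(design, "simulation_design"))
  f <- dr_evaluate(design$model, design$theta, design$doses)
  with_seed(design$seed, {
    reps <- lapply(seq_along(design$doses), function(i) {
      r <- stats::rnorm(design$n_reps, f[i], design$sigma)
      pmin(pmax(r, 0), 100)
    })
    n <- design$n_reps
    m <- vapply(reps, mean, 0)
    s <- if (n > 1) vapply(reps, stats::sd, 0) else rep(0, length(reps))
    dose_response_data(design$doses, n, m, s, endpoint)
  })
}

#' Simulate well-level count data
#'
#' Emulates the plate design of the bundled study: each replicate holds a
#' fixed number of embryos dying with probability `p = f(d)/100` (clamped
#' to \[0, 1\]) by 5 dpf. Deaths are spread across days 1-5 by a fixed
#' monotone logistic-in-time weight schedule applied through per-day
#' conditional hazards `h_k = 1 - (1-p)^(w_k)`, so cumulative counts are
#' non-decreasing by construction, the day-5 total is exactly
#' Binomial(embryos, p), and `p = 1` kills every embryo on day 1 (only
#' the per-day marginals matter downstream). Survivors hatch
#' independently with `hatch_prob`, and malformations among hatched
#' larvae are Binomial with the same dose-response probability.
#'
#' @param design A [simulation_design()].
#' @return A [well_counts()] data frame (one row per replicate per dose).
#' @export
simulate_wells <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  f <- dr_evaluate(design$model, design$theta, design$doses)
  p <- pmin(pmax(f / 100, 0), 1)
  # per-day weights of a fixed logistic-in-time mortality schedule
  share <- stats::plogis((1:5 - 2.5) / 0.8)
  share <- share / share[5]
  w <- diff(c(0, share))
  with_seed(design$seed, {
    rows <- lapply(seq_along(design$doses), function(i) {
      alive <- rep(design$embryos, design$n_reps)
      dead_by_day <- matrix(0L, 5, design$n_reps)
      cum <- rep(0L, design$n_reps)
      for (k in 1:5) {
        hk <- 1 - (1 - p[i])^(w[k]) # conditional hazard for day k
        died <- stats::rbinom(design$n_reps, alive, hk)
        cum <- cum + died
        alive <- alive - died
        dead_by_day[k, ] <- cum
      }
      dead5 <- cum
      survivors <- design$embryos - dead5
      hatched <- stats::rbinom(design$n_reps, survivors, design$hatch_prob)
      malformed <- stats::rbinom(design$n_reps, hatched, p[i])
      data.frame(dose = design$doses[i],
                 replicate = paste0("d", design$doses[i], "_r",
                                    seq_len(design$n_reps)),
                 n_embryos = design$embryos,
                 dead_d1 = dead_by_day[1, ], dead_d2 = dead_by_day[2, ],
                 dead_d3 = dead_by_day[3, ], dead_d4 = dead_by_day[4, ],
                 dead_d5 = dead_by_day[5, ],
                 n_hatched = hatched, n_malformed = malformed)
    })
    well_counts(do.call(rbind, rows))
  })
}
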