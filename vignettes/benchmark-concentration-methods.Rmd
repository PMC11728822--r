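---
title: "Bayesian benchmark-concentration modeling with model averaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian benchmark-concentration modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesbmc)
```

## The problem

Acute and short-term toxicity studies in zebrafish embryos expose groups of
embryos to a ladder of water concentrations of a test chemical and record
percent endpoints per replicate: cumulative mortality (CM, cumulative dead ÷
total) at 1–5 days post-fertilization and the cumulative malformation rate
(CMA, malformed ÷ hatched) at 5 dpf. From such summary tables — dose (mg/L),
replicate count, mean ± SD per group — risk assessors want three kinds of
numbers:

* **LC50/EC50**: the concentration at which the fitted response curve
  crosses 50%.
* **BMC / BMCL / BMCU**: the benchmark concentration at which the response
  rises by a benchmark response (BMR, here 10%) relative to background,
  with its lower/upper posterior bounds.
* **NOAEL / LOAEL**: the classical no/lowest-observed-adverse-effect levels
  from per-dose significance tests.

Because no single dose–response shape is "the" right one, `bayesbmc` fits
eight standard continuous models and averages them with weights reflecting
how well each predicts the data — Bayesian model averaging over a fixed
model set.

## The models

All eight mean functions share a background parameter `a` (= response at
dose 0) and are non-decreasing in dose under the fitted constraints:

| name | f(dose) | parameters |
|---|---|---|
| exp2 | a·e^(b·d) | a, b |
| exp3 | a·e^(b·d^g) | a, b, g |
| exp4 | a·(c − (c−1)·e^(−b·d)) | a, b, c |
| exp5 | a·(c − (c−1)·e^(−b·d^g)) | a, b, c, g |
| hill | a + b·d^g/(c^g + d^g) | a, b, c, g |
| power | a + b·d^g | a, b, g |
| michaelis_menten | a + b·d/(c + d) | a, b, c |
| linear | a + b·d | a, b |

`evaluate(·, dose = 0) = a` holds identically for all eight, and closed-form
inversions of `f(d) = target` exist for every model; the package uses
vectorized bisection for all of them and keeps the closed forms
(`bmc_closed_form()`, `lc50_closed_form()`) as independent cross-checks,
tested to 1e-6 relative agreement.

## Likelihood

The data are group-level sufficient statistics `(n_i, m_i, s_i)`. The
default error model is **lognormal**: replicate responses are treated as
lognormal around a median curve `f(d)`, using log-scale moments matched from
the printed summaries (`slog_i² = log(1 + s_i²/m_i²)`,
`mlog_i = log m_i − slog_i²/2`) and a constant log-scale SD σ. Two
observations drive this default:

* in percent-mortality data the group SDs scale strongly with the mean
  (here ~2% SD at 6% response, ~20% SD at 50% response, 0 at 100%),
  which is the lognormal signature, not the constant-variance one;
* a constant-variance normal fit of the linear model necessarily
  reproduces the (weighted) least-squares intercept/slope ratio, which on
  the bundled data puts the linear-model BMC ~50% above the value the
  reference analysis reports, while the lognormal fit lands on it almost
  exactly. The per-model benchmark table essentially identifies the error
  model.

The constant-variance normal likelihood of the classical summary-statistic
form

  Σᵢ [ −nᵢ log σ − ((nᵢ−1)sᵢ² + nᵢ(mᵢ − f(dᵢ))²)/(2σ²) ]

remains fully implemented (`likelihood = "normal"`), equals the sum of
per-observation normal densities up to a constant (tested against a brute
force per-observation oracle), and is the right choice when responses can
be 0. The lognormal path requires all group means to be positive and errors
out otherwise. Responses are bounded in [0,100] but neither likelihood is
truncated, matching common benchmark-dose practice; predictions above 100%
are possible in principle and are capped in prior support (below).

## Priors and parameter constraints

Fitting happens on a rescaled problem (dose ÷ max dose, response ÷ 100) for
sampler stability; all reported quantities are back-transformed to mg/L
and %. Priors are weakly informative box priors on that scale:

* `a` uniform on (0, 2 × max observed mean response];
* the increment/rate parameters are constrained jointly with `a` so the
  prior mean response stays within (0, 200%] over the observed dose range
  (e.g. Hill's `b | a` uniform on (0, 2 − a′)); this is what makes the
  prior predictive well-behaved;
* `c` for hill/michaelis_menten uniform on (0, 10 × max dose]; for
  exp4/exp5 the fold-range `c` spans (1, 200%/a];
* the exponent `g` uniform on **[1, 15]**. The lower bound of 1 is the
  standard benchmark-dose restriction: with `g < 1` the exp3/exp5/power
  (and Hill) curves have infinite slope at dose 0, and in practice a
  `g → 0` spike soaks up any background jump, wins the predictive weights
  and drives BMC estimates to numerically zero values with failed
  convergence. The reference analysis's per-model benchmark values are
  only consistent with the restriction being active. `prior_config(g_min
  = 0)` restores the unrestricted supralinear mode;
* σ half-Cauchy with scale 0.25 (log scale, lognormal) or 10% (normal).

## Sampling and diagnostics

A componentwise adaptive random-walk Metropolis sampler (compiled, working
on logistic-transformed parameters) runs 30,000 iterations with warmup
fraction 0.5 by default; step sizes adapt toward 44% acceptance during
warmup only, warmup draws are discarded, never thinned, and every draw is
bit-reproducible given the seed. Chains are initialized at a posterior mode
found from the best of 200 random starts refined by BFGS.

* **R̂**: split-chain potential scale reduction per parameter (a single
  chain is split in half — the only coherent reading of a one-chain R̂);
  gate at ≤ 1.05.
* **PPP**: posterior predictive p-value of a χ²-type discrepancy, gate at
  [0.05, 0.95]. The default discrepancy is the *omnibus* total sum of
  squares, T = Σᵢ[(nᵢ−1)sᵢ² + nᵢ(mᵢ−fᵢ)²]/σ², with fully replicated
  groups: because σ absorbs residual misfit, PPP values cluster mid-range
  for all models, which is how benchmark-dose systems that report
  near-identical PPP across well- and badly-shaped models must behave. The
  mean-only discrepancy Σᵢnᵢ(mᵢ−fᵢ)²/σ² (`ppp_stat = "means"`) is the
  sharp-misfit detector: on strongly saturating data it pushes the
  unbounded exponential-growth model below 0.05, and that behavior is
  tested.
* **LOO**: leave-one-dose-group-out expected log predictive density via
  truncated importance sampling (weights capped at √S × mean), with a
  WAIC fallback on non-finite weights. Validated against brute-force
  refit-without-each-group on small datasets.

## Benchmark quantities

* **BMR type**: relative change from control median, `f(BMC) =
  f(0)(1+BMR)`, the continuous-data default consistent with the low BMC
  magnitudes of this kind of analysis; absolute-change and SD-based
  variants sit behind `benchmark_config()`.
* **LC50/EC50**: absolute 50% response including background, not
  background-corrected extra risk — with background near 6–14% the
  absolute reading is the one consistent with a linear-model LC50 near
  148 mg/L on the 1 dpf data.
* Per-draw values solve `f(d) = target` by bisection on
  [0, 10 × max dose]; draws whose curve never reaches the target are
  undefined, counted, and excluded from summaries (with a warning above
  1%). BMCL/BMCU are the empirical 5th/95th percentiles (linear
  interpolation between order statistics, `quantile` type 7) — a
  two-sided 90% interval; the percentile pair is configurable.

## Model averaging

Weights are pseudo-Bayesian-model-averaging softmax weights on the LOO
elpd, `w_m ∝ exp(elpd_m − max elpd)`, computed through log-sum-exp (hence
shift-invariant), with fits failing the diagnostic gates excluded and
weights renormalized. WAIC weights are available as a sensitivity option.
The model-averaged BMC and LC50 distributions are resampled mixtures
(draw a model by weight, then one of its defined draws), seeded
independently of the MCMC stream; the "average" LC50 is the mixture
median, with the arithmetic mean of per-model medians also reported for
comparison since reference tables rarely state how their average row was
formed.

Two caveats discovered while validating: (1) the eight models are nested
(hill ⊇ michaelis_menten, exp3 ⊇ exp2, power ⊇ linear, exp5 ⊇ exp4), so on
data generated from one model the *family* of mimicking models absorbs the
weight rather than the single true model — the recovery tests assert the
family-level property; (2) predictive weights are not the only defensible
scheme, and on endpoints with one high-leverage group (the malformation
endpoint here, which jumps from 27% to 87% between adjacent doses) they can
legitimately rank the hyperbolic models above the sigmoidal ones where a
marginal-likelihood scheme would do the opposite; this moves the averaged
BMCL for that endpoint more than any other choice in the package.

## NOAEL/LOAEL

One-way ANOVA from sufficient statistics (exactly equal to the raw-data
ANOVA when summaries come from raw replicates — a tested identity),
followed by Fisher's LSD comparisons of each dose against control using
the pooled MSE and error df, flagged at p < 0.05 in the adverse
(mean-above-control) direction. LOAEL = smallest flagged dose, NOAEL =
largest dose below it; non-monotone flag patterns are reported as-is with
a warning, and `loael_consensus()` gives the cross-endpoint majority call.
The bundled summaries do not state the per-group replicate count (three
experiments × two plates could mean n = 3 or n = 6); n = 6 is the package
default, is recorded in every result, and is exposed as configuration.

## The synthetic-data generator

`simulation_design()` + `simulate_summary()` emulate the bundled study's
structure: a 14-level dose ladder from 0 to 300 mg/L, replicate percent
responses Normal(f(d), σ) truncated to [0, 100], summarized to
(n, mean, SD); `simulate_wells()` adds a well-level mode (40 embryos per
replicate by default) with binomial deaths spread over days 1–5 by fixed
conditional hazards, binomial hatching among survivors and binomial
malformations among the hatched. The defaults mirror the study conditions;
residual SD defaults to 8%, the typical within-group SD in the bundled
table. What the generator does *not* emulate: between-replicate
correlation within plates, dose-measurement error, time-varying hazards,
and the exact mortality/malformation dependence — so passing recovery
tests demonstrate correctness of the estimation machinery under the
model's assumptions, not robustness to real-data violations of them.

The parameter-recovery suite uses linear truth (a = 10%, b = 0.5 %/(mg/L),
σ = 3%, n = 6), giving analytic LC50 = 80 mg/L and BMC₁₀ = 2.0 mg/L, on
the study ladder restricted to 0–150 mg/L: beyond 180 mg/L the linear
truth exceeds 100% and the generator's truncation makes the simulated
truth non-linear, at which point saturating models correctly dominate and
no linear recovery target is meaningful.

## Numerical choices and problem sizes

Bisection uses 80 iterations on [0, 10 × max dose] (sub-1e-9 absolute
precision at these scales); degenerate draws with background already at or
above the target return dose 0; quantile interpolation is fixed to type 7;
the mixture size defaults to the per-fit draw count (15,000). The test
suite runs reduced problem sizes (2,000–10,000 iterations) for unit tests
and the full 30,000-iteration configuration for the end-to-end
reproduction; the six-endpoint pipeline takes well under a minute on one
CPU thanks to the compiled sampler.

## Known limitations

* Quantal (binomial) likelihoods, litter effects and covariates are out of
  scope; the analysis treats percent summaries as continuous data.
* The lognormal likelihood cannot handle groups with mean 0 (use
  `likelihood = "normal"` there).
* Model weights depend on the weighting scheme (predictive LOO here);
  reference analyses using undocumented weight formulas will not be
  reproduced weight-for-weight even when every per-model estimate agrees.
* Time-to-event structure in the daily mortality counts is summarized,
  not modeled.

## A short example

```{r example, eval = FALSE}
data <- fluoride_table3("cm_1dpf")           # bundled summary data
fit <- fit_model("hill", data)               # one model
bmc_draws(fit)                               # its BMC distribution

run <- run_bmc_analysis()                    # all 6 endpoints x 8 models
run$endpoints$cm_1dpf$bmc_table              # weights + BMC/BMCL/BMCU
run$noael$table                              # NOAEL/LOAEL per endpoint
write_bmc_run(run, "results")                # CSV + JSON + draws
```
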