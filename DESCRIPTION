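Package: bayesbmc
Title: Bayesian Benchmark Concentration Estimation with Dose-Response Model Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits eight continuous dose-response models (exponential 2-5, Hill,
    power, Michaelis-Menten, linear) to summary dose-response data (group means
    and standard deviations) by seed-deterministic Markov chain Monte Carlo,
    checks convergence (split-chain Rhat) and fit (posterior predictive p-value),
    derives per-model and model-averaged benchmark concentrations (BMC/BMCL/BMCU)
    and median lethal or effect concentrations (LC50/EC50), and calls NOAEL/LOAEL
    by one-way ANOVA with LSD post-hoc tests from sufficient statistics. Bundles
    a zebrafish embryo/sac-fry fluoride toxicity dataset (cumulative mortality at
    1-5 days post-fertilization and cumulative malformation rate at 5 dpf) and a
    synthetic-data generator emulating its design, plus a one-command pipeline
    reproducing the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Depends: R (>= 4.0)
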