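test_that("cumulative mortality and malformation rates follow the count formulas", {
  wells <- well_counts(data.frame(
    dose = c(0, 0, 100, 300), replicate = c("r1", "r2", "r1", "r1"),
    n_embryos = 40,
    dead_d1 = c(0, 0, 10, 40), dead_d2 = c(0, 2, 20, 40),
    dead_d3 = c(0, 2, 20, 40), dead_d4 = c(0, 2, 20, 40),
    dead_d5 = c(0, 4, 20, 40),
    n_hatched = c(30, 30, 18, 0), n_malformed = c(0, 15, 9, 0)))

  cm1 <- compute_cm(wells, 1)
  expect_equal(cm1$response, c(0, 0, 25, 100))
  expect_equal(compute_cm(wells, 2)$response[3], 50)

  # cumulative mortality is non-decreasing across days for every replicate
  cms <- sapply(1:5, function(day) compute_cm(wells, day)$response)
  expect_true(all(apply(cms, 1, function(r) all(diff(r) >= 0))))

  expect_warning(cma <- compute_cma(wells), "zero hatched")
  expect_equal(cma$response, c(0, 50, 50))

  expect_error(compute_cm(wells, 6), "day")
  expect_error(compute_cm(wells[0, ], 1), "empty")
  none_hatched <- wells
  none_hatched$n_malformed <- 0L
  none_hatched$n_hatched <- 0L
  expect_error(compute_cma(none_hatched), "zero hatched")
})

test_that("well-count validation rejects inconsistent counts", {
  base <- data.frame(dose = 0, replicate = "r1", n_embryos = 10,
                     dead_d1 = 2, dead_d2 = 3, dead_d3 = 3, dead_d4 = 4,
                     dead_d5 = 4, n_hatched = 5, n_malformed = 1)
  expect_s3_class(well_counts(base), "well_counts")
  bad <- base; bad$dead_d2 <- 1 # decreasing cumulative deaths
  expect_error(well_counts(bad), "non-decreasing")
  bad <- base; bad$n_malformed <- 7 # malformed > hatched
  expect_error(well_counts(bad), "n_malformed")
  bad <- base; bad$dead_d5 <- 11
  expect_error(well_counts(bad), "n_embryos")
})

test_that("summarize_groups computes replicate means and n-1 sample SDs", {
  r <- data.frame(dose = rep(c(0, 10, 20), each = 3),
                  response = c(10, 10, 10, 0, 100, 50, 20, 30, 40))
  d <- summarize_groups(r[r$dose != 10 | r$response != 50, ], "ep")
  expect_s3_class(d, "dr_data")
  expect_equal(d$mean, c(10, 50, 30))
  expect_equal(d$sd[1], 0)
  expect_equal(d$sd[2], 70.71, tolerance = 1e-4) # hand-computed sample SD
  expect_equal(d$n, c(3, 2, 3))

  expect_warning(
    single <- summarize_groups(
      data.frame(dose = c(0, 1, 2), response = c(25, 30, 40))),
    "single-replicate")
  expect_equal(single$sd, c(0, 0, 0))
  expect_equal(single$mean[1], 25)
})

test_that("summary-statistic ANOVA reproduces the raw-data ANOVA exactly", {
  for (seed in 1:5) {
    raw <- random_raw_data(seed)
    d <- summarize_groups(raw, "ep")
    res <- anova_lsd(d)
    fit <- stats::aov(response ~ factor(dose), data = raw)
    tab <- summary(fit)[[1]]
    expect_equal(res$f_statistic, tab[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$f_p, tab[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("LSD comparison equals the pooled-variance two-sample t test", {
  set.seed(3)
  raw <- data.frame(dose = rep(c(0, 50), each = 6),
                    response = c(rnorm(6, 10, 4), rnorm(6, 25, 4)))
  raw$response <- pmin(pmax(raw$response, 0), 100)
  res <- anova_lsd(raw)
  tt <- stats::t.test(response ~ dose, data = raw, var.equal = TRUE)
  expect_equal(res$table$p[res$table$dose == 50], tt$p.value,
               tolerance = 1e-12)
})

test_that("ANOVA p-values are invariant to scaling all responses", {
  raw <- random_raw_data(11)
  res1 <- anova_lsd(summarize_groups(raw))
  raw2 <- raw; raw2$response <- raw2$response * 0.5
  res2 <- anova_lsd(summarize_groups(raw2))
  expect_equal(res1$table$p, res2$table$p, tolerance = 1e-10)
  expect_equal(res1$f_p, res2$f_p, tolerance = 1e-10)
})

test_that("degenerate and flag-free datasets give safe NOAEL calls", {
  d <- dose_response_data(c(0, 10, 100), 4, c(20, 20, 20), c(5, 5, 5), "flat")
  res <- anova_lsd(d)
  expect_false(any(res$table$flagged))
  expect_equal(res$noael, 100)
  expect_true(is.na(res$loael))

  const <- dose_response_data(c(0, 10, 100), 4, c(20, 20, 20), c(0, 0, 0))
  expect_warning(res0 <- anova_lsd(const), "MSE")
  expect_false(any(res0$table$flagged))
})

test_that("the fluoride study flags 20 mg/L as the LOAEL for most endpoints", {
  eps <- fluoride_table3(n = 6)
  res1 <- anova_lsd(eps$cm_1dpf)
  expect_equal(res1$loael, 20)
  expect_equal(res1$noael, 10)

  consensus <- loael_consensus(lapply(eps, anova_lsd))
  expect_equal(consensus$majority_loael, 20)
  expect_true(sum(consensus$table$loael == 20, na.rm = TRUE) >= 4)
})

test_that("dataset validation enforces the dose-response invariants", {
  expect_error(dose_response_data(c(0, 10), 3, c(1, 2), c(0, 0)), "3 dose")
  expect_error(dose_response_data(c(0, 10, 5), 3, c(1, 2, 3), c(0, 0, 0)),
               "increasing")
  expect_error(dose_response_data(c(1, 5, 10), 3, c(1, 2, 3), c(0, 0, 0)),
               "control")
  expect_error(dose_response_data(c(0, 5, 10), 3, c(1, 2, 103), c(0, 0, 0)),
               "\\[0, 100\\]")
})

test_that("the bundled fluoride table round-trips through the CSV reader", {
  eps <- fluoride_table3()
  expect_named(eps, c(paste0("cm_", 1:5, "dpf"), "cma_5dpf"))
  for (d in eps) {
    expect_equal(nrow(d), 14)
    expect_equal(d$dose[1], 0)
    expect_equal(max(d$dose), 300)
    expect_true(all(d$mean <= 100 & d$mean >= 0))
  }
  expect_equal(eps$cm_1dpf$mean[14], 100)
  expect_equal(eps$cm_1dpf$sd[14], 0)
})
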