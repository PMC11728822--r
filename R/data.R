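#' Dose-response summary dataset
#'
#' Container for one toxicity endpoint summarized per dose group: dose
#' (mg/L), replicate count, mean response (%) and sample SD (%). Doses must
#' be strictly increasing, include exactly one control at dose 0, and there
#' must be at least 3 groups.
#'
#' @param dose Numeric vector of doses (mg/L), strictly increasing,
#'   containing exactly one 0.
#' @param n Replicate counts per group (scalar recycled, or vector).
#' @param mean Mean response per group, percent in \[0, 100\].
#' @param sd Sample SD per group, percent `>= 0` (0 is allowed, e.g. for
#'   all-dead groups).
#' @param endpoint Endpoint label, e.g. `"cm_1dpf"` or `"cma_5dpf"`.
#' @return A data frame of class `dr_data` with columns `dose`, `n`,
#'   `mean`, `sd` and attribute `endpoint`.
#' @examples
#' dose_response_data(c(0, 10, 100), 6, c(5, 20, 90), c(2, 6, 4), "cm_1dpf")
#' @export
dose_response_data <- function(dose, n, mean, sd, endpoint = "endpoint") {
  k <- length(dose)
  if (k < 3) stop("need at least 3 dose groups")
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  if (sum(dose == 0) != 1) stop("exactly one control group at dose 0 required")
  n <- rep_len(as.numeric(n), k)
  if (length(mean) != k || length(sd) != k)
    stop("mean and sd must match dose in length")
  if (any(mean < 0 | mean > 100)) stop("mean response must be in [0, 100]%")
  if (any(sd < 0)) stop("sd must be >= 0")
  if (any(n < 1)) stop("n must be >= 1")
  out <- data.frame(dose = as.numeric(dose), n = n, mean = as.numeric(mean),
                    sd = as.numeric(sd))
  attr(out, "endpoint") <- endpoint
  class(out) <- c("dr_data", "data.frame")
  out
}

#' @export
print.dr_data <- function(x, ...) {
  cat("<dose-response data>", attr(x, "endpoint"), "-", nrow(x),
      "dose groups\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

endpoint_label <- function(data) attr(data, "endpoint") %||% "endpoint"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Well-level count data
#'
#' Validates a data frame of per-replicate embryo counts: `dose` (mg/L),
#' `replicate` (label), `n_embryos`, cumulative dead counts `dead_d1` ..
#' `dead_d5` (non-decreasing across days), `n_hatched` and cumulative
#' `n_malformed` (malformed <= hatched <= embryos).
#'
#' @param x Data frame with the columns above.
#' @return `x` with class `well_counts` prepended.
#' @export
well_counts <- function(x) {
  need <- c("dose", "replicate", "n_embryos", paste0("dead_d", 1:5),
            "n_hatched", "n_malformed")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(x$dose < 0)) stop("dose must be >= 0")
  dead <- as.matrix(x[paste0("dead_d", 1:5)])
  if (any(dead < 0) || any(dead > x$n_embryos))
    stop("cumulative dead counts must be within [0, n_embryos]")
  if (any(apply(dead, 1, function(r) any(diff(r) < 0))))
    stop("cumulative dead counts must be non-decreasing across days")
  if (any(x$n_hatched > x$n_embryos) || any(x$n_hatched < 0))
    stop("n_hatched must be within [0, n_embryos]")
  if (any(x$n_malformed > x$n_hatched) || any(x$n_malformed < 0))
    stop("n_malformed must be within [0, n_hatched]")
  class(x) <- unique(c("well_counts", class(x)))
  x
}

#' Cumulative mortality per replicate
#'
#' Cumulative mortality (CM) at a given day post-fertilization:
#' 100 x cumulative dead at that day / total embryos, per replicate.
#'
#' @param wells A [well_counts()] data frame.
#' @param day Day post-fertilization, 1 to 5.
#' @return Data frame with columns `dose`, `replicate`, `response` (%).
#' @export
compute_cm <- function(wells, day) {
  wells <- well_counts(wells)
  if (nrow(wells) == 0) stop("empty well data")
  if (length(day) != 1 || !day %in% 1:5) stop("day must be in 1..5")
  data.frame(dose = wells$dose, replicate = wells$replicate,
             response = 100 * wells[[paste0("dead_d", day)]] / wells$n_embryos)
}

#' Cumulative malformation rate per replicate
#'
#' Cumulative malformation rate (CMA) at 5 dpf: 100 x malformed / hatched
#' per replicate. Replicates with zero hatched larvae are undefined and are
#' excluded with a warning; if no replicate hatched, an error is raised.
#'
#' @param wells A [well_counts()] data frame.
#' @return Data frame with columns `dose`, `replicate`, `response` (%).
#' @export
compute_cma <- function(wells) {
  wells <- well_counts(wells)
  if (nrow(wells) == 0) stop("empty well data")
  keep <- wells$n_hatched > 0
  if (!any(keep)) stop("all replicates have zero hatched larvae; CMA undefined")
  if (any(!keep))
    warning(sum(!keep), " replicate(s) with zero hatched larvae excluded")
  w <- wells[keep, ]
  data.frame(dose = w$dose, replicate = w$replicate,
             response = 100 * w$n_malformed / w$n_hatched)
}

#' Summarize per-replicate responses into a dose-response dataset
#'
#' Groups per-replicate responses by dose and records replicate count, mean
#' and sample SD (denominator `n - 1`). A single-replicate group gets SD 0
#' with a warning.
#'
#' @param responses Data frame with columns `dose` and `response` (%), e.g.
#'   from [compute_cm()].
#' @param endpoint Endpoint label for the result.
#' @return A [dose_response_data()] object.
#' @export
summarize_groups <- function(responses, endpoint = "endpoint") {
  stopifnot(all(c("dose", "response") %in% names(responses)))
  doses <- sort(unique(responses$dose))
  n <- m <- s <- numeric(length(doses))
  single <- FALSE
  for (i in seq_along(doses)) {
    r <- responses$response[responses$dose == doses[i]]
    n[i] <- length(r)
    m[i] <- mean(r)
    s[i] <- if (n[i] > 1) stats::sd(r) else { single <- TRUE; 0 }
  }
  if (single)
    warning("single-replicate group(s): SD set to 0")
  dose_response_data(doses, n, m, s, endpoint)
}

#' One-way ANOVA with LSD post-hoc comparisons from sufficient statistics
#'
#' Computes the one-way ANOVA F test over all dose groups from `(n, mean,
#' sd)` sufficient statistics and then compares each dose with the control
#' (dose 0) by Fisher's least significant difference test using the pooled
#' mean squared error and its error degrees of freedom. A dose is flagged
#' adverse when the two-sided LSD p-value is below `alpha` and its mean
#' lies above the control mean. The LOAEL is the smallest flagged dose and
#' the NOAEL the largest dose below it; non-monotone flag patterns are
#' reported as-is with a warning.
#'
#' Identical to a raw-data ANOVA when the summaries were computed from raw
#' replicates (sufficient-statistic identity). When every group is constant
#' (pooled MSE 0) no test is performed and nothing is flagged.
#'
#' @param data A [dose_response_data()] object, or a data frame of raw
#'   replicates with columns `dose` and `response`.
#' @param n Assumed per-group replicate count overriding `data$n` (the
#'   bundled fluoride tables do not state it; 6 is the package default
#'   there). `NULL` uses the counts in `data`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `noael_result`: list with `endpoint`,
#'   `table` (dose, mean, t, p, flagged), `noael`, `loael`, `assumed_n`,
#'   `f_statistic`, `f_p`.
#' @export
anova_lsd <- function(data, n = NULL, alpha = 0.05) {
  if (!inherits(data, "dr_data")) {
    stopifnot(all(c("dose", "response") %in% names(data)))
    # summarize directly: the test is defined for as few as two groups,
    # fewer than dose_response_data's modeling invariant requires
    doses <- sort(unique(data$dose))
    data <- do.call(rbind, lapply(doses, function(dd) {
      r <- data$response[data$dose == dd]
      data.frame(dose = dd, n = length(r), mean = mean(r),
                 sd = if (length(r) > 1) stats::sd(r) else 0)
    }))
    attr(data, "endpoint") <- "endpoint"
  }
  if (!is.null(n)) data$n <- rep_len(as.numeric(n), nrow(data))
  if (nrow(data) < 2) stop("need at least 2 groups")
  if (any(data$n < 2)) stop("need n >= 2 per group for the LSD test")
  k <- nrow(data)
  N <- sum(data$n)
  grand <- sum(data$n * data$mean) / N
  ss_between <- sum(data$n * (data$mean - grand)^2)
  ss_within <- sum((data$n - 1) * data$sd^2)
  df1 <- k - 1
  df2 <- N - k
  mse <- ss_within / df2

  ctrl <- which(data$dose == 0)
  if (length(ctrl) != 1) stop("exactly one control group at dose 0 required")

  if (mse <= 0) {
    warning("pooled MSE is 0 (all groups constant): no test performed")
    tab <- data.frame(dose = data$dose, mean = data$mean, t = NA_real_,
                      p = NA_real_, flagged = FALSE)
    f_stat <- f_p <- NA_real_
  } else {
    f_stat <- (ss_between / df1) / mse
    f_p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
    se <- sqrt(mse * (1 / data$n + 1 / data$n[ctrl]))
    tval <- (data$mean - data$mean[ctrl]) / se
    pval <- 2 * stats::pt(abs(tval), df2, lower.tail = FALSE)
    tval[ctrl] <- NA_real_
    pval[ctrl] <- NA_real_
    flagged <- !is.na(pval) & pval < alpha & data$mean > data$mean[ctrl]
    tab <- data.frame(dose = data$dose, mean = data$mean, t = tval, p = pval,
                      flagged = flagged)
  }

  flagged_doses <- tab$dose[tab$flagged]
  if (length(flagged_doses)) {
    loael <- min(flagged_doses)
    below <- tab$dose[tab$dose < loael]
    noael <- if (length(below)) max(below) else NA_real_
    above <- tab$dose > loael
    if (any(above & !tab$flagged & tab$dose != 0))
      warning("non-monotone significance pattern: dose(s) above the LOAEL ",
              "are not flagged")
  } else {
    loael <- NA_real_
    noael <- max(tab$dose)
  }

  structure(list(endpoint = endpoint_label(data), table = tab, noael = noael,
                 loael = loael, assumed_n = data$n,
                 f_statistic = f_stat, f_p = f_p, alpha = alpha),
            class = "noael_result")
}

#' @export
print.noael_result <- function(x, ...) {
  cat("<NOAEL/LOAEL>", x$endpoint, "\n")
  cat("  F =", format(x$f_statistic, digits = 4), " p =",
      format(x$f_p, digits = 3), "\n")
  cat("  NOAEL:", x$noael, "mg/L   LOAEL:", x$loael, "mg/L  (n per group:",
      paste(unique(x$assumed_n), collapse = "/"), ")\n")
  invisible(x)
}

#' Cross-endpoint LOAEL consensus
#'
#' Summarizes per-endpoint NOAEL/LOAEL calls and reports the majority
#' (modal) LOAEL across endpoints.
#'
#' @param results List of [anova_lsd()] results.
#' @return List with `table` (endpoint, noael, loael) and `majority_loael`
#'   (the most frequent defined LOAEL; ties resolved to the smallest).
#' @export
loael_consensus <- function(results) {
  tab <- data.frame(
    endpoint = vapply(results, function(r) r$endpoint, ""),
    noael = vapply(results, function(r) r$noael, 0),
    loael = vapply(results, function(r) r$loael, 0))
  lo <- tab$loael[!is.na(tab$loael)]
  majority <- if (length(lo)) {
    counts <- table(lo)
    as.numeric(names(counts)[counts == max(counts)])[1]
  } else NA_real_
  list(table = tab, majority_loael = majority)
}

#' Read a dose-response CSV
#'
#' Reads either the summary format (columns `endpoint`, `dose_mg_L`, `n`
#' (optional), `mean_pct`, `sd_pct`) or the long replicate format (columns
#' `endpoint`, `dose_mg_L`, `replicate`, `response_pct`).
#'
#' @param path CSV file path.
#' @param n Assumed replicate count for summary files lacking an `n` column.
#' @return Named list of [dose_response_data()] objects, one per endpoint.
#' @export
read_dose_response <- function(path, n = 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("endpoint", "dose_mg_L", "mean_pct", "sd_pct") %in% names(df))) {
    split_df <- split(df, df$endpoint)
    out <- lapply(split_df, function(d) {
      d <- d[order(d$dose_mg_L), ]
      nn <- if ("n" %in% names(d)) d$n else n
      dose_response_data(d$dose_mg_L, nn, d$mean_pct, d$sd_pct,
                         endpoint = d$endpoint[1])
    })
  } else if (all(c("endpoint", "dose_mg_L", "replicate", "response_pct")
                 %in% names(df))) {
    split_df <- split(df, df$endpoint)
    out <- lapply(split_df, function(d) {
      summarize_groups(data.frame(dose = d$dose_mg_L,
                                  response = d$response_pct),
                       endpoint = d$endpoint[1])
    })
  } else {
    stop("unrecognized CSV layout: need summary columns ",
         "(endpoint, dose_mg_L, mean_pct, sd_pct) or long columns ",
         "(endpoint, dose_mg_L, replicate, response_pct)")
  }
  out[order(match(names(out), c(paste0("cm_", 1:5, "dpf"), "cma_5dpf")))]
}

#' Zebrafish fluoride toxicity summary data
#'
#' The bundled dose-response summary table for water-fluoride exposure of
#' zebrafish embryo/sac-fry stages: cumulative mortality (CM) at 1-5 days
#' post-fertilization and cumulative malformation rate (CMA) at 5 dpf, for
#' 14 dose groups from 0 to 300 mg/L (mean +/- SD per group). The
#' per-group replicate count is not part of the published summaries; `n`
#' sets the assumed count (default 6, i.e. three experiments times two
#' plates) and is recorded in the returned objects.
#'
#' @param endpoint Optional endpoint name (`"cm_1dpf"` .. `"cm_5dpf"`,
#'   `"cma_5dpf"`); `NULL` returns all six.
#' @param n Assumed replicate count per dose group (default 6).
#' @return A [dose_response_data()] object, or a named list of all six.
#' @export
fluoride_table3 <- function(endpoint = NULL, n = 6) {
  path <- system.file("extdata", "fluoride_zebrafish_summary.csv",
                      package = "bayesbmc", mustWork = TRUE)
  out <- read_dose_response(path, n = n)
  if (is.null(endpoint)) return(out)
  endpoint <- match.arg(endpoint, names(out))
  out[[endpoint]]
}
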