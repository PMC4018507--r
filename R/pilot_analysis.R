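## Short-term pilot-evaluation statistics: a single post-campaign month is
## compared against the preceding baseline months with a one-sample t test
## using the prediction-variance inflation sd*sqrt(1 + 1/n), plus the two
## descriptive excess measures (vs the same month one year earlier, and vs
## baseline mean + 2 sd).

.series_counts <- function(series, region = NULL) {
  df <- as.data.frame(series)
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  agg <- stats::aggregate(count ~ month, data = df, FUN = sum)
  agg <- agg[order(agg$month), ]
  stats::setNames(agg$count, agg$month)
}

#' Test a single month for a step change against the preceding baseline
#'
#' One-sample t test of the test-month count against the mean of all
#' earlier months:
#' \deqn{t = (obs - \bar{x}) / (s\sqrt{1 + 1/n}),}
#' with a two-sided p-value from the t distribution on `n - 1` degrees of
#' freedom. The `sqrt(1 + 1/n)` factor is the prediction standard error for
#' a new observation; `variant = "plain"` drops it. Also reports the
#' percentage excess versus the same calendar month one year earlier (when
#' available) and versus baseline mean + 2 sd.
#'
#' @param series A `pilot_series` (or data frame with `month`, `region`,
#'   `count`); counts are pooled over regions.
#' @param test_month 1-based index of the month under test; all earlier
#'   months form the baseline (at least 3 required).
#' @param variant `"prediction"` (default) or `"plain"`.
#' @return Object of class `step_test_result` with `t_statistic`, `p_value`,
#'   `baseline_mean`, `baseline_sd`, `baseline_n`, `observed`,
#'   `pct_vs_same_month_prior_year`, `pct_vs_mean_plus_2sd`.
#' @export
step_change_ttest <- function(series, test_month,
                              variant = c("prediction", "plain")) {
  variant <- match.arg(variant)
  counts <- .series_counts(series)
  months <- as.integer(names(counts))
  if (!test_month %in% months) stop("test_month not present in series")
  baseline <- counts[months < test_month]
  if (length(baseline) < 3)
    stop("need at least 3 baseline months before test_month")
  m <- mean(baseline); s <- stats::sd(baseline); n <- length(baseline)
  if (s == 0) stop("degenerate baseline: zero variance")
  obs <- counts[[as.character(test_month)]]
  se <- if (variant == "prediction") s * sqrt(1 + 1 / n) else s
  t_stat <- (obs - m) / se
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  yoy <- if ((test_month - 12) %in% months &&
             counts[[as.character(test_month - 12)]] > 0)
    year_on_year_increase(series, test_month) else NA_real_
  ref2sd <- m + 2 * s
  structure(list(t_statistic = t_stat, p_value = p,
                 baseline_mean = m, baseline_sd = s, baseline_n = n,
                 observed = obs,
                 pct_vs_same_month_prior_year = yoy,
                 pct_vs_mean_plus_2sd = (obs - ref2sd) / ref2sd,
                 variant = variant, test_month = test_month),
            class = "step_test_result")
}

#' @export
print.step_test_result <- function(x, ...) {
  cat(sprintf("step-change t test, month %d: observed %.0f vs baseline %.1f (sd %.1f, n=%d)\n",
              x$test_month, x$observed, x$baseline_mean, x$baseline_sd,
              x$baseline_n))
  cat(sprintf("  t = %.3f, two-sided p = %.4g\n", x$t_statistic, x$p_value))
  if (!is.na(x$pct_vs_same_month_prior_year))
    cat(sprintf("  %+.1f%% vs same month prior year\n",
                100 * x$pct_vs_same_month_prior_year))
  cat(sprintf("  %+.1f%% vs baseline mean + 2sd\n",
              100 * x$pct_vs_mean_plus_2sd))
  invisible(x)
}

#' Year-on-year increase for one calendar month
#'
#' @param series A `pilot_series`; counts pooled over regions.
#' @param month 1-based month index; the same calendar month one year
#'   earlier (`month - 12`) must exist with a positive count.
#' @return Fractional increase `(this year - last year) / last year`.
#' @export
year_on_year_increase <- function(series, month) {
  counts <- .series_counts(series)
  months <- as.integer(names(counts))
  if (!month %in% months) stop("month not present in series")
  prior <- month - 12
  if (!prior %in% months) stop("no same calendar month one year earlier")
  prev <- counts[[as.character(prior)]]
  if (prev == 0) stop("prior-year count is zero; increase undefined")
  (counts[[as.character(month)]] - prev) / prev
}

#' Step-change tests per region and pooled
#'
#' Runs [step_change_ttest()] on each region's series and on the
#' region-summed series.
#'
#' @inheritParams step_change_ttest
#' @return List with one `step_test_result` per region plus `"pooled"`.
#' @export
pooled_and_regional_tests <- function(series, test_month,
                                      variant = c("prediction", "plain")) {
  variant <- match.arg(variant)
  df <- as.data.frame(series)
  regions <- unique(df$region)
  if (length(regions) < 1) stop("series must contain at least one region")
  out <- lapply(regions, function(r)
    step_change_ttest(df[df$region == r, , drop = FALSE], test_month, variant))
  names(out) <- regions
  out$pooled <- step_change_ttest(df, test_month, variant)
  out
}
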