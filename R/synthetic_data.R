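## Synthetic fixtures for every model input that is not published: an
## England-like age structure with Gompertz all-cause mortality, a
## stage-ordered CRC survival fixture, and seeded Poisson pilot-style
## monthly incidence series. These are explicitly NOT registry/ONS data;
## they have plausible shapes and documented constants only.

#' Synthetic demography fixture
#'
#' Deterministic single-year-of-age population (ages 30-100) with a
#' Gompertz-like all-cause mortality schedule. The `"england_like"` preset
#' shapes the pyramid proportionally to the Gompertz survival curve from age
#' 30 (a stationary-population approximation) and scales it to the requested
#' total; `"uniform"` spreads the total evenly across ages.
#'
#' @param total_population Total persons aged 30+ (default 33 million, the
#'   modelled England 30+ population).
#' @param shape `"england_like"` or `"uniform"`.
#' @param gompertz `c(rate30, slope)`: mortality hazard `rate30 *
#'   exp(slope * (age - 30))`.
#' @return Object of class `demography`: data frame fields `age` (30-100),
#'   `population`, `all_cause_mortality` (annual death probability).
#' @examples
#' demo <- make_demography_fixture(33e6, "england_like")
#' sum(demo$population)
#' @export
make_demography_fixture <- function(total_population = 33e6,
                                    shape = c("england_like", "uniform"),
                                    gompertz = c(6e-4, 0.085)) {
  if (total_population <= 0) stop("total_population must be > 0")
  shape <- match.arg(shape)
  ages <- 30:100
  hazard <- gompertz[1] * exp(gompertz[2] * (ages - 30))
  mortality <- -expm1(-hazard)
  weights <- switch(shape,
    england_like = exp(-cumsum(c(0, hazard[-length(hazard)]))),
    uniform = rep(1, length(ages)))
  population <- total_population * weights / sum(weights)
  structure(list(age = ages, population = population,
                 all_cause_mortality = mortality,
                 shape = shape, gompertz = gompertz),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("demography fixture ('%s'): ages %d-%d, total %.0f persons\n",
              x$shape, min(x$age), max(x$age), sum(x$population)))
  invisible(x)
}

## Annual death probability at a given age (vectorised over age).
.other_cause_mortality <- function(demography, age) {
  stats::approx(demography$age, demography$all_cause_mortality, xout = age,
                rule = 2)$y
}

## Documented fixture constants: per-stage 5-year CRC-specific survival and
## the declining hazard weights across years since diagnosis.
.SURV_5Y <- c(A = 0.95, B = 0.80, C = 0.55, D = 0.10)
.SURV_YEAR_WEIGHTS <- c(1.6, 1.3, 1.0, 0.8, 0.6)

#' Synthetic stage-specific CRC survival fixture
#'
#' Annual CRC-specific death probabilities by Dukes' stage and year since
#' diagnosis (years 1-5). The default preset fixes 5-year CRC-specific
#' survival at A 0.95, B 0.80, C 0.55, D 0.10 and distributes the total
#' hazard over years 1-5 with declining weights (1.6, 1.3, 1.0, 0.8, 0.6),
#' so stage ordering A best to D worst holds in every year band. The
#' `"null"` preset sets all CRC death probabilities to zero (useful to check
#' that without excess mortality the campaign gains no life-years).
#'
#' @param preset `"default"` or `"null"`.
#' @return Object of class `survival_fixture`: a 4x5 matrix
#'   `annual_death_prob` (rows Dukes' A-D, columns years 1-5 since
#'   diagnosis) plus the preset name.
#' @export
make_survival_fixture <- function(preset = c("default", "null")) {
  preset <- match.arg(preset)
  years <- paste0("year", 1:5)
  if (preset == "null") {
    m <- matrix(0, 4, 5, dimnames = list(DUKES_STAGES, years))
  } else {
    w <- .SURV_YEAR_WEIGHTS / sum(.SURV_YEAR_WEIGHTS)
    total_h <- -log(.SURV_5Y)
    m <- -expm1(-outer(total_h, w))
    dimnames(m) <- list(DUKES_STAGES, years)
  }
  structure(list(annual_death_prob = m, preset = preset),
            class = "survival_fixture")
}

#' Constant-hazard annual CRC death probability per stage
#'
#' The cohort engine does not carry a time-since-diagnosis dimension, so the
#' year-banded fixture is collapsed to its constant-hazard equivalent over
#' the first five years: `1 - (prod(1 - p_year))^(1/5)`.
#'
#' @param survival A [make_survival_fixture()] object.
#' @return Named numeric over Dukes' stages.
#' @export
survival_annual_death_probs <- function(survival) {
  stopifnot(inherits(survival, "survival_fixture"))
  surv5 <- apply(1 - survival$annual_death_prob, 1, prod)
  1 - surv5^(1 / 5)
}

#' @export
print.survival_fixture <- function(x, ...) {
  cat(sprintf("survival fixture ('%s'); annual CRC death probability:\n", x$preset))
  print(round(x$annual_death_prob, 4))
  invisible(x)
}

#' Specification of a synthetic pilot-style monthly incidence series
#'
#' @param n_months Number of months.
#' @param baseline_mean Mean monthly count under the null.
#' @param step_month_index 1-based month whose mean is multiplied by
#'   `step_multiplier` (the one-month campaign-effect analogue).
#' @param step_multiplier Multiplicative step (1 = no step).
#' @param n_regions Number of regions; counts are independent per region
#'   with the baseline mean split equally unless `region_means` is given.
#' @param region_means Optional per-region baseline means.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return Object of class `pilot_series_spec`.
#' @export
pilot_series_spec <- function(n_months = 24, baseline_mean = 300,
                              step_month_index = 14, step_multiplier = 1.10,
                              n_regions = 1, region_means = NULL,
                              seed = 1L) {
  if (baseline_mean <= 0) stop("baseline_mean must be > 0")
  if (step_month_index < 1 || step_month_index > n_months)
    stop("step_month_index must lie within 1..n_months")
  if (step_multiplier < 0) stop("step_multiplier must be >= 0")
  if (is.null(region_means))
    region_means <- rep(baseline_mean / n_regions, n_regions)
  stopifnot(length(region_means) == n_regions)
  structure(list(n_months = n_months, baseline_mean = baseline_mean,
                 step_month_index = step_month_index,
                 step_multiplier = step_multiplier,
                 n_regions = n_regions, region_means = region_means,
                 seed = as.integer(seed)),
            class = "pilot_series_spec")
}

## Evaluate fn with a temporary RNG state seeded from `seed`.
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic monthly CRC incidence series
#'
#' Seeded Poisson counts per month and region; the step month's mean is
#' `baseline_mean * step_multiplier`. Identical specs (including seed)
#' produce identical series.
#'
#' @param spec A [pilot_series_spec()].
#' @return Object of class `pilot_series`: data frame with columns `month`,
#'   `region`, `count`, plus the generating spec as attribute.
#' @export
generate_pilot_incidence_series <- function(spec) {
  stopifnot(inherits(spec, "pilot_series_spec"))
  counts <- .with_seed(spec$seed, function() {
    vapply(seq_len(spec$n_regions), function(r) {
      mu <- rep(spec$region_means[r], spec$n_months)
      mu[spec$step_month_index] <- mu[spec$step_month_index] * spec$step_multiplier
      stats::rpois(spec$n_months, mu)
    }, integer(spec$n_months))
  })
  df <- data.frame(
    month = rep(seq_len(spec$n_months), times = spec$n_regions),
    region = rep(paste0("region", seq_len(spec$n_regions)),
                 each = spec$n_months),
    count = as.integer(counts))
  structure(df, class = c("pilot_series", "data.frame"), spec = spec)
}

#' Read/write a pilot series as CSV (columns month, region, count)
#'
#' @param series A `pilot_series` (or compatible data frame).
#' @param path File path.
#' @return `write_pilot_series` returns `path` invisibly;
#'   `read_pilot_series` returns a `pilot_series`.
#' @export
write_pilot_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("month", "region", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pilot_series
#' @export
read_pilot_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("month", "region", "count")
  if (!all(needed %in% names(df)))
    stop("pilot series CSV must have columns month, region, count")
  if (any(df$count < 0)) stop("pilot series counts must be >= 0")
  structure(df[, needed], class = c("pilot_series", "data.frame"))
}
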