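## Experiment drivers: deterministic base case, duration x magnitude
## sensitivity grid (all-stage and stage-restricted), probabilistic
## sensitivity analysis, and the screening-uptake equivalence search.

#' Base-case incremental evaluation
#'
#' Runs the no-campaign comparator and the campaign scenario on identical
#' inputs and returns the incremental comparison.
#'
#' @param model A [crc_model()].
#' @param campaign A [campaign_scenario()] (default: the base case, a 10 \%
#'   presentation-rate increase for one month).
#' @param baseline Optional precomputed baseline outcome bundle (reused by
#'   the grid driver); computed when `NULL`.
#' @return A `ce_result` with the baseline and campaign scenario bundles
#'   attached as attributes `"base"` and `"intervention"`.
#' @export
run_base_case <- function(model, campaign = campaign_scenario(),
                          baseline = NULL) {
  stopifnot(inherits(model, "crc_model"))
  mats <- .model_matrices(model, campaign)
  init <- .init_population(model, mats = mats)
  if (is.null(baseline))
    baseline <- .scenario_outcomes(model, NULL, init, mats = mats)
  intervention <- .scenario_outcomes(model, campaign, init, mats = mats)
  out <- incremental_ce(baseline, intervention, model$econ$wtp_threshold)
  attr(out, "base") <- baseline
  attr(out, "intervention") <- intervention
  out
}

#' Duration x magnitude sensitivity grid
#'
#' Evaluates the campaign over all combinations of duration (months) and
#' magnitude (fractional all-stage incidence increase). When
#' `stage_restricted` is `TRUE` the increase is applied to Dukes' stages C
#' and D only, scaled by their incidence share so the all-stage incidence
#' rise is matched (see [equivalent_stage_restricted_multiplier()]).
#'
#' @param model A [crc_model()].
#' @param durations Numeric vector of campaign durations in months.
#' @param magnitudes Numeric vector of fractional increases.
#' @param stage_restricted Restrict the increase to stages C and D.
#' @param template Campaign cost/attendance parameters to reuse
#'   (default [campaign_scenario()]).
#' @return A `grid_result` data frame: one row per cell with
#'   `duration_months`, `magnitude`, `deaths_prevented`, `qaly_gain`,
#'   `icer`, `nmb`, `delta_cost`.
#' @export
run_sensitivity_grid <- function(model, durations = c(1, 3, 6),
                                 magnitudes = c(0.05, 0.10, 0.20),
                                 stage_restricted = FALSE,
                                 template = campaign_scenario()) {
  stopifnot(length(durations) > 0, length(magnitudes) > 0)
  init <- .init_population(model)
  baseline <- .scenario_outcomes(model, NULL, init)
  cells <- expand.grid(duration_months = durations, magnitude = magnitudes)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- cells$duration_months[i]; m <- cells$magnitude[i]
    mult <- if (stage_restricted) {
      m_cd <- equivalent_stage_restricted_multiplier(
        m, model$stage_distribution, c("C", "D"))
      c(A = 0, B = 0, C = m_cd, D = m_cd)
    } else c(A = m, B = m, C = m, D = m)
    sc <- template
    sc$stage_multipliers <- mult
    sc$duration_months <- d
    ce <- incremental_ce(baseline, .scenario_outcomes(model, sc, init),
                         model$econ$wtp_threshold)
    data.frame(duration_months = d, magnitude = m,
               deaths_prevented = ce$deaths_prevented,
               qaly_gain = ce$delta_qaly, icer = ce$icer, nmb = ce$nmb,
               delta_cost = ce$delta_cost)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", "data.frame")
  out
}

## --- PSA sampling -----------------------------------------------------

## Beta draw with mean m and sd rel_se*m (method of moments); degenerate
## means (0, 1) or rel_se = 0 stay fixed.
.sample_beta <- function(m, rel_se) {
  out <- m
  idx <- which(m > 0 & m < 1 & rel_se > 0)
  for (i in idx) {
    v <- min((rel_se * m[i])^2, 0.9 * m[i] * (1 - m[i]))
    k <- m[i] * (1 - m[i]) / v - 1
    out[i] <- stats::rbeta(1, m[i] * k, (1 - m[i]) * k)
  }
  out
}

## Gamma draw with mean m and sd rel_se*m; zero means or rel_se = 0 fixed.
.sample_gamma <- function(m, rel_se) {
  out <- m
  idx <- which(m > 0 & rel_se > 0)
  shape <- 1 / rel_se^2
  for (i in idx) out[i] <- stats::rgamma(1, shape = shape,
                                         scale = m[i] / shape)
  out
}

.resample_until <- function(draw, ok, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    x <- draw()
    if (ok(x)) return(x)
  }
  stop("could not draw a parameter set satisfying ordering constraints")
}

## One sampled parameter set: natural-history probabilities and test
## characteristics (Beta), utilities (Beta, ordering preserved), unit and
## treatment costs (Gamma). Participation, campaign and adverse-event
## parameters stay at their point estimates.
.sample_model <- function(model, rel_se) {
  nh0 <- model$nh
  sample_curve <- function(curve) age_curve(curve$ages,
                                            .sample_beta(curve$values, rel_se))
  pres <- .resample_until(
    function() .sample_beta(nh0$presentation, rel_se),
    function(p) !is.unsorted(p, strictly = TRUE))
  nh <- natural_history_params(
    adenoma_onset = sample_curve(nh0$adenoma_onset),
    lr_to_hr = sample_curve(nh0$lr_to_hr),
    hr_to_crcA = sample_curve(nh0$hr_to_crcA),
    normal_to_crcA = .sample_beta(nh0$normal_to_crcA, rel_se),
    stage_progression = .sample_beta(nh0$stage_progression, rel_se),
    presentation = pres,
    proximal_fraction = nh0$proximal_fraction,
    adenomas_per_carrier = nh0$adenomas_per_carrier,
    advanced_hr_fraction = nh0$advanced_hr_fraction)
  t0 <- model$tests
  tests <- test_characteristics(
    gfobt_sens = .sample_beta(t0$gfobt_sens, rel_se),
    gfobt_spec = sample_curve(t0$gfobt_spec),
    col_sens = .sample_beta(t0$col_sens, rel_se),
    col_spec = .sample_beta(t0$col_spec, rel_se))
  e0 <- model$econ
  ut <- .resample_until(
    function() c(.sample_beta(e0$utility_cancer_free, rel_se),
                 .sample_beta(e0$utility_crc, rel_se)),
    function(u) u[2] < u[1])
  rng <- e0$treatment_cost_ranges
  lo <- .sample_gamma(rng[, "min"], rel_se)
  hi <- .sample_gamma(rng[, "max"], rel_se)
  econ <- economic_params(
    utility_cancer_free = ut[1], utility_crc = ut[2],
    discount_rate = e0$discount_rate, wtp_threshold = e0$wtp_threshold,
    treatment_cost_ranges = cbind(min = pmin(lo, hi), max = pmax(lo, hi)),
    treatment_cost_age_direction = e0$treatment_cost_age_direction,
    screening_costs = .sample_gamma(e0$screening_costs, rel_se))
  m <- model
  m$nh <- nh; m$tests <- tests; m$econ <- econ
  m
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_samples` parameter sets (Beta for probabilities and utilities,
#' Gamma for costs, with standard error `rel_se` times the mean), reruns
#' the incremental comparison for each draw, and summarises the 2.5-97.5
#' percentile intervals. With `rel_se = 0` every draw reproduces the
#' deterministic result exactly.
#'
#' @param model A [crc_model()].
#' @param campaign A [campaign_scenario()].
#' @param n_samples Number of parameter sets (at least 2).
#' @param seed Integer seed; results are a pure function of
#'   `(model, campaign, n_samples, seed, rel_se)`.
#' @param rel_se Relative standard error of the sampling distributions.
#' @return Object of class `psa_result`: `samples` (one row per draw:
#'   `deaths_prevented`, `qaly_gain`, `delta_cost`, `icer`, `nmb`),
#'   `intervals` (2.5/97.5 percentiles per output), `n_samples`, `seed`.
#' @export
run_psa <- function(model, campaign = campaign_scenario(), n_samples = 1000,
                    seed = 1L, rel_se = 0.1) {
  stopifnot(inherits(model, "crc_model"), n_samples >= 2)
  samples <- .with_seed(seed, function() {
    rows <- vector("list", n_samples)
    for (k in seq_len(n_samples)) {
      mk <- if (rel_se > 0) .sample_model(model, rel_se) else model
      ce <- run_base_case(mk, campaign)
      rows[[k]] <- data.frame(draw = k,
                              deaths_prevented = ce$deaths_prevented,
                              qaly_gain = ce$delta_qaly,
                              delta_cost = ce$delta_cost,
                              icer = ce$icer, nmb = ce$nmb)
    }
    do.call(rbind, rows)
  })
  outs <- c("deaths_prevented", "qaly_gain", "delta_cost", "icer", "nmb")
  intervals <- t(vapply(outs, function(o)
    stats::quantile(samples[[o]], c(0.025, 0.975), na.rm = TRUE, names = FALSE),
    numeric(2)))
  colnames(intervals) <- c("p2.5", "p97.5")
  structure(list(samples = samples, intervals = intervals,
                 n_samples = n_samples, seed = seed, rel_se = rel_se),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d parameter sets (seed %d, rel. SE %.0f%%)\n",
              x$n_samples, x$seed, 100 * x$rel_se))
  print(round(x$intervals, 1))
  invisible(x)
}

#' Screening-uptake change equivalent to the campaign's QALY gain
#'
#' Searches for the relative reduction in the screening never-participant
#' share that yields the same QALY gain (without any campaign) as a target,
#' typically the campaign's own QALY gain. Mass removed from the
#' never-participant group is moved to the ever-participant group at
#' baseline. The response is continuous and increasing in the reduction, so
#' the equation is solved by root bisection.
#'
#' @param model A [crc_model()].
#' @param target_qaly_gain Positive QALY gain to match.
#' @param tol Absolute tolerance on the matched QALY gain.
#' @param response Optional replacement response function mapping the
#'   relative reduction in the never share to a QALY gain (used for
#'   verification); defaults to the model-based response.
#' @return List: `relative_reduction`, `absolute_reduction` (percentage
#'   points of the population), `never_share_before`, `never_share_after`,
#'   `achieved_qaly_gain`.
#' @export
screening_uptake_equivalence <- function(model, target_qaly_gain,
                                         tol = 1e-2, response = NULL) {
  if (target_qaly_gain < 0) stop("target_qaly_gain must be >= 0")
  never0 <- 1 - model$behaviour$ever_participation
  if (is.null(response)) {
    init0 <- .init_population(model)
    q0 <- accumulate_qalys(run_population(model, init = init0))$qaly_disc
    response <- function(x) {
      init <- init0
      moved <- x * init$occ[, 1, , drop = FALSE]
      init$occ[, 1, ] <- init$occ[, 1, ] - moved[, 1, ]
      init$occ[, 2, ] <- init$occ[, 2, ] + moved[, 1, ]
      accumulate_qalys(run_population(model, init = init))$qaly_disc - q0
    }
  }
  if (target_qaly_gain == 0) {
    x <- 0
  } else {
    gmax <- response(1)
    if (gmax < target_qaly_gain)
      stop("target QALY gain unattainable even with full uptake conversion")
    x <- stats::uniroot(function(z) response(z) - target_qaly_gain,
                        lower = 0, upper = 1, f.lower = -target_qaly_gain,
                        f.upper = gmax - target_qaly_gain,
                        tol = 1e-6)$root
  }
  list(relative_reduction = x,
       absolute_reduction = x * never0,
       never_share_before = never0,
       never_share_after = never0 * (1 - x),
       achieved_qaly_gain = response(x))
}
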