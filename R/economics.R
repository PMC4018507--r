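## Health-economic evaluation: discounted costs, life-years, QALYs and the
## incremental comparison (ICER, net monetary benefit).

#' Discount factor
#'
#' `(1 + rate)^(-t)`; outcomes in the first model year (cycle 1) take
#' `t = 0` and are undiscounted.
#'
#' @param t Time in years since the start of the model (vectorised).
#' @param rate Annual discount rate.
#' @return Dimensionless factor(s).
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) stop("t must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  (1 + rate)^(-t)
}

#' Stage- and age-dependent CRC treatment cost
#'
#' Maps the per-stage published cost range linearly over age at diagnosis.
#' Under the default `"max_at_youngest"` direction the range maximum applies
#' at age 30 and the minimum at age 100 (more aggressive treatment at
#' younger ages); `"min_at_youngest"` reverses the mapping.
#'
#' @param stage Dukes' stage, `"A"`-`"D"` (vectorised).
#' @param age Age at diagnosis in years (vectorised).
#' @param econ An [economic_params()] object.
#' @return Treatment cost in GBP.
#' @export
treatment_cost <- function(stage, age, econ) {
  rng <- econ$treatment_cost_ranges[stage, , drop = FALSE]
  frac <- pmin(pmax((age - 30) / 70, 0), 1)
  if (econ$treatment_cost_age_direction == "max_at_youngest")
    rng[, "max"] + frac * (rng[, "min"] - rng[, "max"])
  else
    rng[, "min"] + frac * (rng[, "max"] - rng[, "min"])
}

.cost_breakdown <- function(screening_related, cancer_management,
                            gp_consultations_referrals, campaign_delivery,
                            undiscounted = NULL) {
  total <- screening_related + cancer_management +
    gp_consultations_referrals + campaign_delivery
  structure(list(screening_related = screening_related,
                 cancer_management = cancer_management,
                 gp_consultations_referrals = gp_consultations_referrals,
                 campaign_delivery = campaign_delivery,
                 total = total, undiscounted = undiscounted),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Discounted costs (GBP)\n")
  for (nm in c("screening_related", "cancer_management",
               "gp_consultations_referrals", "campaign_delivery", "total"))
    cat(sprintf("  %-28s %14.0f\n", nm, x[[nm]]))
  invisible(x)
}

## Per-(cohort, age) discount factors aligned with a trace's event arrays.
.trace_discounts <- function(trace, rate) {
  outer(trace$start_ages, trace$ages,
        function(s, a) ifelse(a >= s, (1 + rate)^(-(a - s)), 0))
}

#' Accumulate discounted costs from a trace
#'
#' Screening-related costs price the per-cycle screening events (completed
#' kits by result, non-complier handling, follow-up and surveillance
#' colonoscopies, pathology per colonoscopy specimen, and expected
#' colonoscopy adverse events). Cancer-management costs charge the stage-
#' and age-dependent treatment cost once per diagnosis, at the diagnosis
#' cycle. Campaign delivery and GP attendance costs are taken from
#' `campaign_costs` and fall in the first year (discount factor 1).
#'
#' @param trace A `cohort_trace` from [run_population()].
#' @param econ An [economic_params()]; defaults to the trace's model.
#' @param campaign_costs Optional [campaign_direct_costs()] result.
#' @return A `cost_breakdown` with discounted components, their sum, and an
#'   `undiscounted` twin.
#' @export
accumulate_costs <- function(trace, econ = trace$model$econ,
                             campaign_costs = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  ae <- trace$model$ae
  sc <- econ$screening_costs
  ev <- trace$events
  n_col <- ev[, , "colonoscopies"] + ev[, , "surveillance_colonoscopies"]
  n_poly <- ev[, , "polypectomies"]
  n_scr_dx <- ev[, , "scr_dx_A"] + ev[, , "scr_dx_B"] +
    ev[, , "scr_dx_C"] + ev[, , "scr_dx_D"]
  perf <- n_poly * ae$perforation_prob_polypectomy +
    pmax(n_col - n_poly, 0) * ae$perforation_prob_no_polypectomy
  ## unit costs per completed screen/procedure; pathology is charged per
  ## colonoscopy specimen (removed adenoma or detected cancer)
  screening_cells <-
    sc[["gfobt_noncomplier"]] * ev[, , "gfobt_noncompliant"] +
    sc[["gfobt_normal"]] * ev[, , "gfobt_normal"] +
    sc[["gfobt_positive"]] * ev[, , "gfobt_positive"] +
    sc[["colonoscopy"]] * n_col +
    sc[["pathology"]] * (n_poly + n_scr_dx) +
    perf * ae$perforation_cost +
    n_col * ae$bleed_hospitalisation_prob * ae$bleed_cost

  ages_m <- matrix(trace$ages, nrow = length(trace$start_ages),
                   ncol = length(trace$ages), byrow = TRUE)
  cancer_cells <- 0
  for (i in seq_along(DUKES_STAGES)) {
    dx <- ev[, , paste0("sym_dx_", DUKES_STAGES[i])] +
      ev[, , paste0("scr_dx_", DUKES_STAGES[i])]
    unit <- treatment_cost(rep(DUKES_STAGES[i], length(ages_m)),
                           as.numeric(ages_m), econ)
    cancer_cells <- cancer_cells + dx * matrix(unit, nrow = nrow(ages_m))
  }

  disc <- .trace_discounts(trace, econ$discount_rate)
  gp <- if (is.null(campaign_costs)) 0 else
    campaign_costs$gp_and_secondary_attendance
  delivery <- if (is.null(campaign_costs)) 0 else
    campaign_costs$campaign_delivery
  .cost_breakdown(
    screening_related = sum(screening_cells * disc),
    cancer_management = sum(cancer_cells * disc),
    gp_consultations_referrals = gp,
    campaign_delivery = delivery,
    undiscounted = list(screening_related = sum(screening_cells),
                        cancer_management = sum(cancer_cells),
                        gp_consultations_referrals = gp,
                        campaign_delivery = delivery))
}

#' Accumulate life-years and QALYs from a trace
#'
#' Each model year, alive occupancy accrues one life-year weighted by the
#' state utility (clinical CRC states take the cancer utility, all other
#' alive states the cancer-free utility) and the calendar discount factor.
#' With the half-cycle correction enabled, the mean of start- and
#' end-of-year occupancy is used instead of the start-of-year value.
#'
#' @param trace A `cohort_trace`.
#' @param econ An [economic_params()]; defaults to the trace's model.
#' @return List: `ly_undisc`, `ly_disc`, `qaly_disc` (and `qaly_undisc`).
#' @export
accumulate_qalys <- function(trace, econ = trace$model$econ) {
  stopifnot(inherits(trace, "cohort_trace"))
  u <- numeric(length(CRC_STATES))
  u[STATES_ALIVE] <- econ$utility_cancer_free
  u[STATES_CLINICAL] <- econ$utility_crc
  alive <- numeric(length(CRC_STATES)); alive[STATES_ALIVE] <- 1

  occ <- trace$occupancy
  n_c <- dim(occ)[1]; n_age <- length(trace$ages)
  acc <- occ[, -n_age, , drop = FALSE]        # start-of-year occupancy
  if (isTRUE(trace$model$half_cycle_correction))
    acc <- (acc + occ[, -1L, , drop = FALSE]) / 2
  dim(acc) <- c(n_c * (n_age - 1L), length(CRC_STATES))
  ly_cells <- matrix(acc %*% alive, n_c, n_age - 1L)
  q_cells <- matrix(acc %*% u, n_c, n_age - 1L)
  disc <- .trace_discounts(trace, econ$discount_rate)[, -n_age, drop = FALSE]
  list(ly_undisc = sum(ly_cells), ly_disc = sum(ly_cells * disc),
       qaly_undisc = sum(q_cells), qaly_disc = sum(q_cells * disc))
}

## Full per-scenario evaluation used by the experiment drivers.
.scenario_outcomes <- function(model, campaign = NULL, init = NULL,
                               mats = NULL) {
  if (is.null(init)) init <- .init_population(model, mats = mats)
  trace <- .simulate(model, campaign, init, mats = mats)
  cc <- if (is.null(campaign)) NULL else
    campaign_direct_costs(campaign, model$campaign_population)
  costs <- accumulate_costs(trace, model$econ, cc)
  qalys <- accumulate_qalys(trace, model$econ)
  ev <- trace$events
  sym <- vapply(DUKES_STAGES, function(s)
    sum(ev[, , paste0("sym_dx_", s)]), numeric(1))
  scr <- vapply(DUKES_STAGES, function(s)
    sum(ev[, , paste0("scr_dx_", s)]), numeric(1))
  list(trace = trace, costs = costs, qalys = qalys,
       sym_dx = sym, scr_dx = scr,
       crc_deaths = sum(ev[, , "crc_deaths"]),
       deaths_undiag_crc = sum(ev[, , "other_deaths_undiag_crc"]))
}

#' Incremental cost-effectiveness comparison
#'
#' Componentwise differences between a campaign scenario and its
#' no-campaign comparator run on identical inputs, with the ICER
#' (`delta_cost / delta_qaly`, defined when `delta_qaly > 0`) and net
#' monetary benefit (`wtp * delta_qaly - delta_cost`).
#'
#' @param base,intervention Scenario outcome bundles as produced internally
#'   by the experiment drivers (each holding a `cost_breakdown`, the
#'   [accumulate_qalys()] list, cumulative diagnoses by stage and route, and
#'   death totals).
#' @param wtp Willingness-to-pay threshold (GBP per QALY).
#' @return Object of class `ce_result`.
#' @export
incremental_ce <- function(base, intervention, wtp = 20000) {
  delta_cost <- intervention$costs$total - base$costs$total
  delta_qaly <- intervention$qalys$qaly_disc - base$qalys$qaly_disc
  icer <- if (delta_qaly > 0) delta_cost / delta_qaly else NA_real_
  structure(list(
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    delta_ly_undisc = intervention$qalys$ly_undisc - base$qalys$ly_undisc,
    delta_ly_disc = intervention$qalys$ly_disc - base$qalys$ly_disc,
    icer = icer,
    nmb = wtp * delta_qaly - delta_cost,
    wtp = wtp,
    dominated = delta_qaly <= 0 && delta_cost >= 0 &&
      !(delta_qaly == 0 && delta_cost == 0),
    deaths_prevented = base$crc_deaths - intervention$crc_deaths,
    deaths_with_undiagnosed_crc_change =
      intervention$deaths_undiag_crc - base$deaths_undiag_crc,
    delta_sym_dx = intervention$sym_dx - base$sym_dx,
    delta_scr_dx = intervention$scr_dx - base$scr_dx,
    delta_costs = list(
      screening_related = intervention$costs$screening_related -
        base$costs$screening_related,
      cancer_management = intervention$costs$cancer_management -
        base$costs$cancer_management,
      gp_consultations_referrals =
        intervention$costs$gp_consultations_referrals -
        base$costs$gp_consultations_referrals,
      campaign_delivery = intervention$costs$campaign_delivery -
        base$costs$campaign_delivery)),
    class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Incremental comparison vs no campaign\n")
  cat(sprintf("  CRC deaths prevented        %10.1f\n", x$deaths_prevented))
  cat(sprintf("  QALYs gained (discounted)   %10.1f\n", x$delta_qaly))
  cat(sprintf("  life-years gained (undisc.) %10.1f\n", x$delta_ly_undisc))
  cat(sprintf("  incremental cost            %10.0f\n", x$delta_cost))
  cat(sprintf("  ICER (GBP/QALY)             %10s\n",
              if (is.na(x$icer)) "undefined" else sprintf("%.0f", x$icer)))
  cat(sprintf("  NMB at WTP %.0f            %10.0f\n", x$wtp, x$nmb))
  invisible(x)
}

#' Tabulate an incremental result in outcome-decomposition form
#'
#' @param ce A `ce_result`.
#' @return Data frame with columns `outcome` and `value`: incidence change
#'   by stage and diagnosis route, deaths, discounted cost components,
#'   life-years, QALYs, ICER and NMB.
#' @export
ce_table <- function(ce) {
  stopifnot(inherits(ce, "ce_result"))
  data.frame(
    outcome = c(paste0("symptomatic_dx_", DUKES_STAGES), "symptomatic_dx_total",
                paste0("screen_detected_dx_", DUKES_STAGES),
                "screen_detected_dx_total",
                "crc_deaths", "deaths_with_undiagnosed_crc",
                "cost_screening_related", "cost_cancer_management",
                "cost_gp_consultations_referrals", "cost_campaign_delivery",
                "cost_total", "life_years_undiscounted",
                "life_years_discounted", "qalys_discounted", "icer", "nmb"),
    value = c(ce$delta_sym_dx, sum(ce$delta_sym_dx),
              ce$delta_scr_dx, sum(ce$delta_scr_dx),
              -ce$deaths_prevented, ce$deaths_with_undiagnosed_crc_change,
              ce$delta_costs$screening_related,
              ce$delta_costs$cancer_management,
              ce$delta_costs$gp_consultations_referrals,
              ce$delta_costs$campaign_delivery,
              ce$delta_cost, ce$delta_ly_undisc, ce$delta_ly_disc,
              ce$delta_qaly, ce$icer, ce$nmb),
    row.names = NULL)
}
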