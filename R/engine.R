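## The multi-cohort engine. Every current age cohort (ages 30..max_age) is
## simulated with annual cycles from its present age to max_age/death.
## Iteration is age-major: at age step `a` every cohort that has reached age
## `a` is advanced by the same age-specific matrix, so the whole population
## advances with one matrix product per age. Calendar time for a cohort
## starting at age s is t = a - s (t = 0 in the first model year, when the
## one-off campaign applies).

EVENT_NAMES <- c("sym_dx_A", "sym_dx_B", "sym_dx_C", "sym_dx_D",
                 "scr_dx_A", "scr_dx_B", "scr_dx_C", "scr_dx_D",
                 "crc_deaths", "other_deaths", "other_deaths_undiag_crc",
                 "invitations", "gfobt_noncompliant", "gfobt_normal",
                 "gfobt_positive", "colonoscopies",
                 "surveillance_colonoscopies", "polypectomies")

#' Assemble a complete model specification
#'
#' Bundles the natural-history, screening, adverse-event and economic
#' parameters with the demography and survival fixtures and the programme
#' settings into one object consumed by [run_population()] and the
#' experiment drivers.
#'
#' @param nh [natural_history_params()].
#' @param tests [test_characteristics()].
#' @param behaviour [screening_behaviour()].
#' @param ae [adverse_event_params()].
#' @param econ [economic_params()].
#' @param demography [make_demography_fixture()].
#' @param survival [make_survival_fixture()].
#' @param screening List: `enabled`, `start_age`, `end_age`,
#'   `interval_years` (biennial gFOBT invitation ages) and
#'   `surveillance_interval_years`.
#' @param max_age Simulation cap in years (cohorts stop at this age).
#' @param stage_distribution Named numeric over Dukes' stages: the stage
#'   distribution of symptomatic incidence used to translate an all-stage
#'   incidence increase into a stage-restricted multiplier.
#' @param half_cycle_correction Logical; average start- and end-of-cycle
#'   occupancy when accruing life-years/QALYs (default off).
#' @param campaign_population Denominator for the campaign's per-person
#'   costs; defaults to the modelled population total.
#' @return Object of class `crc_model`.
#' @export
crc_model <- function(nh = natural_history_params(),
                      tests = test_characteristics(),
                      behaviour = screening_behaviour(),
                      ae = adverse_event_params(),
                      econ = economic_params(),
                      demography = make_demography_fixture(),
                      survival = make_survival_fixture(),
                      screening = list(enabled = TRUE, start_age = 60,
                                       end_age = 69, interval_years = 2,
                                       surveillance_interval_years = 3),
                      max_age = 100,
                      stage_distribution = c(A = 0.11, B = 0.25,
                                             C = 0.36, D = 0.29),
                      half_cycle_correction = FALSE,
                      campaign_population = NULL) {
  stopifnot(inherits(nh, "natural_history_params"),
            inherits(tests, "test_characteristics"),
            inherits(behaviour, "screening_behaviour"),
            inherits(ae, "adverse_event_params"),
            inherits(econ, "economic_params"),
            inherits(demography, "demography"),
            inherits(survival, "survival_fixture"))
  if (max_age > 100) stop("max_age cannot exceed 100 (last anchor age)")
  screening$ages <- if (isTRUE(screening$enabled))
    seq(screening$start_age, screening$end_age, by = screening$interval_years)
  else integer(0)
  stage_distribution <- stage_distribution[DUKES_STAGES]
  if (is.null(campaign_population))
    campaign_population <- sum(demography$population)
  structure(list(nh = nh, tests = tests, behaviour = behaviour, ae = ae,
                 econ = econ, demography = demography, survival = survival,
                 screening = screening, max_age = max_age,
                 stage_distribution = stage_distribution,
                 half_cycle_correction = half_cycle_correction,
                 campaign_population = campaign_population),
            class = "crc_model")
}

#' @export
print.crc_model <- function(x, ...) {
  cat("CRC natural-history/screening model\n")
  cat(sprintf("  population: %.0f persons aged %d-%d\n",
              sum(x$demography$population), min(x$demography$age), x$max_age))
  cat(sprintf("  screening: %s\n", if (length(x$screening$ages))
    paste("gFOBT at ages", paste(x$screening$ages, collapse = ", "))
    else "disabled"))
  invisible(x)
}

## Precompute transition matrices for ages min_age..(max_age-1); when a
## campaign is given, also the cycle-1 (campaign-adjusted) variants.
.model_matrices <- function(model, campaign = NULL) {
  nh <- model$nh
  ages <- min(model$demography$age):(model$max_age - 1L)
  crc_death <- survival_annual_death_probs(model$survival)
  onset <- interpolate_age_curve(nh$adenoma_onset, ages)
  lr_hr <- interpolate_age_curve(nh$lr_to_hr, ages)
  hr_ca <- interpolate_age_curve(nh$hr_to_crcA, ages)
  q <- .other_cause_mortality(model$demography, ages)
  mk <- function(pres) {
    out <- lapply(seq_along(ages), function(i)
      .build_tm(onset[i], lr_hr[i], hr_ca[i], nh$normal_to_crcA,
                nh$stage_progression, pres, crc_death, q[i]))
    names(out) <- ages
    out
  }
  base <- mk(nh$presentation)
  camp <- NULL
  if (!is.null(campaign) &&
      any(campaign$stage_multipliers > 0) && campaign$duration_months > 0)
    camp <- mk(campaign_adjusted_presentation(nh$presentation,
                                              campaign$stage_multipliers,
                                              campaign$duration_months))
  list(ages = ages, base = base, campaign = camp)
}

## Core age-major simulation.
## init: list(start_ages, population, occ = array[n_cohort, 3 groups, 14]).
## Returns occupancy[cohort, age, state] (group-summed; by-group array when
## record_groups), events[cohort, age, event].
.simulate <- function(model, campaign = NULL, init, record_groups = FALSE,
                      mats = NULL) {
  if (is.null(mats)) mats <- .model_matrices(model, campaign)
  use_camp <- !is.null(campaign) && !is.null(mats$campaign)
  ages_all <- c(mats$ages, model$max_age)
  n_ages <- length(ages_all)
  start_ages <- init$start_ages
  n_c <- length(start_ages)
  n_s <- length(CRC_STATES)
  ng <- length(BEHAVIOUR_GROUPS)

  occ <- init$occ                       # [cohort, group, state]
  trace <- array(0, dim = c(n_c, n_ages, n_s),
                 dimnames = list(NULL, ages_all, CRC_STATES))
  traceG <- if (record_groups)
    array(0, dim = c(n_c, n_ages, ng, n_s),
          dimnames = list(NULL, ages_all, BEHAVIOUR_GROUPS, CRC_STATES))
  events <- array(0, dim = c(n_c, n_ages, length(EVENT_NAMES)),
                  dimnames = list(NULL, ages_all, EVENT_NAMES))

  surv_rate <- model$behaviour$col_surveillance_compliance /
    model$screening$surveillance_interval_years
  i_never <- 1L; i_ever <- 2L; i_surv <- 3L

  pre <- STATES_PRECLINICAL; clin <- STATES_CLINICAL
  for (ai in seq_along(mats$ages)) {
    a <- mats$ages[ai]
    act <- which(start_ages <= a)
    if (!length(act)) next
    Xn <- occ[act, i_never, , drop = FALSE][, 1L, ]
    Xe <- occ[act, i_ever, , drop = FALSE][, 1L, ]
    Xs <- occ[act, i_surv, , drop = FALSE][, 1L, ]
    dim(Xn) <- dim(Xe) <- dim(Xs) <- c(length(act), n_s)

    trace[act, ai, ] <- Xn + Xe + Xs
    if (record_groups) {
      traceG[act, ai, i_never, ] <- Xn
      traceG[act, ai, i_ever, ] <- Xe
      traceG[act, ai, i_surv, ] <- Xs
    }

    ## screening within the year, before progression
    if (a %in% model$screening$ages) {
      res <- .screen_group(Xe, model$behaviour$conditional_uptake,
                           model$tests, model$behaviour, a)
      Xe <- res$occ
      Xs[, .S$clear] <- Xs[, .S$clear] + res$to_surveillance
      for (nm in colnames(res$events))
        events[act, ai, nm] <- events[act, ai, nm] + res$events[, nm]
      nev <- rowSums(Xn[, STATES_UNDIAGNOSED, drop = FALSE])
      events[act, ai, "invitations"] <- events[act, ai, "invitations"] + nev
      events[act, ai, "gfobt_noncompliant"] <-
        events[act, ai, "gfobt_noncompliant"] + nev
    }
    if (length(model$screening$ages) && any(Xs > 0)) {
      res <- .surveillance_group(Xs, surv_rate, model$tests)
      Xs <- res$occ
      for (nm in colnames(res$events))
        events[act, ai, nm] <- events[act, ai, nm] + res$events[, nm]
    }

    ## annual transition; the cohort entering this step (start age == a)
    ## experiences its first model year now, i.e. the campaign year
    M <- mats$base[[ai]]
    X <- rbind(Xn, Xe, Xs)
    rows_new <- integer(0)
    if (use_camp) {
      new_c <- which(start_ages[act] == a)
      if (length(new_c))
        rows_new <- c(new_c, new_c + length(act), new_c + 2L * length(act))
    }
    Y <- X %*% M
    if (length(rows_new)) {
      Mc <- mats$campaign[[ai]]
      Y[rows_new, ] <- X[rows_new, , drop = FALSE] %*% Mc
    }

    ## flows of interest, per row then summed over the three group blocks
    per_cohort <- function(v) v[seq_along(act)] +
      v[seq_along(act) + length(act)] + v[seq_along(act) + 2L * length(act)]
    flow <- function(from, to) {
      p <- rep(M[from, to], nrow(X))
      if (length(rows_new)) p[rows_new] <- mats$campaign[[ai]][from, to]
      per_cohort(X[, from] * p)
    }
    for (i in 1:4) {
      events[act, ai, paste0("sym_dx_", DUKES_STAGES[i])] <-
        events[act, ai, paste0("sym_dx_", DUKES_STAGES[i])] +
        flow(pre[i], clin[i])
      events[act, ai, "crc_deaths"] <- events[act, ai, "crc_deaths"] +
        flow(clin[i], .S$dead_crc)
      events[act, ai, "other_deaths_undiag_crc"] <-
        events[act, ai, "other_deaths_undiag_crc"] +
        flow(pre[i], .S$dead_other_undiag_crc)
    }
    for (s in c(.S$clear, .S$lr_adenoma, .S$hr_adenoma, STATES_CLINICAL))
      events[act, ai, "other_deaths"] <- events[act, ai, "other_deaths"] +
        flow(s, .S$dead_other)

    nb <- length(act)
    occ[act, i_never, ] <- Y[seq_len(nb), ]
    occ[act, i_ever, ] <- Y[nb + seq_len(nb), ]
    occ[act, i_surv, ] <- Y[2L * nb + seq_len(nb), ]
  }

  ## occupancy at the final (cap) age
  fin <- which(start_ages <= model$max_age)
  O <- occ[fin, , , drop = FALSE]
  trace[fin, n_ages, ] <- O[, 1L, ] + O[, 2L, ] + O[, 3L, ]
  if (record_groups) traceG[fin, n_ages, , ] <- O

  structure(list(start_ages = start_ages, population = init$population,
                 ages = ages_all, occupancy = trace,
                 occupancy_by_group = if (record_groups) traceG,
                 events = events, campaign = campaign, model = model),
            class = "cohort_trace")
}

## Burn-in: the baseline (already-alive) population carries prevalent
## adenomas and preclinical cancers. A single clear cohort is simulated from
## age 30 under status quo screening; the alive-state distribution at each
## age, renormalised, initialises the baseline cohort of that age.
.init_population <- function(model, never_share = NULL, mats = NULL) {
  behaviour <- model$behaviour
  if (is.null(never_share)) never_share <- 1 - behaviour$ever_participation
  a0 <- min(model$demography$age)
  occ0 <- array(0, dim = c(1, 3, length(CRC_STATES)))
  occ0[1, 1, .S$clear] <- never_share
  occ0[1, 2, .S$clear] <- 1 - never_share
  burn <- .simulate(model, campaign = NULL,
                    init = list(start_ages = a0, population = 1, occ = occ0),
                    record_groups = TRUE, mats = mats)
  ages <- model$demography$age[model$demography$age <= model$max_age]
  n_c <- length(ages)
  occ <- array(0, dim = c(n_c, 3, length(CRC_STATES)),
               dimnames = list(NULL, BEHAVIOUR_GROUPS, CRC_STATES))
  pop <- stats::approx(model$demography$age, model$demography$population,
                       xout = ages, rule = 2)$y
  for (i in seq_len(n_c)) {
    ai <- match(ages[i], burn$ages)
    dist <- burn$occupancy_by_group[1, ai, , ]
    dist[, STATES_ABSORBING] <- 0
    alive <- sum(dist)
    if (alive <= 0) stop("burn-in produced no survivors at age ", ages[i])
    occ[i, , ] <- pop[i] * dist / alive
  }
  list(start_ages = ages, population = pop, occ = occ)
}

#' Run the multi-cohort population simulation
#'
#' Simulates every current age cohort of the population from its present
#' age to `max_age` (or death) in annual cycles. When a
#' [campaign_scenario()] is supplied, its presentation-rate increase is
#' applied during each cohort's first model year only (the calendar campaign
#' year). Baseline cohorts are initialised with prevalent disease via a
#' burn-in of a disease-free cohort from age 30 under status quo screening.
#'
#' @param model A [crc_model()].
#' @param campaign A [campaign_scenario()], or `NULL` for the no-campaign
#'   comparator.
#' @param init Optional custom initial population, a list with
#'   `start_ages`, `population` and `occ` (array cohort x group x state).
#'   Defaults to the burn-in initialisation.
#' @param record_groups Keep the behaviour-group-resolved occupancy.
#' @return A `cohort_trace`: occupancy `[cohort, age, state]`, event tallies
#'   `[cohort, age, event]` (symptomatic and screen-detected diagnoses by
#'   stage, deaths, screening activity), cohort start ages and populations.
#' @export
run_population <- function(model, campaign = NULL, init = NULL,
                           record_groups = FALSE) {
  stopifnot(inherits(model, "crc_model"))
  if (!is.null(campaign)) stopifnot(inherits(campaign, "campaign_scenario"))
  if (is.null(init)) init <- .init_population(model)
  .simulate(model, campaign, init, record_groups)
}

#' Advance an occupancy slice by one cycle
#'
#' One-cycle multiplication of occupancy by a transition matrix, with
#' dimension and stochasticity checks. The population engine uses the same
#' product internally; this helper exposes it for oracle-style verification
#' on small instances.
#'
#' @param occupancy Numeric vector (one row) or matrix (rows = cohorts) over
#'   the matrix's states.
#' @param transition_matrix Square row-stochastic matrix.
#' @return Updated occupancy of the same shape.
#' @export
advance_cohort <- function(occupancy, transition_matrix) {
  vec <- is.null(dim(occupancy))
  X <- if (vec) matrix(occupancy, nrow = 1) else as.matrix(occupancy)
  if (ncol(X) != ncol(transition_matrix) ||
      nrow(transition_matrix) != ncol(transition_matrix))
    stop("dimension mismatch between occupancy and transition matrix")
  out <- X %*% transition_matrix
  if (vec) drop(out) else out
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("cohort_trace: %d cohorts (ages %d-%d), %d annual cycles%s\n",
              length(x$start_ages), min(x$start_ages), max(x$start_ages),
              length(x$ages) - 1L,
              if (is.null(x$campaign)) ", no campaign" else ", with campaign"))
  cat(sprintf("  total population %.0f; CRC deaths %.1f; symptomatic dx %.1f\n",
              sum(x$population), sum(x$events[, , "crc_deaths"]),
              sum(x$events[, , paste0("sym_dx_", DUKES_STAGES)])))
  invisible(x)
}

#' Export a trace as tidy data frames
#'
#' @param trace A `cohort_trace`.
#' @return List of two data frames: `occupancy` (cycle, cohort start age,
#'   state, persons) and `events` (cycle, cohort start age, event, count),
#'   zero rows dropped.
#' @export
trace_tables <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- as.data.frame.table(trace$occupancy, responseName = "persons")
  names(occ) <- c("cohort_index", "age", "state", "persons")
  occ$cohort_start_age <- trace$start_ages[as.integer(occ$cohort_index)]
  occ$age <- as.integer(as.character(occ$age))
  occ$cycle <- occ$age - occ$cohort_start_age
  occ <- occ[occ$cycle >= 0 & occ$persons != 0,
             c("cycle", "cohort_start_age", "state", "persons")]
  ev <- as.data.frame.table(trace$events, responseName = "count")
  names(ev) <- c("cohort_index", "age", "event", "count")
  ev$cohort_start_age <- trace$start_ages[as.integer(ev$cohort_index)]
  ev$age <- as.integer(as.character(ev$age))
  ev$cycle <- ev$age - ev$cohort_start_age
  ev <- ev[ev$cycle >= 0 & ev$count != 0,
           c("cycle", "cohort_start_age", "event", "count")]
  rownames(occ) <- rownames(ev) <- NULL
  list(occupancy = occ, events = ev)
}
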