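test_that("campaign-adjusted presentation follows the hazard-scaling form", {
  expect_identical(campaign_adjusted_presentation(0.74, 0, 1), 0.74)
  expect_identical(campaign_adjusted_presentation(0.74, 0.10, 0), 0.74)
  # hand computation: r = -ln(0.26) = 1.3471, scaled to 1.35833
  expect_equal(campaign_adjusted_presentation(0.74, 0.10, 1), 0.7429,
               tolerance = 1e-4)
  expect_equal(campaign_adjusted_presentation(0.74, 0.10, 1),
               1 - 0.26^(12.1 / 12), tolerance = 1e-12)
  # full-year scaling closed form
  expect_equal(campaign_adjusted_presentation(0.37, 0.10, 12),
               1 - 0.63^1.1, tolerance = 1e-12)
  expect_error(campaign_adjusted_presentation(1, 0.1, 1), "infinite hazard")
  expect_error(campaign_adjusted_presentation(0.5, -0.1, 1))
})

test_that("transition matrices are row-stochastic with correct structure", {
  nh <- natural_history_params()
  zero_death <- c(A = 0, B = 0, C = 0, D = 0)
  # clear-epithelium row at age 30, no mortality: off-diagonal mass is the
  # adenoma-onset plus direct-cancer probability (hazard-composed)
  M <- build_transition_matrix(30, nh, zero_death, other_mortality = 0)
  expect_lt(abs((1 - M["clear", "clear"]) - (0.021 + 0.00004)), 1e-5)
  expect_gt(M["clear", "lr_adenoma"], 0)
  expect_gt(M["clear", "pre_A"], 0)
  expect_equal(sum(M["clear", -c(1, 2, 4)]), 0)

  crc_death <- survival_annual_death_probs(make_survival_fixture())
  for (age in c(30, 47, 63, 85, 99)) {
    M <- build_transition_matrix(age, nh, crc_death, other_mortality = 0.02,
                                 presentation_multiplier = c(A = 0.1, B = 0.1,
                                                             C = 0.1, D = 0.1),
                                 duration_months = 1)
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
    # absorbing states stay put
    for (s in c("dead_crc", "dead_other", "dead_other_undiag_crc"))
      expect_identical(unname(M[s, s]), 1)
    # preclinical occupants who die of other causes carry undiagnosed CRC
    expect_true(all(M[c("pre_A", "pre_B", "pre_C", "pre_D"), "dead_other"] == 0))
    expect_true(all(M[c("pre_A", "pre_B", "pre_C", "pre_D"),
                      "dead_other_undiag_crc"] > 0))
  }
  # null survival fixture: no CRC deaths from clinical states
  Mn <- build_transition_matrix(60, nh, zero_death, other_mortality = 0.01)
  expect_true(all(Mn[c("clin_A", "clin_B", "clin_C", "clin_D"),
                     "dead_crc"] == 0))
})

test_that("advance_cohort reproduces hand matrix products on a toy chain", {
  P <- matrix(c(0.7, 0.2, 0.1,
                0.0, 0.6, 0.4,
                0.0, 0.0, 1.0), 3, 3, byrow = TRUE)
  x0 <- c(1, 0, 0)
  expect_equal(advance_cohort(x0, diag(3)), x0)
  x2 <- advance_cohort(advance_cohort(x0, P), P)
  expect_equal(x2, drop(x0 %*% P %*% P), tolerance = 1e-15)
  expect_equal(sum(x2), 1, tolerance = 1e-12)
  expect_error(advance_cohort(c(1, 0), P), "dimension mismatch")
})

test_that("the population engine equals a brute-force matrix-product oracle", {
  # 5 cohorts, at most 10 cycles, screening off so progression is pure
  # matrix multiplication
  model <- small_model(1e4,
                       screening = list(enabled = FALSE,
                                        surveillance_interval_years = 3),
                       max_age = 100)
  campaign <- campaign_scenario()
  start_ages <- 91:95
  n_s <- length(crc_states())
  occ0 <- array(0, dim = c(5, 3, n_s))
  pops <- c(100, 80, 60, 40, 20)
  for (c in 1:5) {                      # mixed initial states
    occ0[c, 1, 1] <- 0.3 * pops[c]
    occ0[c, 2, 1] <- 0.4 * pops[c]
    occ0[c, 2, 4] <- 0.2 * pops[c]     # preclinical A
    occ0[c, 3, 7] <- 0.1 * pops[c]     # preclinical D under surveillance
  }
  init <- list(start_ages = start_ages, population = pops, occ = occ0)
  trace <- run_population(model, campaign, init = init)

  crc_death <- survival_annual_death_probs(model$survival)
  mort <- function(a) model$demography$all_cause_mortality[
    match(a, model$demography$age)]
  for (c in 1:5) {
    x <- occ0[c, 1, ] + occ0[c, 2, ] + occ0[c, 3, ]
    for (a in start_ages[c]:99) {
      M <- if (a == start_ages[c])
        build_transition_matrix(a, model$nh, crc_death, mort(a),
                                campaign$stage_multipliers,
                                campaign$duration_months)
      else build_transition_matrix(a, model$nh, crc_death, mort(a))
      ai <- match(a, trace$ages)
      expect_equal(unname(trace$occupancy[c, ai, ]), unname(x),
                   tolerance = 1e-12)
      x <- drop(x %*% M)
    }
    expect_equal(unname(trace$occupancy[c, match(100, trace$ages), ]),
                 unname(x), tolerance = 1e-12)
  }
})

test_that("cohort mass is conserved every cycle", {
  model <- small_model(5e4)
  for (camp in list(NULL, campaign_scenario())) {
    trace <- run_population(model, camp)
    for (c in seq_along(trace$start_ages)) {
      idx <- which(trace$ages >= trace$start_ages[c])
      totals <- apply(trace$occupancy[c, idx, , drop = FALSE], 2, sum)
      expect_true(all(abs(totals - trace$population[c]) <
                        1e-9 * trace$population[c]))
    }
  }
})

test_that("a null-multiplier campaign is equivalent to no campaign", {
  model <- small_model(1e4)
  t0 <- run_population(model, NULL)
  t_null <- run_population(model, campaign_scenario(
    stage_multipliers = c(A = 0, B = 0, C = 0, D = 0), duration_months = 0))
  expect_identical(t0$occupancy, t_null$occupancy)
  expect_identical(t0$events, t_null$events)
})

test_that("without CRC mortality the campaign changes no life-years", {
  model <- small_model(1e4, survival = make_survival_fixture("null"))
  q0 <- accumulate_qalys(run_population(model, NULL))
  q1 <- accumulate_qalys(run_population(model, campaign_scenario()))
  # agreement to the within-cycle competing-risk approximation error
  expect_equal(q1$ly_undisc, q0$ly_undisc, tolerance = 1e-6)
  expect_equal(q1$ly_disc, q0$ly_disc, tolerance = 1e-6)
})

test_that("cycle-1 diagnoses scale by about m*d/12 when presentation is rare", {
  # the hazard-scaling approximation is designed for small presentation
  # probabilities; use a rare-presentation parameter set
  nh_small <- natural_history_params(
    presentation = c(A = 0.01, B = 0.02, C = 0.04, D = 0.08))
  model <- small_model(1e4, nh = nh_small)
  base <- run_population(model, NULL)
  for (m in c(0.1, 0.2)) {
    camp <- run_population(model, campaign_scenario(
      stage_multipliers = c(A = m, B = m, C = m, D = m),
      duration_months = 1))
    sym1 <- first_cycle_total(camp, "sym_dx_A") +
      first_cycle_total(camp, "sym_dx_B") +
      first_cycle_total(camp, "sym_dx_C") +
      first_cycle_total(camp, "sym_dx_D")
    sym0 <- first_cycle_total(base, "sym_dx_A") +
      first_cycle_total(base, "sym_dx_B") +
      first_cycle_total(base, "sym_dx_C") +
      first_cycle_total(base, "sym_dx_D")
    ratio <- sym1 / sym0
    expect_gt(ratio, 1 + 0.9 * m / 12)
    expect_lt(ratio, 1 + 1.1 * m / 12)
  }
})

test_that("the campaign shifts cumulative symptomatic diagnoses to earlier stages", {
  model <- small_model(1e5)
  base <- run_population(model, NULL)
  camp <- run_population(model, campaign_scenario())
  delta <- stage_event_totals(camp, "sym_dx_") -
    stage_event_totals(base, "sym_dx_")
  expect_true(all(delta[c("A", "B", "C")] > 0))
  expect_lt(delta[["D"]], 0)
})

test_that("trace exports tidy occupancy and event tables", {
  model <- small_model(1e3, max_age = 40)
  trace <- run_population(model)
  tabs <- trace_tables(trace)
  expect_true(all(c("cycle", "cohort_start_age", "state", "persons") %in%
                    names(tabs$occupancy)))
  expect_true(all(tabs$occupancy$cycle >= 0))
  expect_true(all(tabs$events$count > 0))
  # tidy table preserves total initial mass at cycle 0
  cyc0 <- tabs$occupancy[tabs$occupancy$cycle == 0, ]
  expect_equal(sum(cyc0$persons), sum(trace$population), tolerance = 1e-6)
})
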