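# Minimal hand-built traces with one cohort let the accrual arithmetic be
# checked against closed-form values.
mini_trace <- function(model, start_age, ages, fill_occ = NULL,
                       fill_events = NULL) {
  ev_names <- crcaware:::EVENT_NAMES
  occupancy <- array(0, dim = c(1, length(ages), 14),
                     dimnames = list(NULL, ages, crc_states()))
  events <- array(0, dim = c(1, length(ages), length(ev_names)),
                  dimnames = list(NULL, ages, ev_names))
  if (!is.null(fill_occ)) for (f in fill_occ)
    occupancy[1, as.character(f$age), f$state] <- f$persons
  if (!is.null(fill_events)) for (f in fill_events)
    events[1, as.character(f$age), f$event] <- f$count
  structure(list(start_ages = start_age, population = 1, ages = ages,
                 occupancy = occupancy, events = events, campaign = NULL,
                 model = model),
            class = "cohort_trace")
}

test_that("discount factors follow (1+r)^-t with cycle one undiscounted", {
  expect_identical(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_factor(c(0, 5, 40), 0), rep(1, 3))
  expect_error(discount_factor(-1, 0.035), ">= 0")
})

test_that("treatment cost maps the published ranges linearly over age", {
  econ <- economic_params()
  expect_equal(unname(treatment_cost("A", 30, econ)), 8375)
  expect_equal(unname(treatment_cost("A", 100, econ)), 1320)
  expect_equal(unname(treatment_cost("D", 65, econ)), (11198 + 772) / 2)
  rev <- economic_params(treatment_cost_age_direction = "min_at_youngest")
  expect_equal(unname(treatment_cost("A", 30, rev)), 1320)
})

test_that("QALY accrual prices alive years by state utility", {
  model <- small_model(10)
  econ0 <- economic_params(discount_rate = 0)
  # one person alive cancer-free for exactly one cycle
  tr <- mini_trace(model, 50, c(50, 51),
                   fill_occ = list(list(age = 50, state = "clear",
                                        persons = 1),
                                   list(age = 51, state = "dead_other",
                                        persons = 1)))
  q <- accumulate_qalys(tr, econ0)
  expect_equal(q$ly_undisc, 1)
  expect_equal(q$qaly_disc, 0.80)
  # the same year spent in diagnosed (clinical) cancer
  tr2 <- mini_trace(model, 50, c(50, 51),
                    fill_occ = list(list(age = 50, state = "clin_B",
                                         persons = 1)))
  expect_equal(accumulate_qalys(tr2, econ0)$qaly_disc, 0.70)
  # everyone dead: nothing accrues
  tr3 <- mini_trace(model, 50, c(50, 51),
                    fill_occ = list(list(age = 50, state = "dead_crc",
                                         persons = 1)))
  expect_equal(accumulate_qalys(tr3, econ0)$qaly_disc, 0)
  expect_equal(accumulate_qalys(tr3, econ0)$ly_undisc, 0)
})

test_that("cost accumulation prices events at published unit costs", {
  model <- small_model(10)
  # empty trace: all zero
  empty <- mini_trace(model, 30, c(30, 31))
  z <- accumulate_costs(empty)
  expect_equal(z$total, 0)
  # one Dukes' A diagnosis at the youngest age, no discounting
  tr <- mini_trace(model, 30, c(30, 31),
                   fill_events = list(list(age = 30, event = "sym_dx_A",
                                           count = 1)))
  cb <- accumulate_costs(tr, economic_params(discount_rate = 0))
  expect_equal(cb$cancer_management, 8375)
  # 1,000 normal gFOBT results in cycle 1 cost 1000 x 3.36 undiscounted
  tr2 <- mini_trace(model, 30, c(30, 31),
                    fill_events = list(list(age = 30, event = "gfobt_normal",
                                            count = 1000)))
  cb2 <- accumulate_costs(tr2, economic_params(discount_rate = 0.035))
  expect_equal(cb2$screening_related, 3360)
  # the same events one year later are discounted once
  tr3 <- mini_trace(model, 30, c(30, 31),
                    fill_events = list(list(age = 31, event = "gfobt_normal",
                                            count = 1000)))
  cb3 <- accumulate_costs(tr3, economic_params(discount_rate = 0.035))
  expect_equal(cb3$screening_related, 3360 / 1.035, tolerance = 1e-12)
})

test_that("cost breakdown components always sum to the total", {
  model <- small_model(1e4)
  camp <- campaign_scenario()
  trace <- run_population(model, camp)
  cb <- accumulate_costs(trace, model$econ,
                         campaign_direct_costs(camp, sum(model$demography$population)))
  expect_equal(cb$total,
               cb$screening_related + cb$cancer_management +
                 cb$gp_consultations_referrals + cb$campaign_delivery,
               tolerance = 1e-6)
  expect_gt(cb$screening_related, 0)
  expect_gt(cb$cancer_management, 0)
  # discounting can only shrink the components
  expect_lte(cb$screening_related, cb$undiscounted$screening_related)
  expect_lte(cb$cancer_management, cb$undiscounted$cancer_management)
})

test_that("incremental comparison satisfies the ICER and NMB identities", {
  mk <- function(total_cost, qaly) {
    list(costs = crcaware:::.cost_breakdown(total_cost, 0, 0, 0),
         qalys = list(ly_undisc = 0, ly_disc = 0, qaly_disc = qaly),
         sym_dx = c(A = 0, B = 0, C = 0, D = 0),
         scr_dx = c(A = 0, B = 0, C = 0, D = 0),
         crc_deaths = 0, deaths_undiag_crc = 0)
  }
  # the published cost/QALY deltas: 5,446,745 / 404
  ce <- incremental_ce(mk(0, 0), mk(5446745, 404), wtp = 20000)
  expect_equal(ce$icer, 5446745 / 404, tolerance = 1e-12)
  expect_lt(abs(ce$icer - 13482), 1)
  expect_equal(ce$nmb, 20000 * 404 - 5446745, tolerance = 1e-12)
  expect_equal(ce$nmb, 2633255)
  # exact identities of the returned object
  expect_equal(ce$icer * ce$delta_qaly, ce$delta_cost, tolerance = 1e-9)
  expect_equal(ce$nmb, ce$wtp * ce$delta_qaly - ce$delta_cost,
               tolerance = 1e-9)
  # identical scenarios: zero deltas, undefined ICER
  same <- incremental_ce(mk(100, 10), mk(100, 10))
  expect_equal(same$delta_cost, 0)
  expect_true(is.na(same$icer))
  expect_false(same$dominated)
  # costlier and less effective: dominated
  dom <- incremental_ce(mk(0, 10), mk(50, 5))
  expect_true(dom$dominated)
})

test_that("zero discount rate equates discounted and undiscounted results", {
  model <- small_model(1e4, econ = economic_params(discount_rate = 0))
  trace <- run_population(model, campaign_scenario())
  q <- accumulate_qalys(trace)
  expect_equal(q$ly_disc, q$ly_undisc, tolerance = 1e-12)
  expect_equal(q$qaly_disc, q$qaly_undisc, tolerance = 1e-12)
  cb <- accumulate_costs(trace)
  expect_equal(cb$screening_related, cb$undiscounted$screening_related,
               tolerance = 1e-12)
  expect_equal(cb$cancer_management, cb$undiscounted$cancer_management,
               tolerance = 1e-12)
  # and with discounting, discounted life-years are strictly smaller
  model35 <- small_model(1e4)
  q35 <- accumulate_qalys(run_population(model35))
  expect_lt(q35$ly_disc, q35$ly_undisc)
})
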