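test_that("age-curve interpolation is exact at anchors and linear between", {
  onset <- age_curve(c(30, 50, 70, 100), c(0.021, 0.020, 0.045, 0.011))
  expect_equal(interpolate_age_curve(onset, c(30, 50, 70, 100)),
               c(0.021, 0.020, 0.045, 0.011))
  # hand interpolation between (50, 0.020) and (70, 0.045)
  expect_equal(interpolate_age_curve(onset, 60), 0.0325)
  spec_curve <- test_characteristics()$gfobt_spec
  expect_equal(interpolate_age_curve(spec_curve, 70), 0.97)
  # flat extrapolation outside the two printed anchors
  expect_equal(interpolate_age_curve(spec_curve, 45, rule = "clamp"), 0.99)
  expect_equal(interpolate_age_curve(spec_curve, 80, rule = "clamp"), 0.97)
  expect_error(interpolate_age_curve(onset, 29), "out of range")
  expect_error(interpolate_age_curve(onset, 101), "out of range")
})

test_that("interpolated values are monotone between bracketing anchors", {
  curve <- age_curve(c(30, 50, 70, 100), c(0.029, 0.025, 0.054, 0.115))
  for (i in 1:3) {
    lo <- curve$ages[i]; hi <- curve$ages[i + 1]
    ages <- seq(lo, hi, length.out = 11)
    vals <- interpolate_age_curve(curve, ages)
    expect_true(all(diff(vals) * sign(curve$values[i + 1] - curve$values[i]) >= 0))
    expect_true(all(vals >= min(curve$values[i:(i + 1)]) - 1e-15))
    expect_true(all(vals <= max(curve$values[i:(i + 1)]) + 1e-15))
  }
  expect_error(age_curve(c(50, 50), c(0.1, 0.2)), "strictly increasing")
  expect_error(age_curve(c(30, 50), c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("conditional screening participation is the per-round/ever ratio", {
  expect_equal(derive_conditional_participation(0.54, 0.63), 0.54 / 0.63)
  # printed value is 0.85
  expect_lt(abs(derive_conditional_participation(0.54, 0.63) - 0.85), 0.01)
  expect_equal(derive_conditional_participation(0.5, 1.0), 0.5)
  expect_equal(derive_conditional_participation(0.0, 0.63), 0.0)
  # inverse property: (a*e, e) recovers a
  for (a in c(0.1, 0.5, 0.95)) for (e in c(0.2, 0.63, 1)) {
    expect_equal(derive_conditional_participation(a * e, e), a,
                 tolerance = 1e-12)
  }
  expect_error(derive_conditional_participation(0.5, 0), "> 0")
  expect_error(derive_conditional_participation(0.7, 0.63), "inconsistent")
})

test_that("stage-restricted multiplier matches the all-stage incidence rise", {
  shares <- c(A = 0.11, B = 0.25, C = 0.36, D = 0.29)
  m_cd <- equivalent_stage_restricted_multiplier(0.10, shares, c("C", "D"))
  expect_equal(m_cd, 0.10 / 0.65)       # printed rounded as 15 %
  expect_equal(round(100 * m_cd), 15)
  exact <- c(A = 0.2, B = 0.3, C = 0.3, D = 0.2)
  expect_equal(
    equivalent_stage_restricted_multiplier(0.10, exact,
                                           c("A", "B", "C", "D")), 0.10)
  expect_equal(
    equivalent_stage_restricted_multiplier(
      0.10, c(A = 0.5, B = 0, C = 0.25, D = 0.25), c("C", "D")), 0.20)
  # composition: restricted multiplier x restricted share = all-stage rise
  for (m in c(0.05, 0.1, 0.2)) {
    mm <- equivalent_stage_restricted_multiplier(m, exact, c("B", "D"))
    expect_equal(mm * sum(exact[c("B", "D")]), m, tolerance = 1e-12)
  }
  expect_error(
    equivalent_stage_restricted_multiplier(0.1, c(A = 1, B = 0, C = 0, D = 0),
                                           c("C", "D")), "zero")
  expect_error(
    equivalent_stage_restricted_multiplier(0.1, c(A = 0.9, B = 0.05,
                                                  C = 0.02, D = 0.2),
                                           c("C", "D")), "sum to 1")
})

test_that("campaign attendance unit cost reproduces the published arithmetic", {
  base <- campaign_scenario()
  # 0.5 x (0.0014 x 36 + 1.52606e-5 x 200); printed rounded as 0.026
  expect_equal(campaign_unit_cost_per_person(base), 0.02672606,
               tolerance = 1e-9)
  expect_lt(abs(campaign_unit_cost_per_person(base) - 0.026), 0.001)
  none <- campaign_scenario(proportion_additional = 0)
  expect_identical(campaign_unit_cost_per_person(none), 0)
  ninety <- campaign_scenario(proportion_additional = 0.9)
  expect_equal(campaign_unit_cost_per_person(ninety), 0.9 * 0.05345212,
               tolerance = 1e-9)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(natural_history_params(
    presentation = c(A = 0.2, B = 0.18, C = 0.37, D = 0.74)),
    "strictly increasing")
  expect_error(economic_params(utility_crc = 0.85), "below")
  expect_error(economic_params(treatment_cost_ranges = matrix(
    c(9000, 8375, 1479, 8362, 1493, 13862, 772, 11198), 4, 2, byrow = TRUE,
    dimnames = list(c("A", "B", "C", "D"), c("min", "max")))),
    "min must not exceed max")
  expect_error(campaign_scenario(duration_months = 13), "\\[0, 12\\]")
  expect_error(campaign_scenario(stage_multipliers = c(A = -0.1, B = 0,
                                                       C = 0, D = 0)),
               ">= 0")
  expect_error(adverse_event_params(perforation_cost = -1), ">= 0")
  b <- screening_behaviour()
  expect_equal(b$conditional_uptake, 0.54 / 0.63)
})

test_that("configuration round-trips unchanged and rejects bad input", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg, tolerance = 0)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("natural_history:", "  adenomas: 2"), bad)
  expect_error(read_config(bad), "unknown configuration key")
  writeLines(c("campaign:", "  duration_months: 13"), bad)
  expect_error(read_config(bad), "campaign.duration_months")
  writeLines(c("behaviour:", "  per_round_uptake: 0.7",
               "  ever_participation: 0.63"), bad)
  expect_error(read_config(bad), "behaviour.per_round_uptake")
})

test_that("the shipped canonical parameter file loads into a valid model", {
  path <- system.file("extdata", "params_default.yaml", package = "crcaware")
  expect_true(nzchar(path))
  cfg <- read_config(path)
  model <- config_to_model(cfg)
  expect_s3_class(model, "crc_model")
  expect_equal(model$nh$presentation, c(A = 0.04, B = 0.18, C = 0.37, D = 0.74))
  expect_equal(model$econ$screening_costs[["gfobt_positive"]], 11.94)
  camp <- config_to_campaign(cfg)
  expect_equal(camp$secondary_appointments_per_person, 1.52606e-5)
})
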