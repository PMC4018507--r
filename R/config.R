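## Flat YAML configuration binding the pipeline together. The canonical
## file shipped in inst/extdata/params_default.yaml transcribes every model
## parameter at full printed precision; unknown keys are rejected and range
## violations are reported with the offending field named.

#' Default run configuration
#'
#' The complete configuration with every model parameter at its default
#' (published point-estimate) value, fixture settings, and experiment
#' switches. [read_config()] validates user files against this structure.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    population = list(total = 33e6, shape = "england_like"),
    natural_history = list(
      anchor_ages = c(30, 50, 70, 100),
      adenoma_onset = c(0.021, 0.020, 0.045, 0.011),
      lr_to_hr = c(0.009, 0.008, 0.008, 0.004),
      hr_to_crcA = c(0.029, 0.025, 0.054, 0.115),
      normal_to_crcA = 0.00004,
      stage_progression = list(A = 0.51, B = 0.69, C = 0.71),
      presentation = list(A = 0.04, B = 0.18, C = 0.37, D = 0.74),
      proximal_fraction = 0.38,
      adenomas_per_carrier = 1.90,
      advanced_hr_fraction = 0.75),
    tests = list(
      gfobt_sens = list(LR = 0.01, HR = 0.12, CRC = 0.24),
      gfobt_spec_ages = c(50, 70),
      gfobt_spec = c(0.99, 0.97),
      col_sens = list(LR = 0.77, HR = 0.98, CRC = 0.98),
      col_spec = 1.00),
    behaviour = list(
      per_round_uptake = 0.54, ever_participation = 0.63,
      col_followup_compliance = 0.79, col_surveillance_compliance = 0.83,
      repeat_test_rate = 0.07, mean_tests_completed = 1.08),
    adverse_events = list(
      perforation_prob_polypectomy = 0.003,
      perforation_prob_no_polypectomy = 0.0,
      death_given_perforation = 0.052,
      bleed_hospitalisation_prob = 0.003,
      perforation_cost = 5089, bleed_cost = 278),
    economics = list(
      utility_cancer_free = 0.80, utility_crc = 0.70,
      discount_rate = 0.035, wtp_threshold = 20000,
      treatment_cost_min = list(A = 1320, B = 1479, C = 1493, D = 772),
      treatment_cost_max = list(A = 8375, B = 8362, C = 13862, D = 11198),
      treatment_cost_age_direction = "max_at_youngest",
      screening_costs = list(gfobt_noncomplier = 2.03, gfobt_normal = 3.36,
                             gfobt_positive = 11.94, colonoscopy = 563,
                             pathology = 26)),
    campaign = list(
      stage_multipliers = list(A = 0.10, B = 0.10, C = 0.10, D = 0.10),
      duration_months = 1,
      campaign_cost_per_person = 0.14,
      gp_attendances_per_person = 0.0014,
      secondary_appointments_per_person = 1.52606e-5,
      gp_visit_cost = 36, secondary_visit_cost = 200,
      proportion_additional = 0.5,
      population = NULL),
    screening = list(enabled = TRUE, start_age = 60, end_age = 69,
                     interval_years = 2, surveillance_interval_years = 3),
    model = list(max_age = 100, half_cycle_correction = FALSE,
                 survival_preset = "default",
                 stage_distribution = list(A = 0.11, B = 0.25,
                                           C = 0.36, D = 0.29)),
    experiments = list(
      run = "base_case",
      grid_durations = c(1, 3, 6),
      grid_magnitudes = c(0.05, 0.10, 0.20),
      stage_restricted = FALSE,
      psa_samples = 1000, psa_rel_se = 0.1),
    pilot = list(n_months = 24, baseline_mean = 300, step_month_index = 14,
                 step_multiplier = 1.10, n_regions = 2, test_month = 14))
}

## Recursively reject keys absent from the reference structure and fill
## missing keys with defaults.
.merge_config <- function(user, ref, path = "") {
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown))
    stop("unknown configuration key: ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  out <- ref
  for (nm in names(user)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      out[[nm]] <- .merge_config(user[[nm]], ref[[nm]],
                                 paste0(path, ".", nm))
    else out[nm] <- user[nm]
  }
  out
}

.check_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid configuration field '%s': %s", field, msg),
                  call. = FALSE)
}

#' Validate a configuration
#'
#' Checks field ranges and cross-field invariants; errors name the
#' offending field.
#'
#' @param config Nested list as returned by [read_config()] or
#'   [default_config()].
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  cf <- config
  .check_field(cf$population$total > 0, "population.total", "must be > 0")
  .check_field(cf$campaign$duration_months >= 0 &&
                 cf$campaign$duration_months <= 12,
               "campaign.duration_months", "must lie in [0, 12]")
  .check_field(all(unlist(cf$campaign$stage_multipliers) >= 0),
               "campaign.stage_multipliers", "must be >= 0")
  .check_field(cf$campaign$proportion_additional >= 0 &&
                 cf$campaign$proportion_additional <= 1,
               "campaign.proportion_additional", "must lie in [0, 1]")
  .check_field(cf$economics$discount_rate >= 0,
               "economics.discount_rate", "must be >= 0")
  .check_field(cf$economics$utility_crc < cf$economics$utility_cancer_free,
               "economics.utility_crc", "must be below utility_cancer_free")
  .check_field(abs(sum(unlist(cf$model$stage_distribution)) - 1) <= 0.015,
               "model.stage_distribution",
               "must sum to 1 (within printed rounding)")
  .check_field(cf$model$max_age <= 100, "model.max_age",
               "must not exceed 100")
  .check_field(cf$behaviour$per_round_uptake <=
                 cf$behaviour$ever_participation,
               "behaviour.per_round_uptake",
               "cannot exceed ever_participation")
  .check_field(cf$pilot$baseline_mean > 0, "pilot.baseline_mean",
               "must be > 0")
  .check_field(cf$pilot$step_month_index >= 1 &&
                 cf$pilot$step_month_index <= cf$pilot$n_months,
               "pilot.step_month_index", "must lie within 1..n_months")
  invisible(config)
}

#' Read (and validate) a configuration file
#'
#' YAML key-value file; keys not present in [default_config()] are
#' rejected, missing keys take their defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return Validated nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  config <- .merge_config(user, default_config())
  validate_config(config)
  config
}

#' Write a configuration file
#'
#' @param config Nested configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param config Validated configuration list.
#' @return `config_to_model` returns a [crc_model()];
#'   `config_to_campaign` a [campaign_scenario()].
#' @export
config_to_model <- function(config) {
  cf <- validate_config(config)
  nhc <- cf$natural_history
  nh <- natural_history_params(
    adenoma_onset = age_curve(nhc$anchor_ages, nhc$adenoma_onset),
    lr_to_hr = age_curve(nhc$anchor_ages, nhc$lr_to_hr),
    hr_to_crcA = age_curve(nhc$anchor_ages, nhc$hr_to_crcA),
    normal_to_crcA = nhc$normal_to_crcA,
    stage_progression = unlist(nhc$stage_progression),
    presentation = unlist(nhc$presentation),
    proximal_fraction = nhc$proximal_fraction,
    adenomas_per_carrier = nhc$adenomas_per_carrier,
    advanced_hr_fraction = nhc$advanced_hr_fraction)
  tc <- cf$tests
  tests <- test_characteristics(
    gfobt_sens = unlist(tc$gfobt_sens),
    gfobt_spec = age_curve(tc$gfobt_spec_ages, tc$gfobt_spec),
    col_sens = unlist(tc$col_sens), col_spec = tc$col_spec)
  bh <- cf$behaviour
  behaviour <- screening_behaviour(bh$per_round_uptake, bh$ever_participation,
                                   bh$col_followup_compliance,
                                   bh$col_surveillance_compliance,
                                   bh$repeat_test_rate,
                                   bh$mean_tests_completed)
  av <- cf$adverse_events
  ae <- adverse_event_params(av$perforation_prob_polypectomy,
                             av$perforation_prob_no_polypectomy,
                             av$death_given_perforation,
                             av$bleed_hospitalisation_prob,
                             av$perforation_cost, av$bleed_cost)
  ec <- cf$economics
  econ <- economic_params(
    utility_cancer_free = ec$utility_cancer_free,
    utility_crc = ec$utility_crc,
    discount_rate = ec$discount_rate, wtp_threshold = ec$wtp_threshold,
    treatment_cost_ranges = cbind(min = unlist(ec$treatment_cost_min),
                                  max = unlist(ec$treatment_cost_max)),
    treatment_cost_age_direction = ec$treatment_cost_age_direction,
    screening_costs = unlist(ec$screening_costs))
  crc_model(nh = nh, tests = tests, behaviour = behaviour, ae = ae,
            econ = econ,
            demography = make_demography_fixture(cf$population$total,
                                                 cf$population$shape),
            survival = make_survival_fixture(cf$model$survival_preset),
            screening = cf$screening,
            max_age = cf$model$max_age,
            stage_distribution = unlist(cf$model$stage_distribution),
            half_cycle_correction = cf$model$half_cycle_correction,
            campaign_population = cf$campaign$population)
}

#' @rdname config_to_model
#' @export
config_to_campaign <- function(config) {
  cc <- validate_config(config)$campaign
  campaign_scenario(stage_multipliers = unlist(cc$stage_multipliers),
                    duration_months = cc$duration_months,
                    campaign_cost_per_person = cc$campaign_cost_per_person,
                    gp_attendances_per_person = cc$gp_attendances_per_person,
                    secondary_appointments_per_person =
                      cc$secondary_appointments_per_person,
                    gp_visit_cost = cc$gp_visit_cost,
                    secondary_visit_cost = cc$secondary_visit_cost,
                    proportion_additional = cc$proportion_additional)
}
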