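## Parameter bundles for the natural-history, screening and economic model.
## All default values are the published point estimates for the England
## bowel-cancer screening setting; each constructor validates its invariants.

DUKES_STAGES <- c("A", "B", "C", "D")

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}

#' Natural-history parameters of the adenoma-carcinoma model
#'
#' Annual transition probabilities governing disease progression: adenoma
#' onset, low- to high-risk adenoma progression and high-risk adenoma to
#' Dukes' A cancer (all age-dependent, anchored at ages 30/50/70/100), the
#' rare direct normal-epithelium to Dukes' A route, preclinical stage
#' progression, and stage-specific symptomatic/chance presentation.
#'
#' @param adenoma_onset,lr_to_hr,hr_to_crcA [age_curve()] objects for the
#'   age-dependent transitions.
#' @param normal_to_crcA Annual probability of the direct normal to Dukes' A
#'   transition.
#' @param stage_progression Named numeric, annual preclinical progression
#'   probabilities `A` (A to B), `B` (B to C), `C` (C to D).
#' @param presentation Named numeric over Dukes' stages, annual probability
#'   of symptomatic (or chance) presentation while in preclinical stage.
#' @param proximal_fraction Proportion of incidence classified proximal
#'   (descriptive only; carried but not used by the engine).
#' @param adenomas_per_carrier Mean adenomas per carrier (descriptive).
#' @param advanced_hr_fraction Proportion of advanced adenomas that are
#'   high-risk (descriptive).
#' @return Object of class `natural_history_params`.
#' @export
natural_history_params <- function(
    adenoma_onset = age_curve(c(30, 50, 70, 100), c(0.021, 0.020, 0.045, 0.011)),
    lr_to_hr = age_curve(c(30, 50, 70, 100), c(0.009, 0.008, 0.008, 0.004)),
    hr_to_crcA = age_curve(c(30, 50, 70, 100), c(0.029, 0.025, 0.054, 0.115)),
    normal_to_crcA = 0.00004,
    stage_progression = c(A = 0.51, B = 0.69, C = 0.71),
    presentation = c(A = 0.04, B = 0.18, C = 0.37, D = 0.74),
    proximal_fraction = 0.38,
    adenomas_per_carrier = 1.90,
    advanced_hr_fraction = 0.75) {
  stopifnot(inherits(adenoma_onset, "age_curve"), inherits(lr_to_hr, "age_curve"),
            inherits(hr_to_crcA, "age_curve"))
  .check_prob(normal_to_crcA, "normal_to_crcA")
  stage_progression <- stage_progression[c("A", "B", "C")]
  presentation <- presentation[DUKES_STAGES]
  .check_prob(stage_progression, "stage_progression")
  .check_prob(presentation, "presentation")
  .check_prob(proximal_fraction, "proximal_fraction")
  .check_prob(advanced_hr_fraction, "advanced_hr_fraction")
  if (is.unsorted(presentation, strictly = TRUE))
    stop("presentation probabilities must be strictly increasing in stage")
  structure(list(adenoma_onset = adenoma_onset, lr_to_hr = lr_to_hr,
                 hr_to_crcA = hr_to_crcA, normal_to_crcA = normal_to_crcA,
                 stage_progression = stage_progression,
                 presentation = presentation,
                 proximal_fraction = proximal_fraction,
                 adenomas_per_carrier = adenomas_per_carrier,
                 advanced_hr_fraction = advanced_hr_fraction),
            class = "natural_history_params")
}

#' Screening test characteristics
#'
#' Sensitivity of the guaiac faecal occult blood test (gFOBT) by lesion type,
#' its age-dependent specificity (anchored at ages 50 and 70, held flat
#' outside), and colonoscopy sensitivity/specificity.
#'
#' @param gfobt_sens Named numeric: `LR`, `HR`, `CRC` sensitivities.
#' @param gfobt_spec [age_curve()] of specificity (anchors at 50 and 70).
#' @param col_sens Named numeric: colonoscopy sensitivities `LR`, `HR`, `CRC`.
#' @param col_spec Colonoscopy specificity.
#' @return Object of class `test_characteristics`.
#' @export
test_characteristics <- function(
    gfobt_sens = c(LR = 0.01, HR = 0.12, CRC = 0.24),
    gfobt_spec = age_curve(c(50, 70), c(0.99, 0.97)),
    col_sens = c(LR = 0.77, HR = 0.98, CRC = 0.98),
    col_spec = 1.00) {
  gfobt_sens <- gfobt_sens[c("LR", "HR", "CRC")]
  col_sens <- col_sens[c("LR", "HR", "CRC")]
  .check_prob(gfobt_sens, "gfobt_sens"); .check_prob(col_sens, "col_sens")
  .check_prob(col_spec, "col_spec")
  stopifnot(inherits(gfobt_spec, "age_curve"))
  structure(list(gfobt_sens = gfobt_sens, gfobt_spec = gfobt_spec,
                 col_sens = col_sens, col_spec = col_spec),
            class = "test_characteristics")
}

#' Screening participation behaviour
#'
#' Splits the population into never-participants and ever-participants.
#' `conditional_uptake`, the per-round uptake among ever-participants, is
#' derived as `per_round_uptake / ever_participation`.
#'
#' @param per_round_uptake Population probability of completing any given
#'   screening round.
#' @param ever_participation Proportion completing at least one round.
#' @param col_followup_compliance Compliance with follow-up colonoscopy
#'   after a positive gFOBT.
#' @param col_surveillance_compliance Compliance with surveillance
#'   colonoscopy.
#' @param repeat_test_rate Proportion of screens needing a repeat kit
#'   (cost only).
#' @param mean_tests_completed Mean kits used per completed screen
#'   (cost only).
#' @return Object of class `screening_behaviour` with the derived
#'   `conditional_uptake` element.
#' @export
screening_behaviour <- function(per_round_uptake = 0.54,
                                ever_participation = 0.63,
                                col_followup_compliance = 0.79,
                                col_surveillance_compliance = 0.83,
                                repeat_test_rate = 0.07,
                                mean_tests_completed = 1.08) {
  .check_prob(per_round_uptake, "per_round_uptake")
  .check_prob(ever_participation, "ever_participation")
  .check_prob(col_followup_compliance, "col_followup_compliance")
  .check_prob(col_surveillance_compliance, "col_surveillance_compliance")
  .check_prob(repeat_test_rate, "repeat_test_rate")
  cond <- derive_conditional_participation(per_round_uptake, ever_participation)
  structure(list(per_round_uptake = per_round_uptake,
                 ever_participation = ever_participation,
                 conditional_uptake = cond,
                 col_followup_compliance = col_followup_compliance,
                 col_surveillance_compliance = col_surveillance_compliance,
                 repeat_test_rate = repeat_test_rate,
                 mean_tests_completed = mean_tests_completed),
            class = "screening_behaviour")
}

#' Colonoscopy adverse-event parameters
#'
#' Perforation risk applies only when polypectomy is performed; bleeding
#' hospitalisation risk applies to every colonoscopy.
#'
#' @param perforation_prob_polypectomy,perforation_prob_no_polypectomy
#'   Perforation probabilities with/without polypectomy.
#' @param death_given_perforation Case fatality of perforation.
#' @param bleed_hospitalisation_prob Probability of hospitalisation for
#'   bleeding per colonoscopy.
#' @param perforation_cost,bleed_cost Unit costs in GBP.
#' @return Object of class `adverse_event_params`.
#' @export
adverse_event_params <- function(perforation_prob_polypectomy = 0.003,
                                 perforation_prob_no_polypectomy = 0.0,
                                 death_given_perforation = 0.052,
                                 bleed_hospitalisation_prob = 0.003,
                                 perforation_cost = 5089,
                                 bleed_cost = 278) {
  .check_prob(perforation_prob_polypectomy, "perforation_prob_polypectomy")
  .check_prob(perforation_prob_no_polypectomy, "perforation_prob_no_polypectomy")
  .check_prob(death_given_perforation, "death_given_perforation")
  .check_prob(bleed_hospitalisation_prob, "bleed_hospitalisation_prob")
  if (perforation_cost < 0 || bleed_cost < 0) stop("adverse-event costs must be >= 0")
  structure(list(perforation_prob_polypectomy = perforation_prob_polypectomy,
                 perforation_prob_no_polypectomy = perforation_prob_no_polypectomy,
                 death_given_perforation = death_given_perforation,
                 bleed_hospitalisation_prob = bleed_hospitalisation_prob,
                 perforation_cost = perforation_cost, bleed_cost = bleed_cost),
            class = "adverse_event_params")
}

#' Economic parameters: utilities, discounting and unit costs
#'
#' @param utility_cancer_free,utility_crc Health-state utilities; the cancer
#'   utility applies to diagnosed (clinical) disease, all other alive states
#'   use the cancer-free utility.
#' @param discount_rate Annual discount rate for costs and QALYs.
#' @param wtp_threshold Willingness-to-pay threshold, GBP per QALY.
#' @param treatment_cost_ranges 4x2 matrix (rows Dukes' A-D, columns
#'   `min`, `max`) of lifetime treatment costs; ranges reflect variation with
#'   age at diagnosis.
#' @param treatment_cost_age_direction `"max_at_youngest"` (default) maps the
#'   range maximum to the youngest diagnosis age, `"min_at_youngest"`
#'   reverses it.
#' @param screening_costs Named numeric of unit costs: `gfobt_noncomplier`,
#'   `gfobt_normal`, `gfobt_positive`, `colonoscopy`, `pathology`.
#' @return Object of class `economic_params`.
#' @export
economic_params <- function(
    utility_cancer_free = 0.80,
    utility_crc = 0.70,
    discount_rate = 0.035,
    wtp_threshold = 20000,
    treatment_cost_ranges = matrix(
      c(1320, 8375, 1479, 8362, 1493, 13862, 772, 11198),
      nrow = 4, byrow = TRUE,
      dimnames = list(DUKES_STAGES, c("min", "max"))),
    treatment_cost_age_direction = c("max_at_youngest", "min_at_youngest"),
    screening_costs = c(gfobt_noncomplier = 2.03, gfobt_normal = 3.36,
                        gfobt_positive = 11.94, colonoscopy = 563,
                        pathology = 26)) {
  .check_prob(utility_cancer_free, "utility_cancer_free")
  .check_prob(utility_crc, "utility_crc")
  if (utility_crc >= utility_cancer_free)
    stop("utility_crc must be below utility_cancer_free")
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  stopifnot(is.matrix(treatment_cost_ranges),
            nrow(treatment_cost_ranges) == 4, ncol(treatment_cost_ranges) == 2)
  if (any(treatment_cost_ranges[, 1] > treatment_cost_ranges[, 2]))
    stop("treatment cost range min must not exceed max")
  needed <- c("gfobt_noncomplier", "gfobt_normal", "gfobt_positive",
              "colonoscopy", "pathology")
  if (!all(needed %in% names(screening_costs)))
    stop("screening_costs must name: ", paste(needed, collapse = ", "))
  structure(list(utility_cancer_free = utility_cancer_free,
                 utility_crc = utility_crc,
                 discount_rate = discount_rate,
                 wtp_threshold = wtp_threshold,
                 treatment_cost_ranges = treatment_cost_ranges,
                 treatment_cost_age_direction = match.arg(treatment_cost_age_direction),
                 screening_costs = screening_costs[needed]),
            class = "economic_params")
}

#' Awareness-campaign scenario
#'
#' Defines the intervention handed to the cohort engine: per-stage fractional
#' increases in the symptomatic presentation rate, the number of months the
#' increase lasts, and the campaign's direct cost components.
#'
#' @param stage_multipliers Named numeric over Dukes' stages: fractional
#'   increase in the presentation hazard (base case 0.10 for all stages).
#' @param duration_months Months the increase lasts within the first model
#'   year (0 allowed as a null scenario; at most 12).
#' @param campaign_cost_per_person Delivery cost, GBP per person aged 30+.
#' @param gp_attendances_per_person Additional GP attendances per person.
#' @param secondary_appointments_per_person Additional secondary-care
#'   appointments per person.
#' @param gp_visit_cost,secondary_visit_cost Unit costs in GBP.
#' @param proportion_additional Proportion of the extra visits that are
#'   genuinely additional (the remainder are visits merely brought forward,
#'   assumed cost-neutral).
#' @return Object of class `campaign_scenario`.
#' @export
campaign_scenario <- function(stage_multipliers = c(A = 0.10, B = 0.10,
                                                    C = 0.10, D = 0.10),
                              duration_months = 1,
                              campaign_cost_per_person = 0.14,
                              gp_attendances_per_person = 0.0014,
                              secondary_appointments_per_person = 1.52606e-5,
                              gp_visit_cost = 36,
                              secondary_visit_cost = 200,
                              proportion_additional = 0.5) {
  if (length(stage_multipliers) == 1L)
    stage_multipliers <- stats::setNames(rep(stage_multipliers, 4), DUKES_STAGES)
  stage_multipliers <- stage_multipliers[DUKES_STAGES]
  if (any(!is.finite(stage_multipliers)) || any(stage_multipliers < 0))
    stop("stage_multipliers must be >= 0")
  if (duration_months < 0 || duration_months > 12)
    stop("duration_months must lie in [0, 12]")
  .check_prob(proportion_additional, "proportion_additional")
  structure(list(stage_multipliers = stage_multipliers,
                 duration_months = duration_months,
                 campaign_cost_per_person = campaign_cost_per_person,
                 gp_attendances_per_person = gp_attendances_per_person,
                 secondary_appointments_per_person = secondary_appointments_per_person,
                 gp_visit_cost = gp_visit_cost,
                 secondary_visit_cost = secondary_visit_cost,
                 proportion_additional = proportion_additional),
            class = "campaign_scenario")
}

#' Per-round screening uptake among ever-participants
#'
#' The published participation figures give the unconditional per-round
#' uptake and the proportion ever participating; the per-round uptake within
#' the ever-participant group is their ratio.
#'
#' @param per_round Unconditional per-round uptake probability.
#' @param ever Proportion ever participating (must be positive and at least
#'   `per_round`).
#' @return `per_round / ever`.
#' @examples
#' derive_conditional_participation(0.54, 0.63) # ~0.857
#' @export
derive_conditional_participation <- function(per_round, ever) {
  .check_prob(per_round, "per_round"); .check_prob(ever, "ever")
  if (ever == 0) stop("ever participation must be > 0")
  out <- per_round / ever
  if (out > 1 + 1e-12)
    stop("inconsistent participation: per-round uptake exceeds ever participation")
  min(out, 1)
}

#' Stage-restricted presentation multiplier with matched incidence increase
#'
#' If a campaign raises presentation only for a subset of Dukes' stages, the
#' uniform increase on those stages that produces the same all-stage rise in
#' incidence is the all-stage increase divided by the restricted stages'
#' combined share of incidence.
#'
#' @param all_stage_increase Fractional all-stage incidence increase.
#' @param stage_distribution Named numeric over Dukes' stages summing to 1.
#' @param restricted_stages Character subset of `c("A","B","C","D")`.
#' @return The equivalent restricted-stage multiplier.
#' @examples
#' equivalent_stage_restricted_multiplier(
#'   0.10, c(A = 0.11, B = 0.25, C = 0.36, D = 0.29), c("C", "D"))
#' @export
equivalent_stage_restricted_multiplier <- function(all_stage_increase,
                                                   stage_distribution,
                                                   restricted_stages) {
  stage_distribution <- stage_distribution[DUKES_STAGES]
  # published shares are printed to 2 dp and may sum to 1.01; allow that
  if (abs(sum(stage_distribution) - 1) > 0.015)
    stop("stage_distribution must sum to 1 (within printed rounding)")
  restricted_stages <- match.arg(restricted_stages, DUKES_STAGES,
                                 several.ok = TRUE)
  share <- sum(stage_distribution[restricted_stages])
  if (share <= 0) stop("restricted stages carry zero incidence share")
  all_stage_increase / share
}

#' Direct campaign attendance cost per person
#'
#' Expected cost of the additional GP and secondary-care attendances the
#' campaign generates, per person covered. Only the `proportion_additional`
#' share of visits is costed; the rest are visits merely brought forward.
#'
#' @param scenario A [campaign_scenario()].
#' @return Cost in GBP per person.
#' @examples
#' campaign_unit_cost_per_person(campaign_scenario()) # 0.02673
#' @export
campaign_unit_cost_per_person <- function(scenario) {
  stopifnot(inherits(scenario, "campaign_scenario"))
  scenario$proportion_additional *
    (scenario$gp_attendances_per_person * scenario$gp_visit_cost +
     scenario$secondary_appointments_per_person * scenario$secondary_visit_cost)
}

#' @export
print.campaign_scenario <- function(x, ...) {
  cat("Awareness-campaign scenario\n")
  cat("  presentation increase:",
      paste(sprintf("%s %.0f%%", DUKES_STAGES, 100 * x$stage_multipliers),
            collapse = ", "), "\n")
  cat("  duration:", x$duration_months, "month(s)\n")
  cat(sprintf("  delivery cost/person: £%.2f; attendance cost/person: £%.5f\n",
              x$campaign_cost_per_person, campaign_unit_cost_per_person(x)))
  invisible(x)
}
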