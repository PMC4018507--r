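## Biennial gFOBT screening overlay: invitation, test result, follow-up
## colonoscopy, polypectomy, screen detection, and surveillance colonoscopy
## for people with a removed high-risk adenoma. Works on expected-count
## occupancy slices (rows = sub-cohorts, columns = the 14 states).

## gFOBT positivity probability by undiagnosed state at a given age.
.gfobt_positive_probs <- function(tests, age) {
  spec_age <- interpolate_age_curve(tests$gfobt_spec, age, rule = "clamp")
  c(1 - spec_age,                       # clear: false positive
    tests$gfobt_sens[["LR"]],
    tests$gfobt_sens[["HR"]],
    rep(tests$gfobt_sens[["CRC"]], 4))  # preclinical A-D
}

## Screen one behaviour group. X: matrix rows x 14 states. Returns updated
## occupancy, per-row mass of detected HR-adenoma carriers (destined for the
## surveillance group, already removed from X), and per-row event counts.
.screen_group <- function(X, uptake, tests, behaviour, age) {
  eligible <- X[, STATES_UNDIAGNOSED, drop = FALSE]
  screened <- uptake * eligible
  p_pos <- .gfobt_positive_probs(tests, age)
  pos <- sweep(screened, 2, p_pos, "*")
  attend <- behaviour$col_followup_compliance * pos
  det_lr <- attend[, 2L] * tests$col_sens[["LR"]]
  det_hr <- attend[, 3L] * tests$col_sens[["HR"]]
  det_pre <- attend[, 4:7, drop = FALSE] * tests$col_sens[["CRC"]]

  X[, .S$clear] <- X[, .S$clear] + det_lr
  X[, .S$lr_adenoma] <- X[, .S$lr_adenoma] - det_lr
  X[, .S$hr_adenoma] <- X[, .S$hr_adenoma] - det_hr
  X[, STATES_PRECLINICAL] <- X[, STATES_PRECLINICAL, drop = FALSE] - det_pre
  X[, STATES_CLINICAL] <- X[, STATES_CLINICAL, drop = FALSE] + det_pre

  elig_mass <- rowSums(eligible)
  completed <- rowSums(screened)
  positive <- rowSums(pos)
  ev <- cbind(invitations = elig_mass,
              gfobt_noncompliant = elig_mass - completed,
              gfobt_normal = completed - positive,
              gfobt_positive = positive,
              colonoscopies = rowSums(attend),
              polypectomies = det_lr + det_hr,
              scr_dx_A = det_pre[, 1L], scr_dx_B = det_pre[, 2L],
              scr_dx_C = det_pre[, 3L], scr_dx_D = det_pre[, 4L])
  list(occ = X, to_surveillance = det_hr, events = ev)
}

## Surveillance colonoscopy at annual probability `rate` (compliance spread
## over the surveillance interval); no gFOBT stage, lesions detected with
## colonoscopy sensitivity directly.
.surveillance_group <- function(X, rate, tests) {
  attend <- rate * X[, STATES_UNDIAGNOSED, drop = FALSE]
  det_lr <- attend[, 2L] * tests$col_sens[["LR"]]
  det_hr <- attend[, 3L] * tests$col_sens[["HR"]]
  det_pre <- attend[, 4:7, drop = FALSE] * tests$col_sens[["CRC"]]
  X[, .S$clear] <- X[, .S$clear] + det_lr + det_hr
  X[, .S$lr_adenoma] <- X[, .S$lr_adenoma] - det_lr
  X[, .S$hr_adenoma] <- X[, .S$hr_adenoma] - det_hr
  X[, STATES_PRECLINICAL] <- X[, STATES_PRECLINICAL, drop = FALSE] - det_pre
  X[, STATES_CLINICAL] <- X[, STATES_CLINICAL, drop = FALSE] + det_pre
  ev <- cbind(surveillance_colonoscopies = rowSums(attend),
              polypectomies = det_lr + det_hr,
              scr_dx_A = det_pre[, 1L], scr_dx_B = det_pre[, 2L],
              scr_dx_C = det_pre[, 3L], scr_dx_D = det_pre[, 4L])
  list(occ = X, events = ev)
}

#' Apply one gFOBT screening round to an occupancy slice
#'
#' Splits the slice into never-participants (`1 - ever_participation`) and
#' ever-participants, screens the latter with probability
#' `conditional_uptake`, generates true and false positives from the
#' stage-specific gFOBT sensitivities and the age-interpolated specificity,
#' sends positives to colonoscopy with the follow-up compliance, removes
#' detected adenomas (low-risk carriers return to clear epithelium; detected
#' high-risk carriers additionally enter surveillance) and converts detected
#' preclinical cancers to screen-detected clinical cancers of the same
#' stage.
#'
#' @param occupancy Named numeric vector over the 14 states (expected
#'   persons), or a matrix with 14 columns.
#' @param tests A [test_characteristics()] object.
#' @param behaviour A [screening_behaviour()] object.
#' @param age Age of the screened cohort in years.
#' @return A list: `occupancy` (updated, detected HR carriers back in the
#'   clear state), `events` (named numeric of expected event counts) and
#'   `surveillance_entries` (mass entering colonoscopic surveillance).
#' @export
apply_screening_round <- function(occupancy, tests, behaviour, age) {
  vec <- is.null(dim(occupancy))
  X <- if (vec) matrix(occupancy, nrow = 1) else as.matrix(occupancy)
  if (ncol(X) != length(CRC_STATES))
    stop("occupancy must have one entry per health state")
  if (any(X < 0)) stop("occupancy must be non-negative")
  never <- (1 - behaviour$ever_participation) * X
  ever <- behaviour$ever_participation * X
  res <- .screen_group(ever, behaviour$conditional_uptake, tests, behaviour, age)
  out <- never + res$occ
  out[, .S$clear] <- out[, .S$clear] + res$to_surveillance
  ev <- colSums(res$events)
  ev["invitations"] <- ev["invitations"] + sum(never[, STATES_UNDIAGNOSED])
  ev["gfobt_noncompliant"] <- ev["gfobt_noncompliant"] +
    sum(never[, STATES_UNDIAGNOSED])
  if (vec) out <- stats::setNames(drop(out), CRC_STATES)
  list(occupancy = out, events = ev,
       surveillance_entries = sum(res$to_surveillance))
}

#' Expected colonoscopy adverse events and their cost
#'
#' Perforation risk applies to colonoscopies with polypectomy (and at the
#' separate, by default zero, rate without); hospitalisation for bleeding
#' applies to every colonoscopy.
#'
#' @param n_colonoscopies,n_polypectomies Expected procedure counts
#'   (`n_polypectomies <= n_colonoscopies`).
#' @param ae An [adverse_event_params()] object.
#' @return List with `perforations`, `perforation_deaths`, `bleeds`,
#'   `total_cost` (GBP).
#' @examples
#' colonoscopy_adverse_events(17519, 0, adverse_event_params())
#' @export
colonoscopy_adverse_events <- function(n_colonoscopies, n_polypectomies, ae) {
  stopifnot(inherits(ae, "adverse_event_params"))
  if (n_colonoscopies < 0 || n_polypectomies < 0)
    stop("procedure counts must be >= 0")
  if (n_polypectomies > n_colonoscopies)
    stop("n_polypectomies cannot exceed n_colonoscopies")
  perforations <- n_polypectomies * ae$perforation_prob_polypectomy +
    (n_colonoscopies - n_polypectomies) * ae$perforation_prob_no_polypectomy
  bleeds <- n_colonoscopies * ae$bleed_hospitalisation_prob
  list(perforations = perforations,
       perforation_deaths = perforations * ae$death_given_perforation,
       bleeds = bleeds,
       total_cost = perforations * ae$perforation_cost + bleeds * ae$bleed_cost)
}
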