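## One-cycle transition matrices. Competing transitions out of a state are
## composed additively on the hazard (log-survival) scale and the total exit
## probability is split proportionally to the component hazards, so the
## result is order-independent and rows sum to 1 exactly.

#' Campaign-adjusted annual presentation probability
#'
#' Converts the annual symptomatic-presentation probability to a constant
#' hazard \eqn{r = -\log(1-p)}, scales the hazard by \eqn{(1+m)} for
#' `duration_months` of the 12, and converts back:
#' \deqn{p' = 1 - \exp\{-r\,(12 - d + d(1+m))/12\}.}
#' For small \eqn{p} the first-year excess incidence is approximately
#' \eqn{m\,d/12}.
#'
#' @param p_annual Annual presentation probability, in `[0, 1)`.
#' @param multiplier Fractional hazard increase \eqn{m \ge 0}.
#' @param duration_months Months the increase lasts, in `[0, 12]`.
#' @return Adjusted annual probability.
#' @examples
#' campaign_adjusted_presentation(0.74, 0.10, 1)   # 0.7429
#' campaign_adjusted_presentation(0.37, 0.10, 12)  # 1 - 0.63^1.1
#' @export
campaign_adjusted_presentation <- function(p_annual, multiplier, duration_months) {
  if (any(p_annual < 0) || any(p_annual >= 1))
    stop("p_annual must lie in [0, 1): probability 1 has infinite hazard")
  if (any(multiplier < 0)) stop("multiplier must be >= 0")
  if (any(duration_months < 0) || any(duration_months > 12))
    stop("duration_months must lie in [0, 12]")
  r <- -log1p(-p_annual)
  -expm1(-r * (12 - duration_months + duration_months * (1 + multiplier)) / 12)
}

## Fill one row of a transition matrix from competing annual probabilities.
## ps: named-by-index destination probabilities (marginal annual risks).
.compose_row <- function(n, from, to, ps) {
  row <- numeric(n)
  keep <- ps > 0
  to <- to[keep]; ps <- ps[keep]
  if (length(ps)) {
    if (any(ps >= 1)) stop("competing transition probability >= 1 in row ",
                           CRC_STATES[from])
    h <- -log1p(-ps)
    H <- sum(h)
    total <- -expm1(-H)
    row[to] <- total * h / H
  }
  row[from] <- 1 - sum(row)
  row
}

#' Build the one-cycle transition matrix at a given age
#'
#' Assembles the 14x14 annual transition matrix from the age-interpolated
#' adenoma pathway, the direct normal-to-Dukes'-A route, preclinical stage
#' progression, stage-specific symptomatic presentation (optionally
#' campaign-adjusted), other-cause mortality (routing preclinical occupants
#' to the "dead with undiagnosed CRC" state), and stage-specific CRC
#' mortality in the clinical states.
#'
#' @param age Age in years at the start of the cycle.
#' @param nh A [natural_history_params()] object.
#' @param crc_death Named numeric over Dukes' stages: annual CRC-death
#'   probability in the clinical states (see [survival_annual_death_probs()]).
#' @param other_mortality Annual all-cause (non-CRC) death probability at
#'   this age.
#' @param presentation_multiplier Named numeric over stages: fractional
#'   hazard increase applied to presentation (default 0, no campaign).
#' @param duration_months Months the increase applies (default 0).
#' @return A 14x14 row-stochastic matrix with state dimnames.
#' @export
build_transition_matrix <- function(age, nh, crc_death,
                                    other_mortality = 0,
                                    presentation_multiplier = c(A = 0, B = 0,
                                                                C = 0, D = 0),
                                    duration_months = 0) {
  stopifnot(inherits(nh, "natural_history_params"))
  crc_death <- crc_death[DUKES_STAGES]
  presentation_multiplier <- presentation_multiplier[DUKES_STAGES]
  .check_prob(crc_death, "crc_death")
  .check_prob(other_mortality, "other_mortality")
  pres <- campaign_adjusted_presentation(nh$presentation,
                                         presentation_multiplier,
                                         duration_months)
  .build_tm(onset = interpolate_age_curve(nh$adenoma_onset, age),
            lr_hr = interpolate_age_curve(nh$lr_to_hr, age),
            hr_ca = interpolate_age_curve(nh$hr_to_crcA, age),
            normal_ca = nh$normal_to_crcA,
            prog = nh$stage_progression, pres = pres,
            crc_death = crc_death, q = other_mortality)
}

## Low-level assembly from precomputed age-specific values; used by the
## public builder and by the per-age matrix cache in the engine.
.build_tm <- function(onset, lr_hr, hr_ca, normal_ca, prog, pres,
                      crc_death, q) {
  n <- length(CRC_STATES)
  M <- matrix(0, n, n, dimnames = list(CRC_STATES, CRC_STATES))
  M[.S$clear, ] <- .compose_row(n, .S$clear,
    c(.S$lr_adenoma, .S$pre_A, .S$dead_other),
    c(onset, normal_ca, q))
  M[.S$lr_adenoma, ] <- .compose_row(n, .S$lr_adenoma,
    c(.S$hr_adenoma, .S$dead_other), c(lr_hr, q))
  M[.S$hr_adenoma, ] <- .compose_row(n, .S$hr_adenoma,
    c(.S$pre_A, .S$dead_other), c(hr_ca, q))
  for (i in seq_along(DUKES_STAGES)) {
    pre <- STATES_PRECLINICAL[i]; clin <- STATES_CLINICAL[i]
    dest <- c(clin, .S$dead_other_undiag_crc)
    ps <- c(pres[i], q)
    if (i < 4L) { dest <- c(STATES_PRECLINICAL[i + 1L], dest); ps <- c(prog[i], ps) }
    M[pre, ] <- .compose_row(n, pre, dest, ps)
    M[clin, ] <- .compose_row(n, clin, c(.S$dead_crc, .S$dead_other),
                              c(crc_death[i], q))
  }
  for (s in STATES_ABSORBING) M[s, s] <- 1
  if (any(M < 0) || any(M > 1) || any(abs(rowSums(M) - 1) > 1e-12))
    stop("assembled transition matrix is not row-stochastic; ",
         "check parameter consistency")
  M
}
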