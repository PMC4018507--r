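## The campaign's direct (non-treatment) costs and the pilot-to-national
## scaling arithmetic.

#' Direct costs of delivering the awareness campaign
#'
#' Delivery cost plus the expected cost of the additional GP and
#' secondary-care attendances the campaign generates, both incurred in the
#' first model year (discount factor 1).
#'
#' @param scenario A [campaign_scenario()].
#' @param population Persons covered by the campaign (the per-person cost
#'   denominator).
#' @return Object of class `campaign_costs`: `campaign_delivery`,
#'   `gp_and_secondary_attendance` and their sum `total_direct`.
#' @examples
#' campaign_direct_costs(campaign_scenario(), 1e6)
#' @export
campaign_direct_costs <- function(scenario, population) {
  stopifnot(inherits(scenario, "campaign_scenario"))
  if (population <= 0) stop("population must be > 0")
  delivery <- scenario$campaign_cost_per_person * population
  attendance <- campaign_unit_cost_per_person(scenario) * population
  structure(list(campaign_delivery = delivery,
                 gp_and_secondary_attendance = attendance,
                 total_direct = delivery + attendance),
            class = "campaign_costs")
}

#' @export
print.campaign_costs <- function(x, ...) {
  cat(sprintf("campaign direct costs: delivery £%.0f + attendances £%.0f = £%.0f\n",
              x$campaign_delivery, x$gp_and_secondary_attendance,
              x$total_direct))
  invisible(x)
}

#' Scale a pilot-region count to the national level
#'
#' Multiplies a count observed in the pilot regions by a dimensionless
#' scale factor. The base configuration uses a factor of 100, which maps
#' the pilot's 700 additional GP attendances to the 70,000 assumed
#' nationally.
#'
#' @param pilot_count Count observed in the pilot regions.
#' @param scale_factor Positive scaling factor (default 100).
#' @return The nationally scaled count.
#' @examples
#' national_scaling(700, 100) # 70000
#' @export
national_scaling <- function(pilot_count, scale_factor = 100) {
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  if (any(pilot_count < 0)) stop("pilot_count must be >= 0")
  pilot_count * scale_factor
}
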