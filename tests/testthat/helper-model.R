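# Shared fixtures, built in code. A reduced-population model keeps tests
# fast; every result scales linearly with the population total.

small_model <- function(total = 1e5, ...) {
  crc_model(demography = make_demography_fixture(total, "england_like"), ...)
}

# A model with no mortality from any cause (zero-hazard demography and the
# null survival preset): clinical occupancy can only grow, which makes
# diagnosis partition identities exact.
immortal_model <- function(total = 1e4, ...) {
  crc_model(demography = make_demography_fixture(total, "england_like",
                                                 gompertz = c(0, 0)),
            survival = make_survival_fixture("null"), ...)
}

# Sum an event over the whole trace.
event_total <- function(trace, event) sum(trace$events[, , event])

stage_event_totals <- function(trace, prefix) {
  vapply(c("A", "B", "C", "D"),
         function(s) event_total(trace, paste0(prefix, s)), numeric(1))
}

# Cycle-1 totals: each cohort's first model year is the year it enters at
# its own start age.
first_cycle_total <- function(trace, event) {
  sum(vapply(seq_along(trace$start_ages), function(c) {
    ai <- match(trace$start_ages[c], trace$ages)
    trace$events[c, ai, event]
  }, numeric(1)))
}
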