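## The 14-state disease space of the cohort engine.
## Alive states 1-11; the three death states are absorbing. Deaths from
## other causes while carrying undiagnosed CRC are tracked separately so the
## trace can report "deaths with undiagnosed CRC".

CRC_STATES <- c("clear", "lr_adenoma", "hr_adenoma",
                "pre_A", "pre_B", "pre_C", "pre_D",
                "clin_A", "clin_B", "clin_C", "clin_D",
                "dead_crc", "dead_other", "dead_other_undiag_crc")

.S <- as.list(stats::setNames(seq_along(CRC_STATES), CRC_STATES))

STATES_ALIVE <- 1:11
STATES_UNDIAGNOSED <- 1:7       # eligible for screening
STATES_PRECLINICAL <- 4:7
STATES_CLINICAL <- 8:11
STATES_ABSORBING <- 12:14

BEHAVIOUR_GROUPS <- c("never", "ever", "surveillance")

#' Health states of the natural-history model
#'
#' @return Character vector of the 14 state names: clear epithelium, low- and
#'   high-risk adenoma, preclinical (undiagnosed) CRC Dukes' A-D, clinical
#'   (diagnosed) CRC Dukes' A-D, and three absorbing death states (CRC death,
#'   other-cause death, other-cause death with undiagnosed CRC).
#' @export
crc_states <- function() CRC_STATES
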