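---
title: "Modelling the long-term impact of a bowel-cancer awareness campaign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the long-term impact of a bowel-cancer awareness campaign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcaware)
```

## The question

Awareness campaigns for colorectal cancer (CRC) aim to bring people with
symptoms to their GP sooner. The short-term, observable consequence is a
transient bump in symptomatic presentation; the quantities that matter for
policy — cancer deaths averted, quality-adjusted life-years (QALYs) gained,
and cost per QALY — play out over decades and cannot be observed directly.
`crcaware` bridges that gap: it extrapolates a short-term presentation-rate
increase through a state-transition model of CRC natural history and
screening, and evaluates the intervention in the standard health-economic
framework (discounted costs and QALYs, incremental cost-effectiveness ratio
ICER, net monetary benefit NMB at a willingness-to-pay threshold).

## The disease model

The population moves annually between 14 states: clear epithelium,
low-risk and high-risk adenoma, preclinical (undiagnosed) CRC in Dukes'
stages A–D, clinical (diagnosed) CRC in the same stages, and three
absorbing death states (CRC death, other-cause death, and other-cause death
with undiagnosed CRC, tracked separately so "died never knowing" is
reportable).

Annual transition probabilities follow the adenoma–carcinoma sequence:
age-dependent adenoma onset, low-to-high-risk progression and
high-risk-to-cancer transformation (each anchored at ages 30/50/70/100 and
piecewise-linearly interpolated — the simplest scheme exact at every
anchor), a rare direct normal-to-cancer route (4 × 10⁻⁵/year), preclinical
stage progression (A→B 0.51, B→C 0.69, C→D 0.71 per year), and
stage-specific symptomatic/chance presentation (A 0.04, B 0.18, C 0.37,
D 0.74 per year). Presentation moves a person from the preclinical to the
clinical state of the same stage.

**Competing risks within a cycle.** Several transitions compete for the
same occupants (progression, presentation, death). Marginal annual
probabilities are converted to hazards, summed, and the total exit
probability `1 − exp(−ΣH)` is shared in proportion to the component
hazards. This is order-independent and keeps every row of the transition
matrix exactly stochastic. It slightly differs from applying each marginal
probability alone (for the clear-epithelium row at age 30 the off-diagonal
mass is 0.0210392 rather than 0.02104), and it ignores within-year exposure
after a transition — which is why, for example, scenarios that only shuffle
people among alive states agree on life-years to about 10⁻⁷ relative rather
than machine precision.

**Cycle structure.** Cycles are annual, ages capped at 100 (the last
published anchor age). Screening is applied at the start of a cycle,
progression across the remainder. There is no half-cycle correction by
default (a constructor switch enables it); life-years accrue on
start-of-cycle occupancy, so a person alive for exactly one cycle accrues
one (utility-weighted) life-year.

## The screening overlay

The biennial guaiac faecal occult blood (gFOBT) programme invites ages
60–68 by default (configurable). Participation is modelled with two
persistent behaviour groups: never-participants (37% of the population) and
ever-participants, who complete any given round with probability
0.54/0.63 ≈ 0.857. Positives (stage-specific gFOBT sensitivity, specificity
interpolated between ages 50 and 70 and held flat outside) proceed to
colonoscopy with compliance 0.79. Colonoscopy removes detected adenomas
(polypectomy; low-risk carriers return to clear epithelium, detected
high-risk carriers additionally enter a third behaviour group under
colonoscopic surveillance) and converts detected preclinical cancers to
screen-detected clinical cancers of the same stage.

Surveillance is specified as colonoscopy every 3 years with compliance
0.83. Rather than carry a time-since-entry state dimension, the package
applies an annual surveillance-colonoscopy probability of 0.83/3 — the
rate-based equivalent of the 3-yearly schedule. Colonoscopy harms
(perforation 0.3% with polypectomy, fatal in 5.2%; bleeding admission 0.3%
of all colonoscopies) are expected counts priced into screening costs;
adverse-event deaths are reported by `colonoscopy_adverse_events()` but not
removed from occupancy, mirroring their treatment as a scenario analysis.

## The campaign intervention

The campaign multiplies the symptomatic-presentation *hazard* by `1 + m`
for `d` of the 12 months of the first model year:

$$p' = 1 - \exp\!\left\{-r\,\frac{12 - d + d(1+m)}{12}\right\},
\qquad r = -\log(1-p).$$

For rare presentation the first-year excess incidence is ≈ `m·d/12`; at the
published Dukes'-D probability (0.74) the exact form matters
(`p' = 0.7429` for a 10% one-month increase). The base case applies the
same multiplier to all four stages, so the stage mix of the short-term
extra incidence matches the standing incidence mix; a stage-restricted
scenario applies the increase to stages C and D only, scaled by their
incidence share (0.10/0.65 ≈ 15.4% for a 10% all-stage rise) so the
all-stage incidence increase is matched. The campaign year is each cohort's
first simulated year; the hazard embedding reproduces a one-month effect
without a monthly engine. We apply the scaled hazard to the whole
campaign-year presentation process (prevalent and incident preclinical
cases alike).

Direct campaign costs are £0.14 per person delivery plus the expected cost
of extra GP attendances (0.0014/person × £36) and secondary-care
appointments (1.52606 × 10⁻⁵/person × £200), of which only the
`proportion_additional` share (default 50%) is costed — the rest are visits
merely brought forward. Both components fall in year 0 and are undiscounted.
The per-person denominators are internally ambiguous in the source material
(0.0014 × 33 M ≈ 46,200 attendances, not the 70,000 the scaling assumption
implies), so the denominator is exposed in configuration rather than
resolved; the default uses the modelled 30+ population.

## Economics

Costs and QALYs are discounted at 3.5%/year, with first-year outcomes at
discount factor 1. Alive years accrue utility 0.80 (cancer-free, including
undiagnosed preclinical disease) or 0.70 (diagnosed CRC, for life
post-diagnosis — the source gives a single CRC utility with no duration
structure). Screening activity is priced per event (kits £2.03/£3.36/£11.94
by outcome, colonoscopy £563, pathology £26 per specimen, adverse events at
their unit costs). Treatment cost is charged once at diagnosis, mapped
linearly over age at diagnosis within the published per-stage ranges. Which
end of each range belongs to which age is unstated in the source; the
default puts the maximum at the youngest age (treatment intensity falls
with age), with a switch to reverse. ICER = ΔC/ΔQ (when ΔQ > 0) and
NMB = λ·ΔQ − ΔC are exact identities of the returned object.

## What the synthetic fixtures stand in for

Three inputs of the original analysis are not published and are replaced by
explicit, versioned fixtures — **they are not registry, life-table or ONS
data**, and headline magnitudes are therefore approximate by design:

* **Demography** (`make_demography_fixture`): 33 million persons aged
  30–100 shaped proportionally to the survival curve of a Gompertz
  mortality schedule (hazard 6 × 10⁻⁴ at age 30, log-slope 0.085/year) — a
  stationary-population approximation with sensible magnitudes (mortality
  ≈ 0.06%/year at 30, ≈ 9% at 90).
* **Stage-specific CRC survival** (`make_survival_fixture`): five annual
  CRC-death probability bands per stage fixing 5-year CRC-specific survival
  at 0.95/0.80/0.55/0.10 for A/B/C/D, with declining within-band hazard
  weights (1.6, 1.3, 1.0, 0.8, 0.6). Because the state space carries no
  time-since-diagnosis dimension, the engine uses each stage's
  constant-hazard equivalent (`1 − (Π(1−p_y))^{1/5}`), which preserves
  5-year survival but, applied for life, overstates very-long-term excess
  mortality; the stage *contrast* that drives the campaign's benefit is
  retained.
* **Pilot incidence series** (`generate_pilot_incidence_series`): seeded
  Poisson monthly counts (default 300/month pooled over two regions across
  24 months) with an optional one-month multiplicative step. Counts of
  incident cases motivate the Poisson choice; no overdispersion is modelled.

The initial population is another unpublished input: the current
population carries prevalent adenomas and preclinical cancers, without
which a one-month campaign would act on nobody. Each baseline cohort aged
*a* receives the alive-state distribution of a disease-free cohort
simulated from age 30 to *a* under status quo screening (a burn-in), so
prevalence is internally consistent with the natural-history parameters.

Consequently, passing tests demonstrate the *mechanics* — conservation,
identities, oracle equivalence, directional and pattern reproduction — not
agreement with registry data. The published headline numbers (66 deaths
prevented, 404 QALYs, ICER £13,496) depend on the unpublished inputs; with
the default fixtures this implementation produces the same signs and
patterns (symptomatic incidence up in stages A–C and down in D, fewer
screen-detected cases, positive QALY gain, near-proportionality of QALY
gain in campaign magnitude) at different magnitudes.

## Sensitivity and uncertainty analysis

`run_sensitivity_grid()` spans durations {1, 3, 6} months × magnitudes
{5, 10, 20}% (all-stage or stage-restricted). Deaths prevented and QALY
gains are monotone along both axes and the ICER falls as the effect grows;
at one month the QALY gain is near-linear in magnitude (20%:5% ratio ≈ 4).

`run_psa()` draws parameter sets — Beta for probabilities and utilities
(order constraints preserved by resampling), Gamma for costs, with standard
error 10% of the mean by default — and reruns the incremental comparison
per draw, reporting 2.5–97.5 percentile intervals. The distribution
families and dispersion are this package's choices (the source defers its
distributions to an external report); both are configurable, and zero
dispersion reproduces the deterministic result exactly. Campaign-effect
parameters are deliberately excluded from the PSA, as in the source, where
they are explored in the scenario grid instead. With 1,000 draws the PSA
runs in about two minutes.

`screening_uptake_equivalence()` answers "what uptake improvement would
match the campaign?": it moves mass from the never- to the ever-participant
group at baseline and solves, by root bisection on the monotone QALY
response, for the relative reduction in the never-participant share whose
QALY gain (with no campaign) equals a target — typically the campaign's own
gain.

## Pilot statistics

`step_change_ttest()` formalises the short-term evaluation: a single
post-campaign month against the preceding baseline months,

$$t = \frac{x_{obs} - \bar{x}}{s\sqrt{1 + 1/n}},$$

two-sided p on n−1 degrees of freedom. The `1 + 1/n` factor is the
prediction variance for a new observation; a plain variant is available.
Sidedness is a package choice (two-sided). Descriptive excesses versus the
same month one year earlier and versus baseline mean + 2 sd are reported
alongside, and `pooled_and_regional_tests()` runs the test per region and
pooled. Simulation (fixed seed) confirms the nominal type-I error at
α = 0.01 within [0.005, 0.02] under a Poisson null, and power rises with
both step size and baseline count — at the default synthetic magnitudes
(10% step on 300/month) a single month frequently fails to reach
significance, the same sensitivity the regional analyses of the pilot
showed.

## Numerical choices and reproducibility

* Probabilities are stored at full published precision; hazard conversions
  use `log1p`/`expm1` for accuracy at small probabilities.
* Transition rows must sum to 1 within 10⁻¹²; assembly fails loudly on any
  inconsistent parameter set.
* Mass is conserved per cohort to 10⁻⁹ relative over the whole horizon.
* All randomness (pilot series, PSA) flows from explicit integer seeds;
  generators save and restore the session RNG state. Identical
  configuration and seed reproduce byte-identical result tables
  (`run_pipeline()` writes a manifest with the config checksum and seed).
* Problem sizes in the shipped tests use reduced populations (10⁴–10⁵
  persons); every cohort-model output scales linearly in the population
  total, so this choice affects runtime only.

## Known limitations

* No emergency-presentation route and no other lower-GI conditions: extra
  colonoscopies from "worried well" presentations carry costs and harms
  but confer no benefit for non-CRC disease in this model.
* Clinical-state mortality has no time-since-diagnosis structure
  (constant-hazard collapse of the survival fixture).
* Surveillance is rate-based rather than scheduled; screening behaviour
  groups are persistent rather than per-round random.
* The campaign's effect on screening uptake is fixed at zero (as observed
  in the pilot), and treatment costs have no phase-of-care structure.
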