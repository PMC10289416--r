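---
title: "A flexible stage distribution model for screening cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A flexible stage distribution model for screening cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexscreen)
```

## The problem

Deciding whether to extend an ongoing mammography screening programme to
new age groups requires weighing the life-years the extension would gain
against its cost. When a programme has run for decades, there is no
recent unscreened population to serve as a counterfactual, so classical
cost-effectiveness models that compare against "no screening" rest on
data that no longer describe the present. This package implements an
alternative: take the *current* policy as the reference, and express an
alternative policy entirely through its effect on two estimable
quantities per 2-year age group — the probability of a breast cancer
diagnosis during the interval (incidence), and the distribution of stage
at diagnosis conditional on being diagnosed. Survival by age and stage,
cause of death, and treatment costs are shared across policies.
Everything downstream (expected life-years, expected costs, expected
breast cancer deaths, ICERs) is then available in closed form, which
makes the model transparent and cheap to evaluate compared with
microsimulation platforms.

## Model structure

A cohort of `N0` (default 100 000) women is followed from the first
possible invitation age in biennial rounds `j = 1..J`; group `j` covers
ages `44 + 2j` to `45 + 2j` (so `j = 1` is ages 46–47) and nobody
survives past age 100. A policy `h` assigns each group `S` (screened) or
`NS`. At round `j` a woman is in state `k = -1` (no breast cancer) or a
diagnosed stage `k = 0..4` (Unknown, Localized, Regional,
Distant/adjacent tissue, In situ). The state distribution factorises as

    mu[j,h](k) = q(j, h(j), k) * iota(j, h(j))   for k >= 0
    mu[j,h](-1) = 1 - iota(j, h(j))

with `iota` the incidence and `q` the conditional stage law — this
factorisation is what lets a scenario change incidence and stage
distribution independently. Stage codes are kept as integers `-1..4`;
the Finnish Cancer Registry does not record TNM, so no TNM mapping is
attempted.

Given state `k` at round `j`, the whole years lived afterwards follow a
discrete law `lam[j,k](t)`, and for diagnosed states the joint law
`pi[j,k](t, d)` also records whether the death was due to breast cancer
(`d = 1`) or another cause (`d = 2`). Women are censored from the cohort
at diagnosis or death, so the screened population evolves as

    N[j+1] = N[j] * (1 - P(T_j <= 1) - P(T_j >= 2, X_j != -1))

where `T_j` is the mixture death-time over states. Expected total
life-years are accounted per round: arrivals at rounds `2..J` are
credited the two years just lived, cancer-free women dying inside the
interval are credited `lam[j,-1](1)` one year (a death in the first year
credits none), and diagnosed women are credited their full expected
remaining years `E T[j,k]` at diagnosis:

    ET_h = sum_{j=2..J} 2*N[j]
         + sum_j ( lam[j,-1](1)*mu[j](-1) + sum_{k>=0} mu[j](k)*E T[j,k] ) * N[j]

Two asymmetries of this accounting are deliberate and reproduced
verbatim rather than "fixed": a cancer-free death at `t = 0` contributes
zero years while `t = 1` contributes one, and survivors of the *final*
round receive no further credit — the accounting stops at the horizon.
The Monte Carlo validator mirrors exactly the same accounting (see
below), so the two sides are comparable; we interpret the closed form's
silence about post-final-round years as "the horizon ends the model"
and apply it consistently everywhere.

Costs have two parts. Screening costs a flat 30 EUR per invitee per
screened round. Treatment costs depend on age band at diagnosis (seven
5-year bands from 46–49 to 75+), stage, years survived and cause of
death, through three phase tables: `C1` (first year), `C2` (per year,
years 2–5), `C3` (last year before a breast cancer death). A death
during year `n` after diagnosis accrues

    other cause:   C1 + (n-1)*C2        (n <= 5),    C1 + 4*C2        (n > 5)
    breast cancer: (n-1)*C1 + C3        (n in 1,2),
                   C1 + (n-2)*C2 + C3   (n in 3..5),  C1 + 4*C2 + C3  (n > 5)

The `n = 2` breast cancer branch has no `C2` term while the other-cause
branch does; the rule is applied exactly as published, not harmonised.
Treatment is counted for at most five years — a conservative choice, as
real treatment and follow-up often last five to ten. A survival time of
`t` whole years maps to the cost index `n = t + 1`: "dies during n years
after diagnosis" is read as an inclusive count of calendar years
entered, which is what makes the `n = 1` branch (cost `C3` alone)
meaningful for deaths soon after diagnosis. Costs are indexed by age at
diagnosis throughout treatment, not attained age. No discounting is
applied to costs or life-years, and no optional discount rate is
offered: the outputs are meant to be directly comparable across the
policies evaluated here, all on the same horizon.

Participation is *not* a separate parameter. Incidence and stage
distributions are interpreted at the invitee (population) level, i.e.
they already average over the roughly constant attendance observed in
the Finnish programme. A policy flip therefore implicitly assumes the
newly invited groups attend like the nearest currently screened groups.

## Scenarios

The three extension scenarios transform a baseline input set:

* **Younger (46–69):** groups 46–47 and 48–49 flip to `S` and inherit
  the conditional stage distributions of the closest screened groups
  under the current policy (46–47 from 50–51; 48–49 and 50–51 from
  52–53). Incidence is adjusted +28% (46–47, a first-screen prevalence
  effect), +24.7% (48–49) and −11.9% (50–51, detections pulled to
  younger ages). The 50–51 substitution is retained in the combined
  scenario as well.
* **Older (50–74):** groups 70–71 and 72–73 flip to `S` and take the
  stage distribution of the oldest screened group (68–69); every group
  above 73 takes the baseline distribution of the group two positions
  (four years) younger, shifting the old-age stage profile outward. We
  read "each older group gets the distribution of the preceding groups"
  as this two-group shift because the first two extension groups
  receive 68–69's profile — a one-group shift would leave a
  discontinuity at 74–75. Old-age incidence under the extension is an
  external configuration vector (a steady-state decline pattern such as
  Sweden's); the package ships only a clearly-labelled synthetic
  stand-in (`synthetic_older_incidence()`), since no machine-readable
  curve is available.
* **Both (46–74):** younger then older. The two touch disjoint age
  ranges, so the order is immaterial; it is fixed (younger first) and
  asserted by test.

Six one-way sensitivity analyses perturb exactly one dimension:
modelled incidence ±10% (the groups each scenario models: ages 46–69,
above 69, or both), all treatment-cost cells +10% or +50% (screening
cost untouched; applied to every policy including the reference), and
±0.02 conditional probability moved between localized and regional
disease for the modelled stage distributions (ages 46–51 and/or above
69).

## Validation by microsimulation

The central correctness argument is an independent individual-level
Monte Carlo simulator that replays the same stochastic process: draw a
state per round, on diagnosis draw `(t, d)` from the joint law and
credit the *drawn* years and the accumulated cost, otherwise draw a
cancer-free survival time and either die within the interval or carry
on. Because the simulator credits realised draws rather than
expectations, its agreement with the closed forms is a genuine check,
not a tautology. The test suite requires the analytic expected
life-years, costs and breast cancer deaths to sit within 3 Monte Carlo
standard errors of 200 000-individual simulations on five random
synthetic fixtures (J between 3 and 6), and to match *exactly* under
point-mass laws, where the walk is deterministic. One RNG stream per
cohort with a documented draw order (states, then diagnosed stages in
ascending order, then cancer-free survival) makes runs reproducible
from the seed.

## The synthetic generator

No registry inputs are distributable, so `generate_inputs()` produces
complete, always-valid parameter sets that emulate the *shape* of the
real ones: incidence rising with age with a first-screen bump at the
youngest screened group (+28% by default, matching the scenario
constant) and a deficit just after screening stops; conditional stage
distributions reallocating a configurable fraction of regional/distant
mass to localized/in-situ under screening; survival built from a
Gompertz-type female background life table plus a stage-graded excess
hazard that decays linearly to zero 18 years after diagnosis (the
follow-up horizon beyond which excess mortality is assumed gone); and a
breast-cancer death share by stage that fades with the same decay, so
late deaths of long-survivors are attributed to other causes. Hazards
are forced to 1 at age 99 so the 100-year horizon holds by
construction.

What the generator does *not* emulate: the actual Finnish (or Swedish)
rates, calendar-time trends, interval-vs-screen-detected cancers,
overdiagnosis dynamics, or any correlation between incidence and
survival beyond the stage channel. Passing tests on generated data
therefore demonstrate the *machinery* — closed forms, scenario algebra,
cost rules, file handling — not the published Finnish results. On the
default synthetic set the screened incidence exceeds the unscreened
rate enough that extensions cost money without gaining life-years
(negative ICERs); the registry-based analysis found modest positive
gains instead, and its own +10% incidence sensitivity produced exactly
the synthetic behaviour. This is the expected consequence of the
generator's detection-boost default, not a defect of the engine.

## Numerical choices

* Probability rows must sum to 1 within `1e-9`; violations are
  *reported, never repaired* — silent renormalisation would mask
  data-entry errors in parameter files. Loading aggregates all
  violations into one failure.
* Survival mass beyond `t_max(j) = 100 - lower_age(j)` is flagged by
  validation, not truncated: parameter files must already respect the
  horizon.
* `N_j` stays real-valued (expected invitees); rounding would break the
  exact linearity of costs in the treatment tables, which the ±10%/+50%
  sensitivity machinery and its tests rely on.
* ICERs divide the cost difference by the life-year difference, both
  taken as alternative − reference; an ICER with a zero life-year difference is reported as
  undefined (`NA`) while the incremental cost is still given.
* Monetary values are never rounded internally; CSV output uses the
  `.` decimal separator regardless of locale.
* Test and validation problem sizes: unit tests run fixtures with
  J ≤ 6 and simulations up to 50 000 individuals; the acceptance-level
  oracle comparison uses five fixtures at 200 000 individuals, enough
  to resolve sub-percent discrepancies while keeping the whole suite
  around ten seconds.

## Limitations

The model observes states only at screening rounds: there is no
continuous age, no interval-cancer distinction, no radiation burden or
overdiagnosis morbidity, no screening-interval changes, and no
risk-stratified subgroups. Costs cover specialised-care treatment only
(no primary care, travel, or productivity losses) and stop after five
treatment years. Confidence intervals on EC/ET are out of scope — the
model reports point expectations; uncertainty is explored through the
one-way sensitivity scenarios instead.
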