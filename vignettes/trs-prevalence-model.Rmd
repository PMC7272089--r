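---
title: "An incidence-prevalence-mortality model for treatment-resistant schizophrenia"
author: "trsipm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An incidence-prevalence-mortality model for treatment-resistant schizophrenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trsipm)
```

## The model and its assumptions

`trsipm` estimates the cross-sectional prevalence of
treatment-resistant schizophrenia (TRS) by simulating every birth
cohort of a population through four states — Population (alive,
unaffected), Schizophrenia, TRS, and Dead — in one-year Markov cycles
from birth to an index year, then reading off the index-year occupancy
of all cohorts at once.  The approach is an
incidence–prevalence–mortality (IPM) model: prevalence is not observed
but derived from incidence and mortality inputs through an internally
consistent disease process.

The structural assumptions are deliberately spartan:

* **Markov in one-year cycles.**  Transition probabilities depend only
  on the current state, age, sex and birth cohort.  In particular the
  TRS progression risk does not depend on time since schizophrenia
  onset — a one-year-cycle Markov model cannot carry duration
  dependence, so the TRS schedule is applied to every occupant of the
  Schizophrenia state alike.
* **No remission.**  Neither TRS → Schizophrenia nor
  Schizophrenia → Population flows exist; these are structurally
  absent, not merely zero-rated.
* **Closed cohorts.**  Cohorts enter at exact age 0 (the infant death
  probability applies in the first cycle) and there is no migration.
* **Constant epidemiology.**  Incidence rates, TRS risks and SMRs are
  held fixed across calendar time; only background mortality varies by
  cohort, through the cohort life table.

## Transitions within a cycle

Each live state faces up to two exits per cycle.  Mortality is
resolved first at the state's own annual death probability, and the
non-fatal transition then occurs among the cycle's survivors:

* Population: die with probability $q$ (the life-table value); the
  survivors acquire schizophrenia with the age- and sex-specific
  annual risk $p_{inc}$.
* Schizophrenia: die with $q^{SZ} = 1-(1-q)^{\mathrm{SMR}_{SZ}}$;
  survivors progress to TRS with the proxy's annual risk.
* TRS: die with $q^{TRS} = 1-(1-q)^{\mathrm{SMR}_{TRS}}$.

Two candidate conventions exist for combining competing transitions in
a cycle model: the factorized form above, and a simultaneous
allocation on the rate scale, $P(j) = (r_j/R)(1-e^{-R})$ with
$R=\sum r_j$.  We use the factorized form, for a structural reason:
it keeps each state's per-cycle mortality exactly at its SMR-adjusted
life-table value, so that when TRS and Schizophrenia carry the same
SMR, the split of the diseased pool is irrelevant to every aggregate —
the four-state model then collapses *exactly* onto a three-state
Population/Disease/Dead model.  Under the simultaneous allocation this
aggregation consistency fails: the progression hazard competes with
death, giving Schizophrenia occupants a lower effective mortality than
TRS occupants with the identical SMR (about $2\times10^{-4}$ per cycle
at default rates, roughly 1% of the diseased pool over a lifetime).
Since two of the headline analyses are precisely about *whether* TRS
mortality differs from schizophrenia mortality, we consider exact
collapse under equality a requirement, not a nicety.  The two
conventions differ by less than $10^{-6}$ in any single transition
probability at realistic rates, far inside every reported tolerance; a
dedicated test verifies the collapse property at $10^{-9}$ against an
independently coded three-state model.

A consequence of computing transitions from start-of-cycle states is
that incident cases cannot progress to TRS, nor incur excess
mortality, in the cycle of onset.  The state at age $a$ in a
trajectory reflects transitions at start-of-cycle ages $0..a-1$; with
an at-risk window of 15–70 and no mortality, schizophrenia occupancy
at age $a \le 71$ is the geometric-depletion closed form
$1-(1-p)^{a-15}$, which the tests verify to $10^{-12}$.

## Rates, risks, and SMR adjustment

Published incidence is a rate per person-year; the model needs
one-cycle risks.  We interconvert with the constant-hazard-within-cycle
forms $p = 1-e^{-r}$ and $r = -\ln(1-p)$ (implemented with
`expm1`/`log1p` so that round-trips hold to $10^{-12}$ relative across
the whole usable range).

Standardized mortality ratios multiply the *hazard*, not the
probability: $q \mapsto 1-(1-q)^{\mathrm{SMR}}$.  Naive probability
multiplication exceeds 1 for large $q \cdot \mathrm{SMR}$ (e.g.
$q=0.37$, SMR 2.8); the hazard-scale form is standard multistate
life-table practice, is the identity at SMR 1, and is jointly monotone
in both arguments.

## Parameters

| Parameter | Default (M / F) | Units | Notes |
|---|---|---|---|
| IR schizophrenia, median | 1.5 / 1.0 | per 10,000/yr | 10th–90th pct: 0.7/0.3 – 3.4/3.0 |
| SMR Schizophrenia, median | 2.8 / 2.5 | — | 10th–90th pct: 1.7/1.5 – 4.7/5.4 |
| SMR TRS (proxy 1), median | 1.8 / 1.7 | — | 10th–90th pct: 1.1/1.0 – 3.1/3.6 |
| SMR TRS (proxies 2, 3) | = SMR SZ | — | overridable for variant analyses |
| At-risk ages | 15–70 | years | no incident schizophrenia outside |
| Cohorts | 1930–2014 | birth year | index-year ages 0–84 |
| Cycle | 1 | year | |

The printed TRS-state SMRs for proxy 1 are taken as authoritative
inputs.  One could instead derive them from the reported ~44% mortality
reduction under continuous clozapine use (SMR ratio 0.56), but the
printed pairs imply a ratio near 0.65; the package does not attempt to
reconcile the two and uses the printed values.

The overall incidence rate is spread over ages by a relative weight
curve and rescaled so that the reference-population-weighted mean rate
over the at-risk ages reproduces the overall rate exactly (verified to
$10^{-10}$ by direct summation in the tests).  Whether the reference
population should be the at-risk ages only or all ages is not
determinable from the published description; we default to the at-risk
ages — the natural reading of an incidence rate among the population
at risk — and expose `incidence_reference = "all_ages"` as a switch
(the two differ by the population share outside ages 15–70, about
85/56 at a flat pyramid).

## The cross-section

Cohort sizes are back-calculated: each (birth year, sex) cohort is
simulated once at unit size, and its initial size is set to the census
count at its index-year age divided by the simulated survivor
fraction.  This guarantees the model's index-year age structure equals
the census, which the per-10,000 scaling silently assumes; sizing
cohorts at birth instead would let accumulated mortality error distort
the denominator.  The prevalence denominator is the census population
at the ages the cohorts actually cover (0–84 for the default range) —
including ages 85+ would dilute prevalence with people the model never
simulates — with `denominator = "all_ages"` available as the alternate
reading.  The TRS proportion, $100 \cdot TRS/(TRS+SZ)$, is
denominator-free, and a degenerate run with no diseased occupancy
reports it as 0 with a warning rather than failing, so sensitivity
sweeps that pass through zero incidence complete.

Report tables round to one decimal, half up (not banker's), matching
the presentation convention of published prevalence tables; all
internal arithmetic keeps full precision.

## The synthetic input bundle

The three real-world inputs — national cohort life tables, an
index-year census, and a registry-derived TRS incidence schedule — are
not redistributable, so the package generates structural stand-ins
(deterministic given the configuration, hence bit-identical per seed):

* **Mortality**: Gompertz–Makeham hazard
  $\mu(x) = a + be^{cx}$ ($a=4\times10^{-4}$, $b=2.5\times10^{-5}$,
  $c=0.10$), a male excess factor of 1.45, a proportional decline of
  1.2%/yr of birth cohort, and an age-0 override (infant $q$ 0.045 for
  the 1930 cohort, improving likewise).  This is the minimal family
  with the qualitative structure of national cohort tables: an infant
  hump, exponential senescence, and secular improvement.  Default
  parameters give a life expectancy at birth (ages 0–84 truncated) in
  the low 70s/high 70s for the 1930 male/female cohorts, verified by
  an independent survivorship summation in the tests.
* **Population**: a smooth pyramid, broad to about age 60 and tapering
  above, scaled to $3.1\times10^8$, with a male share declining from
  51.2% at birth to ~47% at 84.
* **Onset ages**: gamma-shaped curves over ages 15–70, modes at 22
  (men) and 26 (women).
* **TRS schedules**: constant annual risks of 0.009 (P1), 0.015 (P2),
  0.040 (P3) from age 15 — magnitudes consistent with registry
  estimates of roughly 1–2 clozapine-qualifying events per 100
  patient-years under the narrower definitions and several-fold more
  under the polypharmacy definition, ordered P1 < P2 < P3 because each
  wider proxy contains the narrower one.  These levels place the
  main-definition TRS proportion in the 15–30% band that brackets the
  published estimates; they are a fixture convention, not a claim
  about the registry rates.

What the bundle does **not** emulate: migration, period shocks (wars,
pandemics), cohort-specific incidence trends, heaping and smoothing
artifacts of real census data, or any duration structure in TRS
progression.  Tests passing on the bundle therefore certify the
*machinery* — conservation, aggregation, normalization, monotonicity,
agreement with an agent-level microsimulation — not agreement with the
published US-2014 prevalence values, which depend on the withheld
inputs.  The acceptance blocks that compare against those published
values run on the stand-ins and document the remaining gap (the
synthetic main-definition cross-section lands at 5.6 per 10,000 and
21.9% versus the published 6.5 and 21.5%); they are expected to fail
on prevalence while the structural patterns — proxy ordering,
proportion invariance across incidence rows, monotonicity in each
input, direction of both TRS-mortality variants — all reproduce.

## Numerical and testing choices

* Life-table probabilities are clamped below $1-10^{-12}$ before
  hazard conversion so an exact $q=1$ cannot produce an infinite rate.
* Occupancy conservation holds to $10^{-9}$ relative over 85 cycles
  (each cycle distributes exactly, so error is pure rounding).
* The engine's primary oracle is an agent-based microsimulation using
  the same per-cycle probabilities: $10^5$ agents on one synthetic
  cohort, compared within 3 binomial standard errors at every age and
  state under a fixed seed.  Problem sizes in the default suite — 85
  cohorts × 2 sexes per scenario cell, 17 cells in the full report,
  one $10^5$-agent microsimulation — keep a full run around ten
  seconds while leaving every property at its stated tolerance.
* All generators and the whole pipeline are deterministic; repeated
  CLI invocations are byte-identical, which the suite checks on raw
  file contents.

## Limitations

Beyond the structural assumptions above: the three proxies are
imperfect observables of clinical treatment resistance; constant
epidemiology ignores reported incidence and SMR trends; the synthetic
bundle supports structural validation only; and parameter uncertainty
is explored by one-way percentile sweeps, not probabilistically — a
probabilistic sensitivity analysis over the input distributions would
be the natural extension.
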