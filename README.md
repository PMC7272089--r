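# trsipm

Estimating the prevalence of treatment-resistant schizophrenia (TRS)
with an incidence–prevalence–mortality (IPM) Markov cohort model.

## The problem

Schizophrenia affects roughly 0.3–0.7% of the population, and a
substantial minority of patients — often quoted as 30%, with literature
estimates anywhere from 10% to 60% — respond minimally to at least two
adequate antipsychotic trials and are called treatment-resistant.
There is no ICD or DSM code for TRS and no registry that counts these
patients directly, so its burden has to be inferred.  One route is a
mathematical model that synthesizes what *is* measured: schizophrenia
incidence, the rate at which schizophrenia becomes treatment-resistant
under an observable proxy definition (clozapine initiation,
clozapine eligibility, or prolonged antipsychotic polypharmacy), excess
mortality of the diseased states, and national life tables and census
counts.

`trsipm` implements that synthesis for epidemiologists and
health-policy modellers.  Each birth cohort is propagated through four
states — **Population → Schizophrenia → TRS → Dead** — in one-year
cycles from birth to an index year; the cross-section of all cohorts at
the index year yields TRS prevalence per 10,000 population and the TRS
proportion among the schizophrenia population.

## The model

For a cohort of birth year $b$ and sex $s$, ages advance in one-year
cycles.  With background annual death probability $q_{b,s}(x)$ from a
cohort life table, the diseased states die at SMR-adjusted
probabilities computed on the hazard scale,

$$q^{SZ} = 1 - (1-q)^{\mathrm{SMR}_{SZ}}, \qquad
  q^{TRS} = 1 - (1-q)^{\mathrm{SMR}_{TRS}},$$

which keeps every probability in $[0,1)$ for any SMR.  Within a cycle,
mortality is resolved first and the non-fatal transitions occur among
survivors: from Population, schizophrenia onset at annual risk
$p_{inc}(x,s)$ (an overall incidence of $IR$ per 10,000, spread over
the at-risk ages 15–70 by a relative age-weight curve and normalized so
the population-weighted mean rate reproduces $IR$); from Schizophrenia,
progression to TRS at the proxy's annual risk.  There is no remission
and no migration.  Annual risks and rates interconvert by
$p = 1-e^{-r}$.

Cohort sizes are back-calculated so that simulated survivors at the
index year equal the census count at the cohort's age, making the
model's age structure match the prevalence denominator exactly.  Three
proxy definitions (P1 ⊂ P2 ⊂ P3) are supported, P2 — clozapine
initiation or eligibility — being the main one; P1 carries its own,
lower, TRS SMR reflecting mortality benefits observed under continuous
clozapine use.  One-way sensitivity analyses move the incidence or the
SMR inputs to their published 10th/90th percentiles, one axis at a
time.

Because the study's registry inputs are not redistributable, the
package ships a synthetic generator (`make_synthetic_bundle()`) that
emulates their structure: Gompertz–Makeham cohort mortality with
secular improvement and an infant-mortality override, a smooth
2014-like population pyramid, unimodal onset-age curves peaking at 22
(men) and 26 (women), and proxy-ordered constant TRS risk schedules.

## Worked example

```r
library(trsipm)
cfg      <- synthetic_config(seed = 1)
bundle   <- make_synthetic_bundle(cfg)
scenario <- make_scenario("P2", config = cfg)   # main proxy, median inputs
result   <- run_cross_section(scenario, bundle$life_table,
                              bundle$population)
print(result, digits = 3)
#>            scenario_label proxy   sex sz_prevalence_per_10k
#> 1 P2 ir=median smr=median    P2     M                  23.7
#> 2 P2 ir=median smr=median    P2     F                  16.0
#> 3 P2 ir=median smr=median    P2 Total                  19.8
#>   trs_prevalence_per_10k trs_proportion_pct
#> 1                   6.63               21.9
#> 2                   4.53               22.0
#> 3                   5.57               21.9
```

Read: in the synthetic 2014 cross-section, 5.57 of every 10,000
people are in the TRS state under the main proxy (6.63 among men, 4.53
among women), the non-resistant Schizophrenia state holds another 19.8
per 10,000, and TRS patients are 21.9% of the schizophrenia
population.  `table1_report()` runs every parameter row, proxy and the
two additional TRS-mortality analyses; `one_way_sensitivity()` runs a
single axis; `widen_report()` and `write_report()` produce the wide
"M / F / Total" table layout and tidy CSVs.

A thin command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/trsipm synth  --out-dir data/
Rscript inst/cli/trsipm table1 --life-table data/life_table.csv \
    --population data/population.csv --out-dir results/
```

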