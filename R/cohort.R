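#' Per-state transition probabilities for one cycle
#'
#' Computes, for each live state of the four-state model
#' (Population, Schizophrenia, TRS; Dead is absorbing), the
#' probabilities of every outgoing transition plus the stay
#' probability, for a person of the given age, sex and birth cohort.
#'
#' Background mortality is the cohort life table's annual probability;
#' the Schizophrenia and TRS states multiply its hazard by their SMRs
#' (see [apply_smr()]).  Within a cycle, mortality is resolved first at
#' the state's own death probability, and the non-fatal transitions
#' (schizophrenia onset, TRS progression) then occur among the cycle's
#' survivors at their annual risks:
#' \deqn{P(\mathrm{die}) = q^{state}, \quad
#'       P(\mathrm{move}) = (1 - q^{state})\, p, \quad
#'       P(\mathrm{stay}) = (1 - q^{state})(1 - p).}
#' This factorization keeps each state's per-cycle mortality exactly at
#' its SMR-adjusted life-table value, so the diseased pool aggregates
#' consistently: when TRS and Schizophrenia carry the same SMR, total
#' diseased occupancy is identical to a model that never splits the two
#' states.  An allocation that lets the progression hazard compete with
#' death inside the cycle loses that aggregation property, because it
#' gives the two diseased states different effective mortality.
#'
#' @param age Integer age at the start of the cycle.
#' @param sex `"M"` or `"F"`.
#' @param birth_year Integer birth year (selects the cohort's life
#'   table column).
#' @param scenario A resolved [scenario_spec()] (see
#'   [resolve_scenario()]).
#' @param life_table A [life_table()] or [life_table_index()].
#' @return A list with elements `population`, `schizophrenia`, `trs`,
#'   each a named probability vector summing to 1.
#' @export
transition_probabilities <- function(age, sex, birth_year, scenario,
                                     life_table) {
  p <- cycle_probabilities(age, sex, birth_year, scenario, life_table)
  list(
    population = c(schizophrenia = (1 - p$q_pop[1]) * p$p_inc[1],
                   dead = p$q_pop[1],
                   stay = (1 - p$q_pop[1]) * (1 - p$p_inc[1])),
    schizophrenia = c(trs = (1 - p$q_sz[1]) * p$p_trs[1],
                      dead = p$q_sz[1],
                      stay = (1 - p$q_sz[1]) * (1 - p$p_trs[1])),
    trs = c(dead = p$q_trs[1], stay = 1 - p$q_trs[1])
  )
}

# Vectorized per-cycle transition inputs; `ages` may be a vector.
cycle_probabilities <- function(ages, sex, birth_year, scenario, life_table) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(scenario$incidence_schedule)) {
    stop_invalid("scenario has no incidence schedule; call ",
                 "resolve_scenario() with a reference population first")
  }
  check_sex(sex)
  q <- pmin(cohort_q(life_table, birth_year, sex, ages), 1 - 1e-12)
  list(
    q_pop = q,
    q_sz = apply_smr(q, scenario$smr_sz[[sex]]),
    q_trs = apply_smr(q, scenario$smr_trs[[sex]]),
    p_inc = schedule_values(scenario$incidence_schedule, sex, ages),
    p_trs = schedule_values(scenario$trs_schedule, sex, ages)
  )
}

#' Simulate one birth cohort's expected state occupancy to an end year
#'
#' Deterministic Markov cohort simulation: the full cohort starts in
#' the Population state at age 0 in its birth year, and each one-year
#' cycle redistributes expected occupancy with
#' [transition_probabilities()] evaluated at the start-of-cycle age.
#' There is no remission (TRS never returns to Schizophrenia, nor
#' Schizophrenia to Population) and no migration; total occupancy is
#' conserved and the Dead state only grows.  Incident cases cannot
#' progress further or incur excess mortality within their incidence
#' cycle, since transitions depend on the start-of-cycle state only.
#'
#' @inheritParams transition_probabilities
#' @param initial_size Cohort size placed in Population at age 0.
#' @param end_year Final calendar year simulated (the cross-section
#'   year, typically).
#' @return A data frame of class `cohort_trajectory` with columns
#'   `calendar_year`, `age`, `population`, `schizophrenia`, `trs`,
#'   `dead`; one row per age from 0 to `end_year - birth_year`.
#' @export
simulate_cohort <- function(birth_year, sex, initial_size, scenario,
                            life_table, end_year) {
  birth_year <- as.integer(birth_year)
  end_year <- as.integer(end_year)
  if (end_year < birth_year) {
    stop_invalid("end_year must not precede birth_year")
  }
  n_cycles <- end_year - birth_year
  ages <- 0:n_cycles
  occ <- matrix(0, n_cycles + 1L, 4L,
                dimnames = list(NULL, STATE_NAMES))
  occ[1L, "population"] <- initial_size
  if (n_cycles > 0L) {
    p <- cycle_probabilities(ages[-length(ages)], sex, birth_year,
                             scenario, life_table)
    for (i in seq_len(n_cycles)) {
      pop <- occ[i, "population"]; sz <- occ[i, "schizophrenia"]
      trs <- occ[i, "trs"]; dead <- occ[i, "dead"]
      pop_surv <- pop * (1 - p$q_pop[i])
      sz_surv <- sz * (1 - p$q_sz[i])
      occ[i + 1L, "population"] <- pop_surv * (1 - p$p_inc[i])
      occ[i + 1L, "schizophrenia"] <- pop_surv * p$p_inc[i] +
        sz_surv * (1 - p$p_trs[i])
      occ[i + 1L, "trs"] <- sz_surv * p$p_trs[i] + trs * (1 - p$q_trs[i])
      occ[i + 1L, "dead"] <- dead + pop * p$q_pop[i] + sz * p$q_sz[i] +
        trs * p$q_trs[i]
    }
  } else {
    check_sex(sex)
  }
  out <- data.frame(calendar_year = birth_year + ages, age = ages, occ)
  structure(out, birth_year = birth_year, sex = sex,
            initial_size = initial_size,
            class = c("cohort_trajectory", "data.frame"))
}
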