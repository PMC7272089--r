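# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; the oracles deliberately re-derive quantities by a
# different route than the implementation under test.

# One synthetic bundle reused across files (generation is cheap but the
# life-table index is worth sharing).
default_bundle <- local({
  bundle <- NULL
  function() {
    if (is.null(bundle)) {
      bundle <<- make_synthetic_bundle(synthetic_config())
      bundle$index <<- life_table_index(bundle$life_table)
    }
    bundle
  }
})

# Full report on the default bundle, computed once and reused.
default_report <- local({
  rep <- NULL
  function() {
    if (is.null(rep)) {
      b <- default_bundle()
      rep <<- table1_report(b$index, b$population, config = b$config)
    }
    rep
  }
})

# A deliberately tiny deterministic world for fast engine tests:
# constant mortality, short age range.
toy_life_table <- function(q = 0.01, cohorts = 1990:2014, max_year = 2014) {
  rows <- do.call(rbind, lapply(cohorts, function(by) {
    ages <- 0:(max_year - by)
    data.frame(birth_year = by, sex = rep(c("M", "F"), each = length(ages)),
               age = ages, q = q)
  }))
  life_table(rows$birth_year, rows$sex, rows$age, rows$q)
}

flat_weights <- function(ages = 0:84, window = c(15, 70)) {
  w <- setNames(ifelse(ages >= window[1] & ages <= window[2], 1, 0),
                as.character(ages))
  list(M = w, F = w)
}

constant_schedule <- function(risk, ages = 0:84, window = c(15, 84)) {
  value <- ifelse(ages >= window[1] & ages <= window[2], risk, 0)
  rate_schedule(rep(ages, 2), rep(c("M", "F"), each = length(ages)),
                rep(value, 2), kind = "annual_risk", age_window = window)
}

# Scenario with a hand-set constant incidence risk (bypasses the
# population-weighted normalization so closed forms stay exact).
toy_scenario <- function(inc_risk = 0.002, trs_risk = 0.01,
                         smr_sz = c(M = 2.8, F = 2.5),
                         smr_trs = "same_as_sz",
                         inc_window = c(15, 70)) {
  sc <- scenario_spec(proxy = "P2", ir_sz_per_10k = c(M = 1.5, F = 1.0),
                      age_weights = flat_weights(),
                      smr_sz = smr_sz, smr_trs = smr_trs,
                      trs_schedule = constant_schedule(trs_risk),
                      age_window = inc_window)
  sc$incidence_schedule <- constant_schedule(inc_risk, window = inc_window)
  sc
}

# --- Oracles -----------------------------------------------------------

# Agent-based microsimulation: samples individual one-cycle transitions
# with the same per-cycle probabilities the deterministic engine uses,
# so cohort expectations must agree within binomial error.
microsim_cohort <- function(birth_year, sex, n_agents, scenario, lt,
                            end_year, seed) {
  set.seed(seed)
  n_cycles <- end_year - birth_year
  state <- rep(1L, n_agents)  # 1 pop, 2 sz, 3 trs, 4 dead
  occ <- matrix(0L, n_cycles + 1L, 4L,
                dimnames = list(NULL, c("population", "schizophrenia",
                                        "trs", "dead")))
  occ[1L, ] <- tabulate(state, 4L)
  for (i in seq_len(n_cycles)) {
    age <- i - 1L
    tp <- transition_probabilities(age, sex, birth_year, scenario, lt)
    new <- state
    for (st in 1:3) {
      idx <- which(state == st)
      if (!length(idx)) next
      p <- tp[[c("population", "schizophrenia", "trs")[st]]]
      dest <- switch(st, c(2L, 4L, 1L), c(3L, 4L, 2L), c(4L, 3L))
      u <- runif(length(idx))
      cum <- cumsum(p)
      new[idx] <- dest[findInterval(u, cum) + 1L]
    }
    state <- new
    occ[i + 1L, ] <- tabulate(state, 4L)
  }
  occ
}

# Independent three-state cohort model with the TRS split removed:
# Population -> Disease -> Dead, disease mortality at the shared SMR.
# When trs and schizophrenia mortality coincide, total diseased
# occupancy of the four-state engine must match this exactly.
collapsed_cohort <- function(initial, inc_risk_by_age, q_by_age, smr) {
  n <- length(q_by_age)
  occ <- matrix(0, n + 1L, 3L,
                dimnames = list(NULL, c("population", "disease", "dead")))
  occ[1L, "population"] <- initial
  for (i in seq_len(n)) {
    q <- q_by_age[i]
    q_dis <- -expm1(-smr * -log1p(-q))
    surv <- occ[i, "population"] * (1 - q)
    occ[i + 1L, "population"] <- surv * (1 - inc_risk_by_age[i])
    occ[i + 1L, "disease"] <- surv * inc_risk_by_age[i] +
      occ[i, "disease"] * (1 - q_dis)
    occ[i + 1L, "dead"] <- occ[i, "dead"] + occ[i, "population"] * q +
      occ[i, "disease"] * q_dis
  }
  occ
}

# Period life expectancy at birth by direct survivorship summation.
life_expectancy_at_birth <- function(lt, birth_year, sex, max_age) {
  q <- cohort_q(lt, birth_year, sex, 0:max_age)
  l <- cumprod(c(1, 1 - q))
  sum((l[-length(l)] + l[-1]) / 2)
}
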