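#' Spread an overall incidence rate over ages with a weight curve
#'
#' Published schizophrenia incidence is an overall rate per 10,000, but
#' incidence varies strongly with age and sex.  This routine turns an
#' overall rate plus a relative age-weight curve into a per-age
#' annual-risk schedule: per-age rates are proportional to the weight
#' curve, scaled so that the reference-population-weighted mean rate
#' over the at-risk ages reproduces the overall rate, then converted to
#' annual risks for the one-year cycle.
#'
#' The normalizing reference population is either the at-risk ages only
#' (default) or the full population, controlled by `reference`; the two
#' differ by the share of the population outside the at-risk window.
#'
#' @param ir_per_10k_by_sex Named vector `c(M = , F = )`, overall
#'   incidence per 10,000 per year.
#' @param age_weight_curve List `list(M = , F = )` of non-negative
#'   weight vectors named by age (zero outside the window), or a single
#'   vector used for both sexes.
#' @param age_window Inclusive at-risk age window, e.g. `c(15, 70)`.
#' @param reference_population A [population_table()] supplying the
#'   weights of the normalization.
#' @param reference `"at_risk"` or `"all_ages"`.
#' @return A [rate_schedule()] of kind `"annual_risk"` covering every
#'   age in the reference population, zero outside `age_window`.
#' @export
build_incidence_schedule <- function(ir_per_10k_by_sex, age_weight_curve,
                                     age_window, reference_population,
                                     reference = c("at_risk", "all_ages")) {
  reference <- match.arg(reference)
  ir <- check_sex_pair(ir_per_10k_by_sex, "ir_per_10k_by_sex", min = 0)
  stopifnot(inherits(reference_population, "population_table"))
  age_window <- as.integer(age_window)
  if (!is.list(age_weight_curve)) {
    age_weight_curve <- list(M = age_weight_curve, F = age_weight_curve)
  }
  rows <- lapply(MODEL_SEXES, function(s) {
    sub <- reference_population[reference_population$sex == s, , drop = FALSE]
    ages <- sort(sub$age)
    counts <- sub$count[order(sub$age)]
    w <- weight_at_ages(age_weight_curve[[s]], ages)
    in_win <- ages >= age_window[1] & ages <= age_window[2]
    if (any(w[!in_win] > 0)) {
      stop_invalid("age-weight curve (", s, ") is non-zero outside the ",
                   "at-risk window [", age_window[1], ", ", age_window[2], "]")
    }
    if (all(w[in_win] == 0)) {
      stop_invalid("age-weight curve (", s, ") is zero everywhere inside ",
                   "the at-risk window")
    }
    denom_pop <- if (reference == "at_risk") sum(counts[in_win]) else sum(counts)
    mean_wr <- sum(counts[in_win] * w[in_win])
    scale <- if (mean_wr > 0) (ir[[s]] / 1e4) * denom_pop / mean_wr else 0
    rate <- ifelse(in_win, scale * w, 0)
    data.frame(age = ages, sex = s, value = rate_to_annual_risk(rate),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rate_schedule(df$age, df$sex, df$value, kind = "annual_risk",
                age_window = age_window)
}

weight_at_ages <- function(curve, ages) {
  if (is.null(names(curve))) {
    stop_invalid("age-weight curves must be named by age")
  }
  if (anyNA(curve) || any(curve < 0)) {
    stop_invalid("age-weight curves must be non-negative")
  }
  w <- curve[as.character(ages)]
  w[is.na(w)] <- 0
  unname(w)
}

#' Resolve a scenario against a reference population
#'
#' Fills the scenario's incidence schedule, which depends on the
#' population used to normalize the age-weight curve.  Idempotent: a
#' scenario that already carries a schedule is returned unchanged.
#'
#' @param scenario A [scenario_spec()].
#' @param population A [population_table()].
#' @return The scenario with `incidence_schedule` set.
#' @export
resolve_scenario <- function(scenario, population) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(scenario$incidence_schedule)) return(scenario)
  scenario$incidence_schedule <- build_incidence_schedule(
    scenario$ir_sz_per_10k, scenario$age_weights, scenario$age_window,
    population, reference = scenario$incidence_reference)
  scenario
}
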