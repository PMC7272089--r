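#' Configuration for the synthetic input generator
#'
#' Bundles every knob of the synthetic stand-ins for the model's three
#' real-world inputs: cohort life tables, an index-year population
#' pyramid, and the incidence/TRS schedules.  Mortality follows a
#' Gompertz--Makeham hazard \eqn{\mu(x) = a + b e^{cx}} with a
#' proportional decline per later birth cohort (secular improvement)
#' and an infant-mortality override at age 0 — the minimal family that
#' reproduces the qualitative structure of national cohort life tables.
#'
#' @param seed Integer seed recorded with the bundle (the generators
#'   are fully deterministic, so the seed mainly tags provenance).
#' @param makeham_a Age-independent background hazard (per year).
#' @param gompertz_b,gompertz_c Gompertz level and slope of senescent
#'   mortality (per year; hazard doubles every `log(2)/gompertz_c`
#'   years).
#' @param improvement_rate Proportional hazard decline per one-year
#'   increase in birth year, in \code{[0, 0.05]}.
#' @param infant_q Age-0 death probability for the earliest cohort;
#'   later cohorts improve at `improvement_rate`.
#' @param male_mortality_factor Multiplier on the hazard for males
#'   (males die faster at every age).
#' @param pyramid_shape Non-negative relative population weights named
#'   by age 0..84; the default is a smooth 2014-like pyramid, broad up
#'   to about age 60 and tapering above.
#' @param total_population Total index-year population across both
#'   sexes and all ages.
#' @param male_fraction_at_birth,male_fraction_slope Male share of each
#'   age group: `male_fraction_at_birth - male_fraction_slope * age`
#'   (more boys are born; women outlive men).
#' @param incidence_peak_age Named vector `c(M = , F = )`: modal age of
#'   schizophrenia onset (male peak earlier by convention).
#' @param incidence_spread Scale (years) of the onset-age curve.
#' @param trs_risk_levels Named vector `c(P1 = , P2 = , P3 = )` of the
#'   constant annual TRS risk among Schizophrenia-state occupants under
#'   each proxy definition; must be strictly increasing P1 < P2 < P3
#'   because each proxy's case set contains the previous one's.
#' @param cohort_range,index_year,max_age Coverage of the bundle.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             makeham_a = 4e-4,
                             gompertz_b = 2.5e-5,
                             gompertz_c = 0.10,
                             improvement_rate = 0.012,
                             infant_q = 0.045,
                             male_mortality_factor = 1.45,
                             pyramid_shape = NULL,
                             total_population = 3.1e8,
                             male_fraction_at_birth = 0.512,
                             male_fraction_slope = 5e-4,
                             incidence_peak_age = c(M = 22, F = 26),
                             incidence_spread = 11,
                             trs_risk_levels = c(P1 = 0.009, P2 = 0.015,
                                                 P3 = 0.040),
                             cohort_range = c(1930L, 2014L),
                             index_year = 2014L,
                             max_age = 84L) {
  ages <- 0:max_age
  if (is.null(pyramid_shape)) {
    # logistic taper after ~60 with a floor, smooth and positive
    pyramid_shape <- setNames(0.08 + 1 / (1 + exp((ages - 62) / 9)),
                              as.character(ages))
  }
  cfg <- list(seed = as.integer(seed), makeham_a = makeham_a,
              gompertz_b = gompertz_b, gompertz_c = gompertz_c,
              improvement_rate = improvement_rate, infant_q = infant_q,
              male_mortality_factor = male_mortality_factor,
              pyramid_shape = pyramid_shape,
              total_population = total_population,
              male_fraction_at_birth = male_fraction_at_birth,
              male_fraction_slope = male_fraction_slope,
              incidence_peak_age = incidence_peak_age,
              incidence_spread = incidence_spread,
              trs_risk_levels = trs_risk_levels,
              cohort_range = as.integer(cohort_range),
              index_year = as.integer(index_year),
              max_age = as.integer(max_age))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (makeham_a <= 0 || gompertz_b <= 0 || gompertz_c <= 0) {
      stop_invalid("Gompertz-Makeham parameters must be positive")
    }
    if (improvement_rate < 0 || improvement_rate > 0.05) {
      stop_invalid("improvement_rate must lie in [0, 0.05]")
    }
    if (infant_q <= 0 || infant_q >= 1) {
      stop_invalid("infant_q must be a probability in (0, 1)")
    }
    if (anyNA(pyramid_shape) || any(pyramid_shape < 0) ||
        all(pyramid_shape == 0)) {
      stop_invalid("pyramid_shape must be non-negative with some mass")
    }
    if (!all(c("P1", "P2", "P3") %in% names(trs_risk_levels)) ||
        !(trs_risk_levels[["P1"]] < trs_risk_levels[["P2"]] &&
          trs_risk_levels[["P2"]] < trs_risk_levels[["P3"]])) {
      stop_invalid("trs_risk_levels must be ordered P1 < P2 < P3")
    }
    if (any(trs_risk_levels < 0) || any(trs_risk_levels > 1)) {
      stop_invalid("trs_risk_levels are annual risks and must lie in [0, 1]")
    }
    pk <- incidence_peak_age
    if (any(pk < 15) || any(pk > 70)) {
      stop_invalid("incidence peaks must lie inside the at-risk ages [15, 70]")
    }
  })
  invisible(cfg)
}

#' Generate synthetic cohort life tables
#'
#' One annual death probability per (birth year, sex, age) from the
#' Gompertz--Makeham hazard with per-cohort proportional improvement:
#' \eqn{q(x) = 1 - \exp\{-(a + b e^{cx})(1-\rho)^{y - y_0}\}} for
#' cohort \eqn{y} (earliest cohort \eqn{y_0}), with the infant
#' probability overridden at age 0 and the male hazard scaled up.
#' Deterministic given the configuration.
#'
#' @param config A [synthetic_config()].
#' @return A [life_table()] covering every cohort in
#'   `config$cohort_range` from age 0 through the index year.
#' @export
make_life_tables <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cohorts <- config$cohort_range[1]:config$cohort_range[2]
  rows <- lapply(cohorts, function(by) {
    ages <- 0:(config$index_year - by)
    improve <- (1 - config$improvement_rate)^(by - config$cohort_range[1])
    haz <- (config$makeham_a + config$gompertz_b *
              exp(config$gompertz_c * ages)) * improve
    do.call(rbind, lapply(MODEL_SEXES, function(s) {
      mult <- if (s == "M") config$male_mortality_factor else 1
      q <- -expm1(-haz * mult)
      q[ages == 0] <- min(config$infant_q * mult * improve, 0.99)
      data.frame(birth_year = by, sex = s, age = ages, q = q,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  life_table(df$birth_year, df$sex, df$age, df$q)
}

#' Generate a synthetic index-year population pyramid
#'
#' Counts by single year of age and sex: the configured relative shape
#' scaled to the configured total, split between sexes by a male share
#' that declines linearly with age.
#'
#' @param config A [synthetic_config()].
#' @return A [population_table()] covering ages 0..`max_age`.
#' @export
make_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ages <- 0:config$max_age
  w <- weight_at_ages(config$pyramid_shape, ages)
  if (all(w == 0)) stop_invalid("pyramid_shape has no mass on ages 0..max_age")
  n_age <- config$total_population * w / sum(w)
  mf <- config$male_fraction_at_birth - config$male_fraction_slope * ages
  mf <- pmin(pmax(mf, 0.01), 0.99)
  population_table(age = rep(ages, 2L),
                   sex = rep(MODEL_SEXES, each = length(ages)),
                   count = c(n_age * mf, n_age * (1 - mf)),
                   index_year = config$index_year)
}

#' Generate unimodal age-weight curves for schizophrenia onset
#'
#' A gamma-shaped curve over the at-risk ages, zero outside
#' \code{[15, 70]}, with its mode at the configured peak age (male
#' peak earlier than female).  Only relative shape matters: the curve
#' is rescaled against the overall incidence rate by
#' [build_incidence_schedule()].
#'
#' @param config A [synthetic_config()].
#' @return `list(M = , F = )` of weight vectors named by age 0..84.
#' @export
make_incidence_weights <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ages <- 0:config$max_age
  lapply(setNames(MODEL_SEXES, MODEL_SEXES), function(s) {
    peak <- config$incidence_peak_age[[s]]
    shift <- ages - 14          # curve support starts at age 15
    shape <- 1 + (peak - 14) / config$incidence_spread
    w <- stats::dgamma(shift, shape = shape,
                       rate = 1 / config$incidence_spread)
    w[ages < 15 | ages > 70] <- 0
    setNames(w / max(w), as.character(ages))
  })
}

#' Generate a synthetic TRS annual-risk schedule for one proxy
#'
#' A constant annual risk of progressing from the Schizophrenia state
#' to TRS, applied at every age from 15 up, at the configured level for
#' the chosen proxy.  Levels are ordered P1 < P2 < P3 pointwise, since
#' each wider proxy definition captures every case of the narrower one.
#'
#' @param config A [synthetic_config()].
#' @param proxy `"P1"`, `"P2"` or `"P3"`.
#' @return A [rate_schedule()] of annual risks over ages 15..`max_age`.
#' @export
make_trs_schedule <- function(config, proxy) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!proxy %in% c("P1", "P2", "P3")) {
    stop_invalid("unknown proxy '", proxy, "'")
  }
  ages <- 0:config$max_age
  level <- config$trs_risk_levels[[proxy]]
  value <- ifelse(ages >= 15, level, 0)
  rate_schedule(age = rep(ages, 2L),
                sex = rep(MODEL_SEXES, each = length(ages)),
                value = rep(value, 2L), kind = "annual_risk",
                age_window = c(15L, config$max_age))
}

#' Generate the full synthetic input bundle
#'
#' Everything the pipeline needs in one call: life tables, population,
#' incidence weights and the three per-proxy TRS schedules.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `life_table`, `population`,
#'   `age_weights`, `trs_schedules` (list `P1`/`P2`/`P3`) and `config`.
#' @export
make_synthetic_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  list(life_table = make_life_tables(config),
       population = make_population(config),
       age_weights = make_incidence_weights(config),
       trs_schedules = lapply(setNames(c("P1", "P2", "P3"),
                                       c("P1", "P2", "P3")),
                              function(p) make_trs_schedule(config, p)),
       config = config)
}
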