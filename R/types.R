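#' @importFrom stats setNames
NULL

MODEL_SEXES <- c("M", "F")
STATE_NAMES <- c("population", "schizophrenia", "trs", "dead")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("trsipm_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_coverage <- function(...) {
  stop(structure(class = c("trsipm_data_coverage", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_sex <- function(sex) {
  if (!all(sex %in% MODEL_SEXES)) {
    stop_invalid("sex must be coded 'M' or 'F', got: ",
                 paste(unique(setdiff(sex, MODEL_SEXES)), collapse = ", "))
  }
  sex
}

#' Construct an age- and sex-indexed transition schedule
#'
#' A `rate_schedule` holds one non-negative value per (integer age, sex),
#' either a per-person-year rate or an annual risk, together with the
#' inclusive age window inside which transitions may occur.  Values must
#' be zero outside the window; annual risks must lie in \code{[0, 1]}.
#'
#' @param age Integer ages (single completed years).
#' @param sex Character vector, `"M"`/`"F"`, recycled against `age`.
#' @param value Non-negative values, one per (age, sex) pair.
#' @param kind `"annual_risk"` or `"rate_per_person_year"`.
#' @param age_window Inclusive `c(lo, hi)` integer age window.
#' @return A data frame of class `rate_schedule` with columns
#'   `age`, `sex`, `value` and attributes `kind` and `age_window`.
#' @export
rate_schedule <- function(age, sex, value,
                          kind = c("annual_risk", "rate_per_person_year"),
                          age_window) {
  kind <- match.arg(kind)
  df <- data.frame(age = as.integer(age), sex = as.character(sex),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  check_sex(df$sex)
  if (anyNA(df$value) || any(df$value < 0)) {
    stop_invalid("schedule values must be non-negative and finite")
  }
  if (kind == "annual_risk" && any(df$value > 1)) {
    stop_invalid("annual-risk schedule values must lie in [0, 1]")
  }
  age_window <- as.integer(age_window)
  if (length(age_window) != 2L || age_window[1] > age_window[2]) {
    stop_invalid("age_window must be an inclusive integer pair [lo, hi]")
  }
  outside <- df$age < age_window[1] | df$age > age_window[2]
  if (any(df$value[outside] > 0)) {
    stop_invalid("schedule has non-zero values outside age window [",
                 age_window[1], ", ", age_window[2], "]")
  }
  if (anyDuplicated(df[c("age", "sex")])) {
    stop_invalid("duplicate (age, sex) keys in schedule")
  }
  structure(df, kind = kind, age_window = age_window,
            class = c("rate_schedule", "data.frame"))
}

#' Look up schedule values for a sex over a vector of ages
#'
#' Ages absent from the schedule (including everything outside its age
#' window) return 0.
#'
#' @param schedule A [rate_schedule()].
#' @param sex `"M"` or `"F"`.
#' @param ages Integer ages.
#' @return Numeric vector of values, same length as `ages`.
#' @export
schedule_values <- function(schedule, sex, ages) {
  stopifnot(inherits(schedule, "rate_schedule"))
  check_sex(sex)
  sub <- schedule[schedule$sex == sex, , drop = FALSE]
  idx <- match(as.integer(ages), sub$age)
  out <- sub$value[idx]
  out[is.na(out)] <- 0
  out
}

#' Construct a cohort life table
#'
#' Annual death probabilities indexed by birth year, sex and age, the
#' representation needed for cohort (as opposed to period) mortality:
#' each birth cohort carries its own mortality history, so secular
#' improvement across cohorts is captured.
#'
#' @param birth_year,sex,age,q Parallel vectors: integer birth year,
#'   `"M"`/`"F"`, integer age, and annual death probability in
#'   \code{[0, 1]}.
#' @return A data frame of class `life_table` with those four columns.
#' @export
life_table <- function(birth_year, sex, age, q) {
  df <- data.frame(birth_year = as.integer(birth_year),
                   sex = as.character(sex),
                   age = as.integer(age), q = as.numeric(q),
                   stringsAsFactors = FALSE)
  check_sex(df$sex)
  if (anyNA(df$q) || any(df$q < 0) || any(df$q > 1)) {
    bad <- which(is.na(df$q) | df$q < 0 | df$q > 1)[1]
    stop_invalid("death probability out of [0, 1] at (birth_year=",
                 df$birth_year[bad], ", sex=", df$sex[bad],
                 ", age=", df$age[bad], ")")
  }
  if (anyDuplicated(df[c("birth_year", "sex", "age")])) {
    stop_invalid("duplicate (birth_year, sex, age) keys in life table")
  }
  structure(df, class = c("life_table", "data.frame"))
}

#' Extract one cohort's death probabilities over a run of ages
#'
#' @param lt A [life_table()] or an index built by [life_table_index()].
#' @param birth_year Integer birth year.
#' @param sex `"M"` or `"F"`.
#' @param ages Integer ages; every age must be covered.
#' @return Numeric vector of annual death probabilities.
#' @export
cohort_q <- function(lt, birth_year, sex, ages) {
  if (inherits(lt, "life_table_index")) {
    mat <- lt[[sex]]
    by <- as.character(birth_year)
    q <- if (by %in% colnames(mat)) mat[as.character(ages), by] else
      rep(NA_real_, length(ages))
  } else {
    stopifnot(inherits(lt, "life_table"))
    sub <- lt[lt$birth_year == birth_year & lt$sex == sex, , drop = FALSE]
    q <- sub$q[match(as.integer(ages), sub$age)]
  }
  if (anyNA(q)) {
    miss <- ages[which(is.na(q))[1]]
    stop_coverage("life table does not cover (birth_year=", birth_year,
                  ", sex=", sex, ", age=", miss, ")")
  }
  unname(q)
}

#' Build a fast lookup index over a life table
#'
#' Repeated cohort extraction from a long-format life table is the hot
#' path of the cross-section; this converts it once into per-sex
#' age-by-cohort matrices.  [cohort_q()] accepts the result wherever it
#' accepts the life table itself.
#'
#' @param lt A [life_table()].
#' @return An object of class `life_table_index`.
#' @export
life_table_index <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  out <- lapply(setNames(MODEL_SEXES, MODEL_SEXES), function(s) {
    sub <- lt[lt$sex == s, , drop = FALSE]
    ages <- sort(unique(sub$age))
    bys <- sort(unique(sub$birth_year))
    mat <- matrix(NA_real_, length(ages), length(bys),
                  dimnames = list(as.character(ages), as.character(bys)))
    mat[cbind(match(sub$age, ages), match(sub$birth_year, bys))] <- sub$q
    mat
  })
  structure(out, class = "life_table_index")
}

#' Construct an index-year population table
#'
#' @param age,sex,count Parallel vectors: integer age, `"M"`/`"F"`,
#'   non-negative count.
#' @param index_year Calendar year the counts refer to.
#' @return A data frame of class `population_table` with attribute
#'   `index_year`.
#' @export
population_table <- function(age, sex, count, index_year = 2014L) {
  df <- data.frame(age = as.integer(age), sex = as.character(sex),
                   count = as.numeric(count), stringsAsFactors = FALSE)
  check_sex(df$sex)
  if (anyNA(df$count) || any(df$count < 0) || any(!is.finite(df$count))) {
    stop_invalid("population counts must be finite and non-negative")
  }
  if (anyDuplicated(df[c("age", "sex")])) {
    stop_invalid("duplicate (age, sex) keys in population table")
  }
  structure(df, index_year = as.integer(index_year),
            class = c("population_table", "data.frame"))
}

#' Look up population counts for a sex over a vector of ages
#'
#' @inheritParams schedule_values
#' @param population A [population_table()].
#' @return Numeric counts; uncovered ages raise a coverage error.
#' @export
population_counts <- function(population, sex, ages) {
  stopifnot(inherits(population, "population_table"))
  sub <- population[population$sex == sex, , drop = FALSE]
  out <- sub$count[match(as.integer(ages), sub$age)]
  if (anyNA(out)) {
    stop_coverage("population table does not cover (sex=", sex, ", age=",
                  ages[which(is.na(out))[1]], ")")
  }
  out
}

#' Assemble a full scenario parameterization
#'
#' A scenario fixes everything the cohort engine needs except the life
#' table and population: the TRS proxy definition, overall schizophrenia
#' incidence per 10,000 by sex, the age-weight curves that spread that
#' incidence over the at-risk ages, the mortality SMRs for the
#' Schizophrenia and TRS states, and the TRS annual-risk schedule.
#'
#' `smr_trs = "same_as_sz"` (the default for proxies P2 and P3, where
#' TRS mortality is assumed equal to schizophrenia mortality) resolves
#' to `smr_sz`.
#'
#' @param proxy `"P1"`, `"P2"` or `"P3"` — clozapine initiation;
#'   initiation or eligibility (main definition); either plus 90 days'
#'   antipsychotic polypharmacy.
#' @param ir_sz_per_10k Named vector `c(M = , F = )`, overall annual
#'   schizophrenia incidence per 10,000 at-risk population.
#' @param age_weights List `list(M = , F = )` of non-negative weight
#'   vectors named by age, zero outside `age_window`.
#' @param smr_sz Named vector `c(M = , F = )` of SMRs in the
#'   Schizophrenia state.
#' @param smr_trs `"same_as_sz"` or a named vector `c(M = , F = )`.
#' @param trs_schedule [rate_schedule()] of annual TRS risks applied to
#'   occupants of the Schizophrenia state.
#' @param age_window Ages at risk of incident schizophrenia.
#' @param cohort_range Inclusive birth-year range simulated.
#' @param index_year Cross-section year.
#' @param incidence_reference Which reference population normalizes the
#'   incidence weights: the at-risk ages only (default) or all ages.
#' @param label Free-text scenario label carried into results.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(proxy, ir_sz_per_10k, age_weights, smr_sz,
                          smr_trs = "same_as_sz", trs_schedule,
                          age_window = c(15L, 70L),
                          cohort_range = c(1930L, 2014L),
                          index_year = 2014L,
                          incidence_reference = c("at_risk", "all_ages"),
                          label = proxy) {
  if (!proxy %in% c("P1", "P2", "P3")) {
    stop_invalid("unknown proxy '", proxy, "' (use P1, P2 or P3)")
  }
  incidence_reference <- match.arg(incidence_reference)
  ir <- check_sex_pair(ir_sz_per_10k, "ir_sz_per_10k", min = 0)
  smr_sz <- check_sex_pair(smr_sz, "smr_sz", min = 0, strict = TRUE)
  if (identical(smr_trs, "same_as_sz")) {
    smr_trs <- smr_sz
  } else {
    smr_trs <- check_sex_pair(smr_trs, "smr_trs", min = 0, strict = TRUE)
  }
  stopifnot(inherits(trs_schedule, "rate_schedule"))
  if (!is.list(age_weights) || !all(MODEL_SEXES %in% names(age_weights))) {
    stop_invalid("age_weights must be a list with elements M and F")
  }
  cohort_range <- as.integer(cohort_range)
  if (cohort_range[1] > cohort_range[2]) {
    stop_invalid("cohort_range must be an increasing pair")
  }
  structure(list(proxy = proxy, ir_sz_per_10k = ir,
                 age_weights = age_weights, smr_sz = smr_sz,
                 smr_trs = smr_trs, trs_schedule = trs_schedule,
                 age_window = as.integer(age_window),
                 cohort_range = cohort_range,
                 index_year = as.integer(index_year),
                 incidence_reference = incidence_reference,
                 incidence_schedule = NULL, label = label),
            class = "scenario_spec")
}

check_sex_pair <- function(x, what, min = 0, strict = FALSE) {
  if (length(x) != 2L) stop_invalid(what, " must have one value per sex")
  if (is.null(names(x)) || !all(MODEL_SEXES %in% names(x))) {
    names(x) <- MODEL_SEXES
  }
  x <- x[MODEL_SEXES]
  ok <- is.numeric(x) && !anyNA(x) && all(is.finite(x)) &&
    if (strict) all(x > min) else all(x >= min)
  if (!ok) {
    stop_invalid(what, " must be ", if (strict) "strictly above " else
      "at least ", min, " for both sexes")
  }
  x
}
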