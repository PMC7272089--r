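# CSV dialect is fixed: comma separator, '.' decimal, UTF-8, header
# required — so files written on one machine parse identically on any
# other regardless of locale.

read_validated_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop_invalid("input file does not exist: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid(path, ": missing required column(s) ",
                 paste(missing, collapse = ", "))
  }
  df
}

check_numeric_column <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x)) {
    suppressWarnings(xn <- as.numeric(x))
  } else {
    xn <- as.numeric(x)
  }
  bad <- which(is.na(xn) & !is.na(x))
  if (length(bad)) {
    stop_invalid(path, ": cannot parse column '", col, "' at data line ",
                 bad[1], " (value '", x[bad[1]], "')")
  }
  if (anyNA(xn)) {
    stop_invalid(path, ": missing value in column '", col, "' at data line ",
                 which(is.na(xn))[1])
  }
  xn
}

#' Read a cohort life table from CSV
#'
#' Expects columns `birth_year,sex,age,q`; duplicate
#' (birth_year, sex, age) keys and probabilities outside \code{[0, 1]}
#' are rejected with the offending key named.  A non-monotone run of
#' `q` over ages 40+ within a cohort only triggers a warning, since
#' real tables can wobble slightly.
#'
#' @param path CSV file path.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  df <- read_validated_csv(path, c("birth_year", "sex", "age", "q"))
  lt <- life_table(check_numeric_column(df, "birth_year", path), df$sex,
                   check_numeric_column(df, "age", path),
                   check_numeric_column(df, "q", path))
  old <- lt[lt$age >= 40, , drop = FALSE]
  if (nrow(old)) {
    ord <- order(old$birth_year, old$sex, old$age)
    old <- old[ord, ]
    grp <- paste(old$birth_year, old$sex)
    dec <- diff(old$q) < -1e-9 & grp[-1] == grp[-length(grp)]
    if (any(dec)) {
      warning(path, ": death probabilities decrease with age above 40 ",
              "for cohort (", old$birth_year[which(dec)[1] + 1], ", ",
              old$sex[which(dec)[1] + 1], ")", call. = FALSE)
    }
  }
  lt
}

#' Read an index-year population table from CSV
#'
#' Expects columns `age,sex,count`; negative counts are rejected.
#'
#' @param path CSV file path.
#' @param index_year Calendar year the counts refer to.
#' @return A [population_table()].
#' @export
read_population <- function(path, index_year = 2014L) {
  df <- read_validated_csv(path, c("age", "sex", "count"))
  population_table(check_numeric_column(df, "age", path), df$sex,
                   check_numeric_column(df, "count", path),
                   index_year = index_year)
}

#' Read an annual-risk transition schedule from CSV
#'
#' Expects columns `age,sex,annual_risk`.  If `scenario_window` is
#' given, non-zero risks outside it trigger a validation warning (the
#' schedule's own window is widened to fit, so reading still succeeds).
#'
#' @param path CSV file path.
#' @param age_window Inclusive age window recorded on the schedule;
#'   default spans the ages present.
#' @param scenario_window Optional window to cross-check against.
#' @return A [rate_schedule()] of kind `"annual_risk"`.
#' @export
read_schedule <- function(path, age_window = NULL, scenario_window = NULL) {
  df <- read_validated_csv(path, c("age", "sex", "annual_risk"))
  age <- check_numeric_column(df, "age", path)
  risk <- check_numeric_column(df, "annual_risk", path)
  if (is.null(age_window)) age_window <- range(age)
  if (!is.null(scenario_window)) {
    outside <- risk > 0 & (age < scenario_window[1] | age > scenario_window[2])
    if (any(outside)) {
      warning(path, ": schedule has non-zero risk at age ",
              age[which(outside)[1]], ", outside the scenario window [",
              scenario_window[1], ", ", scenario_window[2], "]",
              call. = FALSE)
    }
  }
  rate_schedule(age, df$sex, risk, kind = "annual_risk",
                age_window = age_window)
}

#' Write model inputs back to their CSV formats
#'
#' Full-precision (17 significant digits) writers for the three input
#' types, so a write/read round trip is lossless.
#'
#' @param x The object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(x, path) {
  stopifnot(inherits(x, "life_table"))
  write_plain_csv(data.frame(birth_year = x$birth_year, sex = x$sex,
                             age = x$age, q = full_precision(x$q)), path)
}

#' @rdname write_life_table
#' @export
write_population <- function(x, path) {
  stopifnot(inherits(x, "population_table"))
  write_plain_csv(data.frame(age = x$age, sex = x$sex,
                             count = full_precision(x$count)), path)
}

#' @rdname write_life_table
#' @export
write_schedule <- function(x, path) {
  stopifnot(inherits(x, "rate_schedule"))
  write_plain_csv(data.frame(age = x$age, sex = x$sex,
                             annual_risk = full_precision(x$value)), path)
}

full_precision <- function(x) formatC(x, format = "g", digits = 17)

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a prevalence report as tidy and/or wide CSV
#'
#' The tidy file has one row per scenario cell, sex and measure; the
#' wide file mirrors a published-table layout via [widen_report()].
#'
#' @param report A `sensitivity_table` or `prevalence_result`.
#' @param tidy_path,wide_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, tidy_path = NULL, wide_path = NULL) {
  written <- character()
  if (!is.null(tidy_path)) {
    long <- report
    id_cols <- intersect(c("axis", "level", "scenario_label", "proxy", "sex"),
                         names(long))
    measures <- c("sz_prevalence_per_10k", "trs_prevalence_per_10k",
                  "trs_proportion_pct")
    tidy <- do.call(rbind, lapply(measures, function(m) {
      cbind(long[id_cols], measure = m,
            value = full_precision(long[[m]]))
    }))
    ord <- do.call(order, tidy[id_cols])
    write_plain_csv(tidy[ord, ], tidy_path)
    written <- c(written, tidy_path)
  }
  if (!is.null(wide_path)) {
    if (!all(c("axis", "level") %in% names(report))) {
      report <- cbind(axis = "scenario",
                      level = report$scenario_label, report)
    }
    write_plain_csv(widen_report(report), wide_path)
    written <- c(written, wide_path)
  }
  invisible(written)
}

#' Read a run configuration from a YAML file
#'
#' Recognized fields: `life_table`, `population`, `trs_schedule`
#' (single path or per-proxy map), `proxy`, `incidence`, `smr`,
#' `denominator` (`ages_0_84`/`all_ages`), `index_year`, `out_dir`,
#' `seed`, `log_level`.  Unknown fields are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("life_table", "population", "trs_schedule", "proxy",
             "incidence", "smr", "denominator", "index_year", "out_dir",
             "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_invalid(path, ": unknown config field(s) ",
                 paste(unknown, collapse = ", "))
  }
  defaults <- list(proxy = "P2", incidence = "median", smr = "median",
                   denominator = "ages_0_84", index_year = 2014L,
                   out_dir = ".", seed = 1L, log_level = "info")
  cfg <- utils::modifyList(defaults, raw)
  structure(cfg, class = "run_config")
}

log_msg <- function(level, ..., threshold = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  }
}
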