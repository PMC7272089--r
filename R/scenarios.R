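# Published parameter sets: median and 10th/90th percentile schizophrenia
# incidence per 10,000 and mortality SMRs, by sex.  The TRS-state SMR set
# is used for proxy P1 only; P2 and P3 share the schizophrenia SMR.
IR_SZ_LEVELS <- list(median = c(M = 1.5, F = 1.0),
                     p10 = c(M = 0.7, F = 0.3),
                     p90 = c(M = 3.4, F = 3.0))
SMR_SZ_LEVELS <- list(median = c(M = 2.8, F = 2.5),
                      p10 = c(M = 1.7, F = 1.5),
                      p90 = c(M = 4.7, F = 5.4))
SMR_TRS_P1_LEVELS <- list(median = c(M = 1.8, F = 1.7),
                          p10 = c(M = 1.1, F = 1.0),
                          p90 = c(M = 3.1, F = 3.6))

pick_level <- function(levels, level, what) {
  if (!level %in% names(levels)) {
    stop_invalid("unknown ", what, " level '", level,
                 "' (use median, p10 or p90)")
  }
  levels[[level]]
}

#' Build a scenario from proxy and percentile levels
#'
#' Resolves the published parameter sets into a full
#' [scenario_spec()]: overall schizophrenia incidence and the
#' schizophrenia-state SMR at the requested percentile level, and the
#' TRS-state SMR following the proxy convention — proxy P1 (clozapine
#' initiation) uses its own, lower, TRS SMR set, while P2 and P3 assume
#' TRS mortality equal to schizophrenia mortality.  `smr_trs` overrides
#' that convention for the additional analyses (e.g. a P1-style TRS SMR
#' under P2, or TRS SMR raised 25\% above the schizophrenia SMR).
#'
#' @param proxy `"P1"`, `"P2"` or `"P3"`.
#' @param incidence,smr Percentile level per axis: `"median"`, `"p10"`
#'   or `"p90"`.
#' @param trs_schedule A [rate_schedule()] of annual TRS risks; default
#'   is the synthetic schedule for the proxy under `config`.
#' @param age_weights Incidence age-weight curves `list(M = , F = )`;
#'   default synthetic.
#' @param smr_trs Optional named vector `c(M = , F = )` overriding the
#'   TRS-state SMR.
#' @param config [synthetic_config()] used for synthetic defaults.
#' @param ... Passed to [scenario_spec()] (e.g. `cohort_range`,
#'   `index_year`, `incidence_reference`).
#' @return A [scenario_spec()].
#' @export
make_scenario <- function(proxy, incidence = "median", smr = "median",
                          trs_schedule = NULL, age_weights = NULL,
                          smr_trs = NULL, config = synthetic_config(), ...) {
  if (!proxy %in% c("P1", "P2", "P3")) {
    stop_invalid("unknown proxy '", proxy, "' (use P1, P2 or P3)")
  }
  ir <- pick_level(IR_SZ_LEVELS, incidence, "incidence")
  smr_sz <- pick_level(SMR_SZ_LEVELS, smr, "smr")
  if (is.null(smr_trs)) {
    smr_trs <- if (proxy == "P1") {
      pick_level(SMR_TRS_P1_LEVELS, smr, "smr")
    } else {
      "same_as_sz"
    }
  }
  if (is.null(trs_schedule)) trs_schedule <- make_trs_schedule(config, proxy)
  if (is.null(age_weights)) age_weights <- make_incidence_weights(config)
  scenario_spec(proxy = proxy, ir_sz_per_10k = ir,
                age_weights = age_weights, smr_sz = smr_sz,
                smr_trs = smr_trs, trs_schedule = trs_schedule,
                label = paste0(proxy, " ir=", incidence, " smr=", smr), ...)
}

#' Index-year cross-section over all birth cohorts
#'
#' Runs the Markov cohort engine for every birth cohort in the
#' scenario's range and reads off the index-year occupancy.  Each
#' cohort is sized by back-calculation: a unit cohort is simulated from
#' birth, and its initial size is set so the simulated survivors at the
#' index year equal the census count at the cohort's index-year age —
#' which makes the model's age structure match the population
#' denominator exactly.  Per-sex and pooled Schizophrenia- and
#' TRS-state occupancies are then scaled to prevalence per 10,000 of
#' the denominator population, and the TRS proportion is
#' \eqn{100 \cdot TRS / (TRS + SZ)}.
#'
#' @param scenario A [scenario_spec()] (resolved against `population`
#'   automatically).
#' @param life_table A [life_table()] or [life_table_index()] covering
#'   all cohorts through the index year.
#' @param population A [population_table()] for the index year.
#' @param denominator `"ages_0_84"` (ages covered by the simulated
#'   cohorts; default) or `"all_ages"` (every age in the population
#'   table).
#' @return A data frame of class `prevalence_result`: one row per sex
#'   plus a pooled `Total` row, with columns `scenario_label`, `proxy`,
#'   `sex`, `sz_prevalence_per_10k` (Schizophrenia state, i.e.
#'   non-resistant), `trs_prevalence_per_10k`, `trs_proportion_pct`.
#' @export
run_cross_section <- function(scenario, life_table, population,
                              denominator = c("ages_0_84", "all_ages")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(population, "population_table"))
  scenario <- resolve_scenario(scenario, population)
  if (!inherits(life_table, "life_table_index")) {
    life_table <- life_table_index(life_table)
  }
  cohorts <- scenario$cohort_range[1]:scenario$cohort_range[2]
  iy <- scenario$index_year
  occ <- list()
  denom <- c(M = 0, F = 0)
  for (s in MODEL_SEXES) {
    sz_sum <- 0
    trs_sum <- 0
    for (by in cohorts) {
      age_iy <- iy - by
      census <- population_counts(population, s, age_iy)
      unit <- simulate_cohort(by, s, 1, scenario, life_table, iy)
      last <- unit[nrow(unit), ]
      alive <- last$population + last$schizophrenia + last$trs
      if (alive <= 0) {
        stop_coverage("no simulated survivors for cohort (", by, ", ", s,
                      "); cannot back-calculate its size")
      }
      size <- census / alive
      sz_sum <- sz_sum + size * last$schizophrenia
      trs_sum <- trs_sum + size * last$trs
    }
    occ[[s]] <- c(sz = sz_sum, trs = trs_sum)
    sub <- population[population$sex == s, , drop = FALSE]
    keep <- if (denominator == "ages_0_84") {
      sub$age >= iy - scenario$cohort_range[2] &
        sub$age <= iy - scenario$cohort_range[1]
    } else {
      rep(TRUE, nrow(sub))
    }
    denom[[s]] <- sum(sub$count[keep])
  }
  degenerate <- character()
  per_sex <- lapply(c("M", "F", "Total"), function(s) {
    if (s == "Total") {
      num <- occ$M + occ$F
      den <- sum(denom)
    } else {
      num <- occ[[s]]
      den <- denom[[s]]
    }
    diseased <- num[["sz"]] + num[["trs"]]
    prop <- if (diseased > 0) 100 * num[["trs"]] / diseased else {
      degenerate <<- c(degenerate, s)
      0
    }
    data.frame(scenario_label = scenario$label, proxy = scenario$proxy,
               sex = s,
               sz_prevalence_per_10k = 1e4 * num[["sz"]] / den,
               trs_prevalence_per_10k = 1e4 * num[["trs"]] / den,
               trs_proportion_pct = prop, stringsAsFactors = FALSE)
  })
  if (length(degenerate)) {
    warning("no diseased occupancy for ", paste(degenerate, collapse = ", "),
            "; TRS proportion reported as 0", call. = FALSE)
  }
  structure(do.call(rbind, per_sex),
            class = c("prevalence_result", "data.frame"))
}

#' One-way sensitivity analysis over incidence and SMR inputs
#'
#' Varies one parameter axis at a time to its 10th/90th percentile set
#' while the other stays at its median, re-running the full
#' cross-section for each level.  The SMR axis moves the
#' schizophrenia-state SMR and, for proxy P1, the TRS-state SMR to the
#' same percentile.
#'
#' @param base_scenario A [scenario_spec()] built at median levels; its
#'   proxy, TRS schedule, age weights and structural settings are kept.
#' @param axes Character subset of `c("incidence", "smr")`.
#' @inheritParams run_cross_section
#' @return A data frame of class `sensitivity_table`: the per-sex
#'   [run_cross_section()] rows stacked, with columns `axis` and
#'   `level` prepended.
#' @export
one_way_sensitivity <- function(base_scenario, axes = c("incidence", "smr"),
                                life_table, population,
                                denominator = c("ages_0_84", "all_ages")) {
  stopifnot(inherits(base_scenario, "scenario_spec"))
  axes <- match.arg(axes, several.ok = TRUE)
  denominator <- match.arg(denominator)
  if (!inherits(life_table, "life_table_index")) {
    life_table <- life_table_index(life_table)
  }
  rows <- list()
  for (axis in axes) {
    for (level in c("p10", "median", "p90")) {
      sc <- scenario_at_level(base_scenario, axis, level)
      res <- run_cross_section(sc, life_table, population, denominator)
      rows[[paste(axis, level)]] <-
        cbind(axis = axis, level = level, res)
    }
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("sensitivity_table", "data.frame"))
}

# Rebuild a scenario with one axis moved to a percentile level.
scenario_at_level <- function(base, axis, level) {
  sc <- base
  if (axis == "incidence") {
    sc$ir_sz_per_10k <- pick_level(IR_SZ_LEVELS, level, "incidence")
    sc$incidence_schedule <- NULL   # must be rebuilt at the new rate
  } else if (axis == "smr") {
    sc$smr_sz <- pick_level(SMR_SZ_LEVELS, level, "smr")
    sc$smr_trs <- if (base$proxy == "P1") {
      pick_level(SMR_TRS_P1_LEVELS, level, "smr")
    } else {
      sc$smr_sz
    }
  }
  sc$label <- paste0(base$proxy, " ", axis, "=", level)
  sc
}

#' Full prevalence report: every parameter row, every proxy
#'
#' Runs the cross-section for the median parameter row, the four
#' one-way sensitivity rows (incidence and SMR at their 10th and 90th
#' percentiles), each under all three TRS proxy definitions, plus the
#' two additional proxy-2 mortality analyses: a P1-style TRS SMR of
#' (1.8, 1.7), and a TRS SMR raised 25\% above the schizophrenia SMR.
#'
#' @param life_table A [life_table()] or [life_table_index()].
#' @param population A [population_table()].
#' @param config [synthetic_config()] supplying synthetic defaults for
#'   whatever `trs_schedules` / `age_weights` do not.
#' @param trs_schedules Optional list `P1`/`P2`/`P3` of
#'   [rate_schedule()]s (e.g. read from file with [read_schedule()]).
#' @param age_weights Optional incidence age-weight curves.
#' @inheritParams run_cross_section
#' @param ... Passed to [make_scenario()].
#' @return A `sensitivity_table` data frame with columns `axis`,
#'   `level`, then the [run_cross_section()] columns; the additional
#'   analyses carry `axis = "smr_trs_variant"`.
#' @export
table1_report <- function(life_table, population,
                          config = synthetic_config(),
                          trs_schedules = NULL, age_weights = NULL,
                          denominator = c("ages_0_84", "all_ages"), ...) {
  denominator <- match.arg(denominator)
  if (!inherits(life_table, "life_table_index")) {
    life_table <- life_table_index(life_table)
  }
  if (is.null(trs_schedules)) {
    trs_schedules <- lapply(setNames(c("P1", "P2", "P3"),
                                     c("P1", "P2", "P3")),
                            function(p) make_trs_schedule(config, p))
  }
  if (is.null(age_weights)) age_weights <- make_incidence_weights(config)
  cells <- list(median = list(axis = "median", incidence = "median",
                              smr = "median"),
                ir_p10 = list(axis = "incidence", incidence = "p10",
                              smr = "median"),
                ir_p90 = list(axis = "incidence", incidence = "p90",
                              smr = "median"),
                smr_p10 = list(axis = "smr", incidence = "median",
                               smr = "p10"),
                smr_p90 = list(axis = "smr", incidence = "median",
                               smr = "p90"))
  rows <- list()
  for (nm in names(cells)) {
    cell <- cells[[nm]]
    level <- if (cell$axis == "median") "median" else
      c(cell$incidence, cell$smr)[c(cell$incidence, cell$smr) != "median"][1]
    for (proxy in c("P1", "P2", "P3")) {
      sc <- make_scenario(proxy, incidence = cell$incidence, smr = cell$smr,
                          trs_schedule = trs_schedules[[proxy]],
                          age_weights = age_weights, config = config, ...)
      res <- run_cross_section(sc, life_table, population, denominator)
      rows[[paste(nm, proxy)]] <- cbind(axis = cell$axis, level = level, res)
    }
  }
  # Additional proxy-2 mortality analyses
  variants <- list(
    p1_style_trs_smr = SMR_TRS_P1_LEVELS$median,
    trs_smr_plus_25pct = 1.25 * SMR_SZ_LEVELS$median
  )
  for (nm in names(variants)) {
    sc <- make_scenario("P2", smr_trs = variants[[nm]],
                        trs_schedule = trs_schedules$P2,
                        age_weights = age_weights, config = config, ...)
    sc$label <- paste0("P2 ", nm)
    res <- run_cross_section(sc, life_table, population, denominator)
    rows[[nm]] <- cbind(axis = "smr_trs_variant", level = nm, res)
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("sensitivity_table", "data.frame"))
}

# Round half up (not to even) to `digits` decimals, the presentation
# convention of the published tables.
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Reshape a report to one wide row per parameter cell
#'
#' Columns `<proxy>_prev` and `<proxy>_prop` hold "M / F / Total"
#' strings rounded to one decimal (half up), mirroring the layout of a
#' published prevalence table.
#'
#' @param report A `sensitivity_table` from [table1_report()] or
#'   [one_way_sensitivity()].
#' @return A wide data frame, one row per (axis, level).
#' @export
widen_report <- function(report) {
  stopifnot(is.data.frame(report),
            all(c("axis", "level", "proxy", "sex") %in% names(report)))
  keys <- unique(report[c("axis", "level")])
  proxies <- unique(report$proxy)
  out <- lapply(seq_len(nrow(keys)), function(i) {
    block <- report[report$axis == keys$axis[i] &
                      report$level == keys$level[i], , drop = FALSE]
    row <- data.frame(axis = keys$axis[i], level = keys$level[i],
                      stringsAsFactors = FALSE)
    for (proxy in proxies) {
      pb <- block[block$proxy == proxy, , drop = FALSE]
      fmt <- function(col) {
        if (nrow(pb) == 0) return(NA_character_)
        paste(format(round_half_up(
          pb[[col]][match(c("M", "F", "Total"), pb$sex)]),
          nsmall = 1, trim = TRUE), collapse = " / ")
      }
      row[[paste0(proxy, "_prev")]] <- fmt("trs_prevalence_per_10k")
      row[[paste0(proxy, "_prop")]] <- fmt("trs_proportion_pct")
    }
    row
  })
  do.call(rbind, out)
}
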