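# A small closed world for fast cross-section tests: cohorts 1990-2014,
# constant background mortality, flat pyramid.
toy_world <- function(q = 0.005) {
  pop <- population_table(rep(0:24, 2), rep(c("M", "F"), each = 25),
                          rep(c(10000, 9800), each = 25))
  list(lt = toy_life_table(q = q), pop = pop)
}

toy_cross_scenario <- function(ir = c(M = 1.5, F = 1.0), ...) {
  scenario_spec(proxy = "P2", ir_sz_per_10k = ir,
                age_weights = flat_weights(),
                smr_sz = c(M = 2.8, F = 2.5),
                trs_schedule = constant_schedule(0.015),
                cohort_range = c(1990L, 2014L), ...)
}

test_that("scenario assembly resolves proxy conventions", {
  p2 <- make_scenario("P2")
  expect_equal(p2$ir_sz_per_10k, c(M = 1.5, F = 1.0))
  expect_equal(p2$smr_sz, c(M = 2.8, F = 2.5))
  expect_equal(p2$smr_trs, p2$smr_sz)  # TRS mortality assumed equal
  p3 <- make_scenario("P3", smr = "p90")
  expect_equal(p3$smr_sz, c(M = 4.7, F = 5.4))
  expect_equal(p3$smr_trs, p3$smr_sz)
  p1 <- make_scenario("P1")
  expect_equal(p1$smr_trs, c(M = 1.8, F = 1.7))  # clozapine-lowered TRS SMR
  p1_lo <- make_scenario("P1", smr = "p10")
  expect_equal(p1_lo$smr_sz, c(M = 1.7, F = 1.5))
  expect_equal(p1_lo$smr_trs, c(M = 1.1, F = 1.0))
  adj <- make_scenario("P2", smr_trs = 1.25 * c(M = 2.8, F = 2.5))
  expect_equal(adj$smr_trs, c(M = 3.5, F = 3.125))
  expect_error(make_scenario("P4"), "unknown proxy")
  expect_error(make_scenario("P2", incidence = "p50"), "unknown incidence")
})

test_that("zero incidence yields zero prevalence and a warned-zero proportion", {
  w <- toy_world()
  sc <- toy_cross_scenario(ir = c(M = 0, F = 0))
  expect_warning(res <- run_cross_section(sc, w$lt, w$pop),
                 "proportion reported as 0")
  expect_equal(res$trs_prevalence_per_10k, rep(0, 3))
  expect_equal(res$sz_prevalence_per_10k, rep(0, 3))
  expect_equal(res$trs_proportion_pct, rep(0, 3))
})

test_that("cross-section totals are the sex mixture with census weights", {
  w <- toy_world()
  res <- run_cross_section(toy_cross_scenario(), w$lt, w$pop)
  m <- res[res$sex == "M", ]; f <- res[res$sex == "F", ]
  tot <- res[res$sex == "Total", ]
  n_m <- 25 * 10000; n_f <- 25 * 9800
  for (col in c("sz_prevalence_per_10k", "trs_prevalence_per_10k")) {
    expect_gte(tot[[col]], min(m[[col]], f[[col]]))
    expect_lte(tot[[col]], max(m[[col]], f[[col]]))
    expect_equal(tot[[col]],
                 (m[[col]] * n_m + f[[col]] * n_f) / (n_m + n_f),
                 tolerance = 1e-9)
  }
  expect_true(all(res$trs_proportion_pct >= 0 &
                    res$trs_proportion_pct <= 100))
})

test_that("back-calculated cohort sizes reproduce the census age structure", {
  w <- toy_world(q = 0.01)
  sc <- resolve_scenario(toy_cross_scenario(), w$pop)
  lti <- life_table_index(w$lt)
  # survivors of the 1990 cohort at 2014 must equal the census count at 24
  unit <- simulate_cohort(1990, "M", 1, sc, lti, 2014)
  alive <- sum(unit[nrow(unit), c("population", "schizophrenia", "trs")])
  expect_lt(alive, 1)
  size <- 10000 / alive
  scaled <- simulate_cohort(1990, "M", size, sc, lti, 2014)
  expect_equal(sum(scaled[nrow(scaled), c("population", "schizophrenia",
                                          "trs")]), 10000, tolerance = 1e-9)
})

test_that("one-way sensitivity is consistent and monotone", {
  b <- default_bundle()
  base <- make_scenario("P2", config = b$config)
  sens <- one_way_sensitivity(base, c("incidence", "smr"), b$index,
                              b$population)
  med_inc <- sens[sens$axis == "incidence" & sens$level == "median" &
                    sens$sex == "Total", ]
  med_smr <- sens[sens$axis == "smr" & sens$level == "median" &
                    sens$sex == "Total", ]
  direct <- run_cross_section(base, b$index, b$population)
  expect_equal(med_inc$trs_prevalence_per_10k,
               direct$trs_prevalence_per_10k[direct$sex == "Total"],
               tolerance = 1e-12)
  expect_equal(med_inc$trs_prevalence_per_10k, med_smr$trs_prevalence_per_10k,
               tolerance = 1e-12)
  # prevalence rises with incidence and falls with mortality
  by_level <- function(axis, col = "trs_prevalence_per_10k") {
    vapply(c("p10", "median", "p90"), function(l) {
      sens[sens$axis == axis & sens$level == l & sens$sex == "Total", col]
    }, numeric(1))
  }
  expect_true(all(diff(by_level("incidence")) > 0))
  expect_true(all(diff(by_level("smr")) < 0))
  expect_true(all(diff(by_level("incidence", "sz_prevalence_per_10k")) > 0))
})

test_that("TRS proportion is invariant under uniform incidence scaling", {
  w <- toy_world()
  base <- run_cross_section(toy_cross_scenario(), w$lt, w$pop)
  scaled <- run_cross_section(toy_cross_scenario(ir = 3 * c(M = 1.5, F = 1.0)),
                              w$lt, w$pop)
  rel <- abs(scaled$trs_proportion_pct - base$trs_proportion_pct) /
    base$trs_proportion_pct
  expect_true(all(rel < 0.01))
  # while prevalence itself scales roughly with incidence
  expect_equal(scaled$trs_prevalence_per_10k / base$trs_prevalence_per_10k,
               rep(3, 3), tolerance = 0.01)
})

test_that("denominator switch rescales prevalence but never the proportion", {
  b <- default_bundle()
  sc <- make_scenario("P2", config = b$config,
                      cohort_range = c(1960L, 2014L))
  narrow <- run_cross_section(sc, b$index, b$population,
                              denominator = "ages_0_84")
  wide <- run_cross_section(sc, b$index, b$population,
                            denominator = "all_ages")
  # cohorts 1960-2014 cover ages 0-54 only, so the 0-84 census is wider
  expect_true(all(wide$trs_prevalence_per_10k <
                    narrow$trs_prevalence_per_10k))
  expect_equal(wide$trs_proportion_pct, narrow$trs_proportion_pct,
               tolerance = 1e-12)
})

test_that("the full report covers every cell with the proxy ordering", {
  rep <- default_report()
  expect_equal(nrow(rep), (5 * 3 + 2) * 3)
  tot <- rep[rep$sex == "Total", ]
  for (lev in unique(tot$level[tot$axis %in%
                               c("median", "incidence", "smr")])) {
    for (ax in unique(tot$axis[tot$level == lev])) {
      cell <- tot[tot$axis == ax & tot$level == lev, ]
      prev <- setNames(cell$trs_prevalence_per_10k, cell$proxy)
      expect_true(prev[["P1"]] < prev[["P2"]] &&
                    prev[["P2"]] < prev[["P3"]])
    }
  }
  # proportion barely moves across incidence rows within a proxy
  for (p in c("P1", "P2", "P3")) {
    inc_rows <- tot[tot$proxy == p & tot$axis %in% c("median", "incidence"), ]
    expect_lt(diff(range(inc_rows$trs_proportion_pct)), 1)
  }
  # P1-style TRS mortality raises prevalence above the shared-SMR run
  p2_med <- tot[tot$axis == "median" & tot$proxy == "P2",
                "trs_prevalence_per_10k"]
  p2_var <- tot[tot$level == "p1_style_trs_smr", "trs_prevalence_per_10k"]
  p2_hi <- tot[tot$level == "trs_smr_plus_25pct", "trs_prevalence_per_10k"]
  expect_gt(p2_var, p2_med)
  expect_lt(p2_hi, p2_med)
})

test_that("wide report layout pivots one row per parameter cell", {
  wide <- widen_report(default_report())
  expect_equal(nrow(wide), 7)
  expect_setequal(names(wide),
                  c("axis", "level", "P1_prev", "P1_prop", "P2_prev",
                    "P2_prop", "P3_prev", "P3_prop"))
  expect_match(wide$P2_prev[wide$axis == "median"],
               "^[0-9.]+ / [0-9.]+ / [0-9.]+$")
  # additional analyses exist for proxy 2 only
  expect_true(all(is.na(wide$P1_prev[wide$axis == "smr_trs_variant"])))
})
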