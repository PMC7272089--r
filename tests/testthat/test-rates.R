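# Frozen expected values below were computed from the closed forms
# 1 - exp(-r), -log(1 - q) evaluated independently at high precision.

test_that("rate/risk conversions match closed-form values", {
  expect_identical(rate_to_annual_risk(0), 0)
  expect_equal(rate_to_annual_risk(1.5e-4), 1.4998875056246e-4,
               tolerance = 1e-12)
  expect_equal(rate_to_annual_risk(10), 0.9999546000702375, tolerance = 1e-12)
  expect_lt(rate_to_annual_risk(10), 1)
  expect_identical(annual_risk_to_rate(0), 0)
  expect_equal(annual_risk_to_rate(0.01), 0.010050335853501441,
               tolerance = 1e-12)
})

test_that("conversions are mutual inverses over [0, 0.99]", {
  q <- seq(0, 0.99, by = 0.0007)
  back <- rate_to_annual_risk(annual_risk_to_rate(q))
  expect_equal(back, q, tolerance = 1e-12)
  r <- seq(0, 6, by = 0.003)
  expect_equal(annual_risk_to_rate(rate_to_annual_risk(r)), r,
               tolerance = 1e-12)
})

test_that("invalid rates and risks are rejected", {
  expect_error(rate_to_annual_risk(-0.1), "non-negative")
  expect_error(annual_risk_to_rate(1), "probability")
  expect_error(annual_risk_to_rate(-0.01), "probability")
  expect_error(apply_smr(0.01, 0), "positive")
  expect_error(apply_smr(0.01, -2), "positive")
})

test_that("SMR adjustment works on the hazard scale and stays below 1", {
  expect_equal(apply_smr(0.01, 1.0), 0.01, tolerance = 1e-14)
  expect_equal(apply_smr(0.37, 1.0), 0.37, tolerance = 1e-14)
  # 1 - exp(-2.8 * (-log 0.99)) evaluated independently
  expect_equal(apply_smr(0.01, 2.8), 0.027748672336809332, tolerance = 1e-12)
  big <- apply_smr(0.9, 5.0)
  expect_equal(big, 0.99999, tolerance = 1e-7)
  expect_lt(big, 1)
})

test_that("SMR adjustment is jointly monotone", {
  qs <- seq(0, 0.9, by = 0.05)
  smrs <- c(0.3, 0.56, 1, 1.8, 2.8, 5)
  grid <- outer(qs, smrs, apply_smr)
  expect_true(all(grid < 1))
  expect_true(all(diff(grid) >= 0))       # increasing in q
  expect_true(all(t(diff(t(grid))) >= 0)) # increasing in smr
})

test_that("flat weighting degenerates to the overall incidence rate", {
  pop <- population_table(rep(0:84, 2), rep(c("M", "F"), each = 85),
                          rep(1000, 170))
  sched <- build_incidence_schedule(c(M = 1.5, F = 1.0), flat_weights(),
                                    c(15, 70), pop)
  for (s in c("M", "F")) {
    ir <- c(M = 1.5, F = 1.0)[[s]]
    expect_equal(schedule_values(sched, s, 15:70),
                 rep(rate_to_annual_risk(ir / 1e4), 56), tolerance = 1e-12)
    # outside the at-risk window nobody acquires the condition
    expect_identical(schedule_values(sched, s, c(14, 71, 0, 84)),
                     rep(0, 4))
  }
})

test_that("schedule normalization reproduces the overall rate for random curves", {
  set.seed(7)
  pop <- population_table(rep(0:84, 2), rep(c("M", "F"), each = 85),
                          runif(170, 500, 5000))
  for (rep_i in 1:20) {
    w <- setNames(ifelse(0:84 >= 15 & 0:84 <= 70, runif(85)^2, 0),
                  as.character(0:84))
    ir <- c(M = runif(1, 0.1, 5), F = runif(1, 0.1, 5))
    sched <- build_incidence_schedule(ir, list(M = w, F = w), c(15, 70), pop)
    for (s in c("M", "F")) {
      counts <- population_counts(pop, s, 15:70)
      rates <- annual_risk_to_rate(schedule_values(sched, s, 15:70))
      expect_equal(sum(counts * rates) / sum(counts), ir[[s]] / 1e4,
                   tolerance = 1e-10)
    }
  }
})

test_that("full-population normalization spreads the rate over more heads", {
  pop <- population_table(rep(0:84, 2), rep(c("M", "F"), each = 85),
                          rep(1000, 170))
  at_risk <- build_incidence_schedule(c(M = 1, F = 1), flat_weights(),
                                      c(15, 70), pop, reference = "at_risk")
  all_ages <- build_incidence_schedule(c(M = 1, F = 1), flat_weights(),
                                       c(15, 70), pop, reference = "all_ages")
  # same overall cases, but the all-ages denominator includes ages the
  # window excludes, so per-age risks inside the window must be larger
  expect_gt(schedule_values(all_ages, "M", 30),
            schedule_values(at_risk, "M", 30))
  expect_equal(annual_risk_to_rate(schedule_values(all_ages, "M", 30)) /
                 annual_risk_to_rate(schedule_values(at_risk, "M", 30)),
               85 / 56, tolerance = 1e-9)
})

test_that("degenerate weight curves are rejected", {
  pop <- population_table(rep(0:84, 2), rep(c("M", "F"), each = 85),
                          rep(1000, 170))
  zero <- setNames(rep(0, 85), as.character(0:84))
  expect_error(build_incidence_schedule(c(M = 1, F = 1),
                                        list(M = zero, F = zero),
                                        c(15, 70), pop),
               "zero everywhere")
  outside <- setNames(ifelse(0:84 == 10, 1, 0), as.character(0:84))
  expect_error(build_incidence_schedule(c(M = 1, F = 1),
                                        list(M = outside, F = outside),
                                        c(15, 70), pop),
               "outside")
})

test_that("schedule containers enforce their invariants", {
  expect_error(rate_schedule(15, "M", 1.2, kind = "annual_risk",
                             age_window = c(15, 70)), "\\[0, 1\\]")
  expect_error(rate_schedule(c(10, 20), c("M", "M"), c(0.1, 0.1),
                             kind = "annual_risk", age_window = c(15, 70)),
               "outside age window")
  expect_error(rate_schedule(c(20, 20), c("M", "M"), c(0.1, 0.1),
                             kind = "annual_risk", age_window = c(15, 70)),
               "duplicate")
  expect_error(rate_schedule(20, "X", 0.1, kind = "annual_risk",
                             age_window = c(15, 70)), "sex")
})
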