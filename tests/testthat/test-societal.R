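test_that("formal care splits the 48-day window by funding branch", {
  fc <- formal_care_cost_per_death(default_p$care)
  expect_equal(fc$private, 0.174 * 8 * 13.56 * 48)
  expect_equal(fc$public, 0.095 * 1.5 * 13.56 * 48)
  expect_equal(fc$total, fc$public + fc$private)
  care0 <- default_p$care
  care0$wage_per_hour <- 0
  expect_equal(formal_care_cost_per_death(care0)$total, 0)
})

test_that("informal care accrues over post-progression occupancy", {
  p <- default_p
  p$settings$discount_rate_annual <- 0
  # a cohort that never progresses receives no informal care
  expect_equal(informal_care_cost(make_trace(p), p), 0)
  # exactly 100 post-progression days at the default assumptions
  tr <- make_trace(p, n_cycles = 10,
                   frac_stable = rep(0, 11),
                   frac_postprog = c(rep(100 / 210, 10), 0))
  expect_equal(informal_care_cost(tr, p), 0.934 * 10.3 * 13.56 * 100,
               tolerance = 1e-12)
  # linear in care hours
  p2 <- p
  p2$care$hours_informal <- 2 * p$care$hours_informal
  expect_equal(informal_care_cost(tr, p2), 2 * informal_care_cost(tr, p))
  # the alternative window books a 48-day block per death instead
  p3 <- p
  p3$settings$informal_care_window <- "last_48_days"
  tr_d <- make_trace(p3, n_cycles = 10,
                     new_deaths = c(0, 1, rep(0, 9)))
  expect_equal(informal_care_cost(tr_d, p3), 0.934 * 10.3 * 13.56 * 48,
               tolerance = 1e-12)
})

test_that("temporary leave is zero past retirement and 67 expected days before", {
  p <- default_p
  # stage IV cohorts are diagnosed at 68.1 years: no productivity loss
  expect_equal(temporary_leave_cost(make_trace(p, "IV"), p), 0)
  # nobody employed, nothing lost
  p0 <- p
  p0$labour$employment_rate <- rep(0, nrow(p0$labour))
  expect_equal(temporary_leave_cost(make_trace(p0, "I"), p0), 0)
  # fully employed at unit daily wage: exactly 0.3*60 + 0.7*70 = 67 days
  p1 <- p
  p1$settings$discount_rate_annual <- 0
  p1$settings$productivity_growth <- 0
  p1$labour$employment_rate <- rep(1, nrow(p1$labour))
  p1$labour$annual_wage <- rep(365.25, nrow(p1$labour))
  tr <- make_trace(p1, "I", age_dx = 50, size = 10)
  expect_equal(temporary_leave_cost(tr, p1), 10 * 67)
})

test_that("progression sick leave splits at one year and caps at retirement", {
  p <- default_p
  p$settings$discount_rate_annual <- 0
  p$settings$productivity_growth <- 0
  p$labour$employment_rate <- rep(1, nrow(p$labour))
  p$labour$annual_wage <- rep(365.25, nrow(p$labour))
  t <- 21 / 365.25
  n <- 60
  # progression in the first cycle at age 63, never dying
  tr <- make_trace(p, "III", n_cycles = n, age_dx = 63,
                   frac_stable = c(1, rep(0, n)),
                   frac_postprog = c(0, rep(1, n)),
                   new_progressions = c(0, 1, rep(0, n - 1)))
  pl <- permanent_and_progression_leave_cost(tr, p)
  # working rows are those with attained age < 65
  working_rows <- which(63 + (0:(n - 1)) * t < 65)
  pp_rows <- intersect(working_rows, 2:(n + 1))
  first_year <- intersect(pp_rows, 2:19)  # 18 cycles after progression
  expect_equal(pl$progression, length(first_year) * 21)
  expect_equal(pl$permanent, (length(pp_rows) - length(first_year)) * 21)
  # lowering retirement below all ages zeroes both rows
  p2 <- p
  p2$settings$retirement_age <- 40
  pl2 <- permanent_and_progression_leave_cost(tr, p2)
  expect_equal(pl2$progression, 0)
  expect_equal(pl2$permanent, 0)
})

test_that("stage III defaults yield zero permanent disability, stage IV zero IC", {
  p <- default_p
  tr3 <- run_cohort_trace(p$stages$III, 2017, 100, p$settings, p$life_table)
  pl3 <- permanent_and_progression_leave_cost(tr3, p)
  expect_equal(pl3$permanent, 0)
  expect_gt(pl3$progression, 0)

  tr4 <- run_cohort_trace(p$stages$IV, 2017, 100, p$settings, p$life_table)
  expect_equal(temporary_leave_cost(tr4, p), 0)
  pl4 <- permanent_and_progression_leave_cost(tr4, p)
  expect_equal(pl4$progression, 0)
  expect_equal(pl4$permanent, 0)
  expect_equal(premature_mortality_cost(tr4, p), 0)
})

test_that("premature mortality values lost earnings until retirement", {
  p <- default_p
  p$settings$discount_rate_annual <- 0
  p$settings$productivity_growth <- 0
  p$labour$employment_rate <- rep(1, nrow(p$labour))
  p$labour$annual_wage <- rep(1000, nrow(p$labour))
  t <- 21 / 365.25
  # one death at exactly age 64: one lost year of wage
  tr <- make_trace(p, "I", n_cycles = 5, age_dx = 64 - t,
                   new_deaths = c(0, 1, 0, 0, 0, 0))
  expect_equal(premature_mortality_cost(tr, p), 1000)
  # with growth, two lost years compound from the accrual date
  p2 <- p
  p2$settings$productivity_growth <- 0.01
  p2$labour$annual_wage <- rep(100, nrow(p2$labour))
  tr2 <- make_trace(p2, "I", n_cycles = 5, age_dx = 63 - t,
                    new_deaths = c(0, 1, 0, 0, 0, 0))
  el <- t  # death occurs one cycle after model start
  expect_equal(premature_mortality_cost(tr2, p2),
               100 * 1.01^el + 100 * 1.01^(el + 1), tolerance = 1e-12)
  # scaling all wages scales every indirect stream
  p3 <- p
  p3$labour$annual_wage <- 2 * p$labour$annual_wage
  expect_equal(premature_mortality_cost(tr, p3),
               2 * premature_mortality_cost(tr, p))
})

test_that("retirement age zero switches off all indirect costs", {
  p <- default_p
  p$settings$retirement_age <- 0
  tr <- run_cohort_trace(p$stages$I, 2017, 100, p$settings, p$life_table)
  expect_equal(temporary_leave_cost(tr, p), 0)
  pl <- permanent_and_progression_leave_cost(tr, p)
  expect_equal(pl$progression + pl$permanent, 0)
  expect_equal(premature_mortality_cost(tr, p), 0)
  # and zero informal share switches off the informal-care row
  p2 <- default_p
  p2$care$pct_informal <- 0
  tr2 <- run_cohort_trace(p2$stages$III, 2017, 100, p2$settings, p2$life_table)
  expect_equal(informal_care_cost(tr2, p2), 0)
})
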