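t_cycle <- 21 / 365.25

test_that("exponential hazard and progression probability follow the closed forms", {
  expect_equal(exp_rate_from_median(log(2)), 1.0)
  expect_equal(exp_rate_from_median(8.33), 0.0832109460456117, tolerance = 1e-12)
  expect_equal(exp_rate_from_median(1.60), 0.433216987849966, tolerance = 1e-12)
  expect_error(exp_rate_from_median(0), "median")

  # the median is the definition of the 50% point under an exponential
  for (me in c(18.33, 6.25, 2.00, 1.60)) expect_equal(prob_progress(me, me), 0.5)
  expect_equal(prob_progress(5, 0), 0)
  expect_equal(prob_progress(1.6, t_cycle), 0.0246001143058315, tolerance = 1e-12)
})

test_that("post-progression death probability adds natural mortality and caps at 1", {
  for (s in default_p$stages)
    expect_equal(prob_death_postprog(s$median_os, s$median_pfs,
                                     s$median_os - s$median_pfs, 0), 0.5)
  expect_equal(prob_death_postprog(1.9, 1.6, t_cycle, 0),
               0.124396003261426, tolerance = 1e-12)
  expect_equal(prob_death_postprog(1.9, 1.6, t_cycle, 1), 1)
  expect_error(prob_death_postprog(1.0, 1.6, t_cycle, 0), "median_os")
})

test_that("natural death probability converts rates over the cycle length", {
  lt0 <- data.frame(age = 0:100, annual_mortality_rate = 0)
  expect_equal(natural_death_prob(50, lt0, t_cycle), 0)
  lt <- data.frame(age = 0:100, annual_mortality_rate = 0.01)
  expect_equal(natural_death_prob(50, lt, 1), 1 - exp(-0.01))
  expect_equal(natural_death_prob(50, lt, t_cycle),
               0.000574783413985758, tolerance = 1e-12)
  # lookup beyond the table clamps to the oldest rate
  lt2 <- data.frame(age = 0:90, annual_mortality_rate = seq(0, 0.9, by = 0.01))
  expect_equal(natural_death_prob(120, lt2, 1), natural_death_prob(90, lt2, 1))
})

test_that("cycle probability rows lie on the simplex", {
  p <- default_p
  cp <- cycle_probabilities(p$stages$IV, 68, p$settings, p$life_table)
  probs <- unlist(cp)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(cp$prss + cp$pdss + cp$ppss, 1, tolerance = 1e-12)
  expect_equal(cp$prps + cp$pdps, 1, tolerance = 1e-12)
  # with zero natural mortality prss is the survival complement of ppss
  cp0 <- cycle_probabilities(p$stages$I, 60, p$settings, immortal_p$life_table)
  expect_equal(cp0$pdss, 0)
  expect_equal(cp0$prss, 1 - cp0$ppss)
  # a cycle as long as the PFS median hits the 50% point with no mortality
  s_long <- immortal_p$settings
  s_long$cycle_days <- p$stages$I$median_pfs * 365.25
  cp_me <- cycle_probabilities(p$stages$I, 60, s_long, immortal_p$life_table)
  expect_equal(cp_me$ppss, 0.5)
  expect_equal(cp_me$prss, 0.5)
})

test_that("traces conserve occupancy and are monotone", {
  for (sl in c("I", "II", "III", "IV")) {
    tr <- run_cohort_trace(default_p$stages[[sl]], 2017, 100,
                           default_p$settings, default_p$life_table)
    expect_equal(nrow(tr), 181)
    expect_equal(tr$frac_stable[1], 1)
    expect_equal(tr$frac_dead[1], 0)
    expect_true(all(abs(tr$frac_stable + tr$frac_postprog + tr$frac_dead - 1) < 1e-9))
    expect_true(all(diff(tr$frac_dead) >= 0))
    expect_true(all(diff(tr$frac_stable) <= 0))
  }
  tr0 <- run_cohort_trace(default_p$stages$I, 2017, 0,
                          default_p$settings, default_p$life_table)
  expect_true(all(tr0$frac_stable == 0 & tr0$frac_postprog == 0 & tr0$frac_dead == 0))
})

test_that("with mortality zeroed the trace reproduces the exponential PFS curve", {
  for (sl in c("I", "IV")) {
    st <- immortal_p$stages[[sl]]
    tr <- run_cohort_trace(st, 2017, 1, immortal_p$settings, immortal_p$life_table)
    elapsed <- tr$cycle_index * t_cycle
    cum_prog <- cumsum(tr$new_progressions)
    expect_equal(cum_prog, 1 - exp(-log(2) * elapsed / st$median_pfs),
                 tolerance = 1e-9)
    expect_equal(tr$frac_stable, exp(-log(2) * elapsed / st$median_pfs),
                 tolerance = 1e-9)
  }
  # one model year (18 cycles, ~1.0345 y) against the closed form
  tr4 <- run_cohort_trace(immortal_p$stages$IV, 2017, 1, immortal_p$settings,
                          immortal_p$life_table, n_cycles = 18)
  expect_equal(tr4$frac_stable[19], exp(-log(2) * 18 * t_cycle / 1.6),
               tolerance = 1e-3)
})

test_that("traces are deterministic and life-years ordered by stage and OS", {
  tr_a <- run_cohort_trace(default_p$stages$III, 2017, 50,
                           default_p$settings, default_p$life_table)
  tr_b <- run_cohort_trace(default_p$stages$III, 2017, 50,
                           default_p$settings, default_p$life_table)
  expect_identical(tr_a, tr_b)

  life_years <- function(st) {
    tr <- run_cohort_trace(st, 2017, 1, default_p$settings, default_p$life_table)
    sum(tr$frac_stable + tr$frac_postprog) * t_cycle
  }
  ly <- sapply(default_p$stages, life_years)
  expect_true(ly[["I"]] > ly[["II"]])
  expect_true(ly[["II"]] > ly[["III"]])
  expect_true(ly[["III"]] > ly[["IV"]])

  # raising median OS never reduces life-years
  st_hi <- default_p$stages$IV
  st_hi$median_os <- 3.0
  expect_gte(life_years(st_hi), ly[["IV"]])
})

test_that("incidence projection splits stages with conserved totals", {
  proj <- project_incidence(default_p)
  expect_equal(nrow(proj), 10)
  expect_equal(proj$year, 2017:2026)
  expect_equal(unlist(proj[1, c("I", "II", "III", "IV")], use.names = FALSE),
               c(1155, 195, 1116, 681))
  expect_equal(proj$eoc_incidence[1], 3147)
  expect_true(all(proj$eoc_incidence <= proj$oc_incidence))
  expect_true(all(rowSums(proj[, c("I", "II", "III", "IV")]) == proj$eoc_incidence))

  p2 <- default_p
  p2$projection$year1_oc <- 1000
  p2$projection$epithelial_fraction <- 1
  proj2 <- project_incidence(p2)
  expect_true(all(proj2$eoc_incidence == 1000))

  p3 <- default_p
  p3$projection$annual_increment <- 50
  proj3 <- project_incidence(p3)
  expect_true(all(diff(proj3$oc_incidence) == 50))
  expect_true(all(rowSums(proj3[, c("I", "II", "III", "IV")]) ==
                  proj3$eoc_incidence))
})

test_that("multi-cohort runs truncate at the calendar horizon", {
  p <- default_p
  traces <- run_multi_cohort(p)
  expect_length(traces, 40)
  expect_equal(nrow(traces[["I_2017"]]), 181)
  expect_equal(nrow(traces[["IV_2026"]]), 19)
  # conservation: total patient entries equal the projected incidence
  proj <- attr(traces, "projection")
  entries <- sum(sapply(traces, attr, "size"))
  expect_equal(entries, sum(proj$eoc_incidence))
  # deaths at truncation never exceed the closed-form OS bound plus
  # cumulative natural mortality
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    st <- p$stages[[attr(tr, "stage_label")]]
    elapsed <- (nrow(tr) - 1) * t_cycle
    os_bound <- 1 - exp(-log(2) * elapsed / st$median_os)
    nat_bound <- sum(attr(tr, "probs")$pdss)
    expect_lte(max(tr$frac_dead), os_bound + nat_bound + 1e-9)
  }
})

test_that("one-year horizon runs only the first-year cohorts", {
  p <- default_p
  p$settings$horizon_years <- 1
  traces <- run_multi_cohort(p)
  expect_length(traces, 4)
  expect_true(all(sapply(traces, nrow) == 19))
})
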