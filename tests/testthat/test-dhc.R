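test_that("dose formulas match hand-evaluated values", {
  # Du Bois BSA, checked against an independent log-space evaluation
  expect_equal(bsa_du_bois(159, 65), 1.67058052925945, tolerance = 1e-9)
  expect_equal(bsa_du_bois(159, 65),
               exp(log(0.007184) + 0.725 * log(159) + 0.425 * log(65)),
               tolerance = 1e-12)
  expect_equal(bsa_du_bois(100, 100), 1.43339644707364, tolerance = 1e-9)
  expect_error(bsa_du_bois(0, 65), "> 0")

  expect_equal(carboplatin_dose_calvert(6, 100), 750)
  expect_equal(carboplatin_dose_calvert(0, 123), 0)
  expect_equal(carboplatin_dose_calvert(5, 75), 500)
  expect_error(carboplatin_dose_calvert(-1, 100), ">= 0")
})

test_that("administration cost covers infusion plus preparation", {
  expect_equal(administration_cost(0), 9.60)
  expect_equal(administration_cost(180), 67.20)
  expect_error(administration_cost(-5), ">= 0")
})

test_that("vial solver picks the cheapest covering combination", {
  r <- vials_and_drug_cost(150, 100, 10)
  expect_equal(r$counts, 2L)
  expect_equal(r$cost, 20)
  r2 <- vials_and_drug_cost(150, c(100, 50), c(10, 6))
  expect_equal(r2$counts, c(1L, 1L))
  expect_equal(r2$cost, 16)
  r3 <- vials_and_drug_cost(100, 100, 10)
  expect_equal(r3$counts, 1L)
  expect_equal(r3$cost, 10)
  # a big vial can undercut exact small-vial coverage
  r4 <- vials_and_drug_cost(300, c(400, 100), c(25, 10))
  expect_equal(r4$cost, 25)
  expect_error(vials_and_drug_cost(100, numeric(0), numeric(0)), "vial")
})

test_that("vial solver agrees with exhaustive enumeration", {
  set.seed(42)
  sizes_pool <- c(20, 30, 50, 100, 150, 200, 400, 450, 500, 600)
  for (i in 1:250) {
    k <- sample(1:4, 1)
    mg <- sample(sizes_pool, k)
    price <- round(mg * runif(k, 0.05, 0.4) + runif(k, 0, 5), 2)
    dose <- runif(1, 1, 1500)
    got <- vials_and_drug_cost(dose, mg, price)
    expect_equal(got$cost, vial_oracle(dose, mg, price))
    expect_gte(sum(got$counts * mg), dose)
  }
})

test_that("chemo cycle cost composes dose, vials and administration", {
  p <- default_p
  settings <- p$settings
  row_flat <- list(drug_id = "x", dose_rule = "flat", dose_value = 100,
                   infusion_minutes = 0, vial_mg = "100", vial_price = "100",
                   deduction_rate = 0)
  # one exact vial at VAT-only public price plus preparation-only admin
  expect_equal(chemo_cycle_cost(row_flat, list(), settings), 104 + 9.60)
  row_kg <- list(drug_id = "beva", dose_rule = "per_kg", dose_value = 15,
                 infusion_minutes = 0, vial_mg = "990", vial_price = "0",
                 deduction_rate = 0)
  # 15 mg/kg at 66 kg = 990 mg: exactly one (free) vial, so only admin cost
  expect_equal(chemo_cycle_cost(row_kg, list(weight = 66), settings), 9.60)
  expect_error(chemo_cycle_cost(row_kg, list(), settings), "weight")
})

test_that("initial treatment cost weights the stage mixes", {
  p <- default_p
  st0 <- p$stages$I
  st0$treatment_mix <- c(none = 1, surgery_only = 0,
                         neoadjuvant_plus_surgery = 0, surgery_plus_adjuvant = 0)
  expect_equal(stage_treatment_cost(st0, p)$total, 0)

  # stage I: laparotomy + hysterectomy only, for every operated patient
  tc <- stage_treatment_cost(p$stages$I, p)
  bundle <- sum(unit_cost(p, c("laparotomy", "hysterectomy")))
  expect_equal(tc$surgery, (1 - p$stages$I$treatment_mix[["none"]]) * bundle)
  # stage I has no neoadjuvant pathway, so chemo comes from the adjuvant mix
  expect_gt(tc$chemo, 0)
  tc4 <- stage_treatment_cost(p$stages$IV, p)
  expect_gt(tc4$surgery, 0)
})

test_that("hospitalization and emergency costs scale the semiannual rates", {
  p <- default_p
  p$unit_costs$unit_cost[p$unit_costs$item_id == "hospital_stay"] <- 4000
  p$unit_costs$unit_cost[p$unit_costs$item_id == "er_visit"] <- 200
  p$unit_costs$source_year[p$unit_costs$item_id %in% c("hospital_stay", "er_visit")] <- 2016
  p$unit_costs$cpi_category[p$unit_costs$item_id %in% c("hospital_stay", "er_visit")] <- "none"
  he <- hospitalization_er_cost_per_cycle(p$stages$III, p)
  cycles_per_6mo <- (365.25 / 2) / 21
  expect_equal((he$hospitalization + he$emergency) * cycles_per_6mo, 4124.28)
  # stages I and II share identical printed rows
  he1 <- hospitalization_er_cost_per_cycle(p$stages$I, p)
  he2 <- hospitalization_er_cost_per_cycle(p$stages$II, p)
  expect_equal(he1, he2)
  st <- p$stages$III
  st$pct_hospitalized <- 0
  st$pct_er <- 0
  he0 <- hospitalization_er_cost_per_cycle(st, p)
  expect_equal(he0$hospitalization + he0$emergency, 0)
})

test_that("genetic cascade costs follow the referral chain", {
  p <- default_p
  p$unit_costs$unit_cost[p$unit_costs$item_id == "brca_test"] <- 200
  p$unit_costs$unit_cost[p$unit_costs$item_id == "genetic_counselling_visit"] <- 50
  idx <- p$unit_costs$item_id %in% c("brca_test", "genetic_counselling_visit")
  p$unit_costs$source_year[idx] <- 2016
  p$unit_costs$cpi_category[idx] <- "none"
  gc <- genetic_cascade_cost(1000, p)
  expect_equal(gc$patients, 0.20 * 1000 * (200 + 2 * 50))
  expect_equal(gc$n_relatives, 0.20 * 0.05 * 5 * 1000)
  p0 <- p
  p0$cascade$pct_tested <- 0
  gc0 <- genetic_cascade_cost(1000, p0)
  expect_equal(gc0$patients, 0)
  expect_equal(gc0$relatives, 0)
})

test_that("palliative pathway expectation weights each branch", {
  p <- default_p
  p$unit_costs$unit_cost <- rep(0, nrow(p$unit_costs))
  p$unit_costs$unit_cost_min <- p$unit_costs$unit_cost_max <- p$unit_costs$unit_cost
  expect_equal(palliative_cost_per_death(p), 0)
  # home-team branch alone: 6.7% x 9.5 visits x price
  p$unit_costs$unit_cost[p$unit_costs$item_id == "palliative_home_visit"] <- 80
  p$unit_costs$source_year[p$unit_costs$item_id == "palliative_home_visit"] <- 2016
  p$unit_costs$cpi_category[p$unit_costs$item_id == "palliative_home_visit"] <- "none"
  expect_equal(palliative_cost_per_death(p), 0.067 * 9.5 * 80)
  # sedation adds 14% of the drug cost
  p$unit_costs$unit_cost[p$unit_costs$item_id == "sedation_drugs"] <- 100
  p$unit_costs$source_year[p$unit_costs$item_id == "sedation_drugs"] <- 2016
  p$unit_costs$cpi_category[p$unit_costs$item_id == "sedation_drugs"] <- "none"
  expect_equal(palliative_cost_per_death(p), 0.067 * 9.5 * 80 + 0.14 * 100)
})

test_that("follow-up schedules convert annual counts to per-cycle euros", {
  p <- default_p
  p$followup_schedule <- p$followup_schedule[0, ]
  expect_equal(followup_cost_per_cycle("stable", p), 0)
  p2 <- default_p
  p2$followup_schedule <- data.frame(state = "stable", item_id = "oncology_visit",
                                     per_year = 4)
  visit <- unit_cost(p2, "oncology_visit")
  expect_equal(followup_cost_per_cycle("stable", p2), 4 * visit / 18)
  # defaults follow post-progression patients at least as intensively
  expect_gte(followup_cost_per_cycle("post_progression", default_p),
             followup_cost_per_cycle("stable", default_p))
})

test_that("all DHC streams are linear in unit prices", {
  p1 <- default_p
  tr <- run_cohort_trace(p1$stages$III, 2017, 100, p1$settings, p1$life_table,
                         n_cycles = 36)
  y1 <- cost_cohort(tr, p1, 1)
  p2 <- p1
  for (col in c("unit_cost_min", "unit_cost", "unit_cost_max"))
    p2$unit_costs[[col]] <- 2 * p2$unit_costs[[col]]
  p2$drug_catalogue$vial_price <- vapply(
    strsplit(p2$drug_catalogue$vial_price, ";"),
    function(v) paste(2 * as.numeric(v), collapse = ";"), character(1))
  p2$settings$admin_cost_per_min <- 2 * p2$settings$admin_cost_per_min
  y2 <- cost_cohort(tr, p2, 1)
  dhc_rows <- c("screening_patients", "genetic_relatives", "diagnosis",
                "followup", "surgery", "chemotherapy", "hospitalizations",
                "emergency", "palliative")
  expect_equal(y2[dhc_rows, ], 2 * y1[dhc_rows, ], tolerance = 1e-12)
  expect_true(all(y1 >= 0))
})
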