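# Synthetic input tables: placeholder unit costs, drug catalogue, life table
# and labour schedule. These stand in for the unpublished regional tariff and
# market tables the costing engine needs; values are documented plausible
# magnitudes, NOT real Spanish tariffs.

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate the synthetic unit-cost table
#'
#' Deterministically (per seed) builds a priced table of every resource item
#' the costing modules reference: visits, tests, surgical procedures,
#' hospital stays, emergency attendance and palliative-care items. Each row
#' carries a minimum / median / maximum price (emulating the spread across
#' regional tariffs), a source year and a CPI category used to update the
#' price to base-year euros. Values are synthetic placeholders drawn from
#' documented plausible ranges.
#'
#' @param seed integer seed
#' @return data.frame (`item_id`, `description`, `unit`, `unit_cost_min`,
#'   `unit_cost`, `unit_cost_max`, `source_year`, `cpi_category`)
#' @export
generate_unit_costs <- function(seed = 1L) {
  base <- data.frame(
    item_id = c("screening_test", "brca_test", "genetic_counselling_visit",
                "tvus", "ca125_test", "ovarian_biopsy", "biochemistry_panel",
                "vaginal_ultrasound", "ct_scan", "specialist_visit",
                "oncology_visit", "laparotomy", "omentectomy", "hysterectomy",
                "salpingo_oophorectomy", "lymphadenectomy", "hospital_stay",
                "er_visit", "palliative_home_visit", "nurse_visit",
                "primary_care_visit", "palliative_hospital_day",
                "sedation_drugs"),
    description = c("opportunistic screening work-up", "BRCA1/2 germline test",
                    "genetic counselling visit", "transvaginal ultrasound",
                    "CA125 tumour marker blood test", "ovarian biopsy",
                    "biochemical analysis panel", "vaginal ultrasonography",
                    "CT scan", "specialist outpatient visit",
                    "oncology follow-up visit", "laparotomy",
                    "omentectomy", "abdominal total hysterectomy",
                    "bilateral salpingo-oophorectomy", "lymphadenectomy",
                    "oncology hospitalization (per stay)",
                    "emergency department attendance",
                    "palliative home-care team visit", "nurse visit",
                    "primary-care doctor visit",
                    "palliative inpatient day", "terminal sedation drugs"),
    unit = c("per-test", "per-test", "per-visit", "per-test", "per-test",
             "per-procedure", "per-test", "per-test", "per-test", "per-visit",
             "per-visit", "per-procedure", "per-procedure", "per-procedure",
             "per-procedure", "per-procedure", "per-stay", "per-visit",
             "per-visit", "per-visit", "per-visit", "per-day", "per-patient"),
    median0 = c(150, 600, 90, 60, 25, 350, 30, 60, 130, 90,
                95, 4500, 1800, 3800, 2500, 2200, 4200, 180, 85, 40,
                50, 350, 110),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    n <- nrow(base)
    med <- base$median0 * stats::runif(n, 0.92, 1.08)
    lo <- med * stats::runif(n, 0.72, 0.88)
    hi <- med * stats::runif(n, 1.15, 1.40)
    yr <- sample(2012:2016, n, replace = TRUE)
    data.frame(
      item_id = base$item_id, description = base$description, unit = base$unit,
      unit_cost_min = round(lo, 2), unit_cost = round(med, 2),
      unit_cost_max = round(hi, 2), source_year = yr,
      # tariffs observed in the base year are treated as already actualised
      cpi_category = ifelse(yr == 2016, "none", "medicine"),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate the synthetic chemotherapy catalogue
#'
#' Deterministically builds the four regimen categories the model costs:
#' neoadjuvant (paclitaxel + carboplatin, 3 cycles before and 3 after
#' surgery), adjuvant (stable state, stages I-III), post-progression
#' (stages I-II) and advanced (post-progression at stage III, both states at
#' stage IV). Each category holds one or more regimens with a market share
#' (shares sum to 1 within the category); each regimen lists its drugs with
#' a dosing rule (`per_m2`, `auc_based`, `per_kg`, `flat`), infusion time and
#' vial options (`mg;mg` / `price;price` semicolon lists of list prices).
#' Prices are synthetic placeholders jittered per seed.
#'
#' @param seed integer seed
#' @return data.frame catalogue, one row per (category, regimen, drug)
#' @export
generate_drug_catalogue <- function(seed = 1L) {
  row <- function(category, regimen, share, drug, rule, dose, inf, mg, pr, cycles)
    data.frame(category = category, regimen_id = regimen, market_share = share,
               drug_id = drug, dose_rule = rule, dose_value = dose,
               infusion_minutes = inf, vial_mg = mg, vial_price = pr,
               deduction_rate = NA_real_, cycles = cycles,
               stringsAsFactors = FALSE)
  pac <- function(cat, reg, share, cyc)
    row(cat, reg, share, "paclitaxel", "per_m2", 175, 180,
        "30;100;300", "35;90;240", cyc)
  carb <- function(cat, reg, share, auc, cyc)
    row(cat, reg, share, "carboplatin", "auc_based", auc, 60,
        "50;150;450;600", "20;55;150;195", cyc)
  cat <- rbind(
    pac("neoadjuvant", "pac_carb", 1, 6),
    carb("neoadjuvant", "pac_carb", 1, 6, 6),
    pac("adjuvant", "pac_carb", 0.8, 6),
    carb("adjuvant", "pac_carb", 0.8, 6, 6),
    carb("adjuvant", "carb_mono", 0.2, 6, 6),
    pac("post_progression", "pac_carb", 0.4, 6),
    carb("post_progression", "pac_carb", 0.4, 5, 6),
    carb("post_progression", "carb_gem", 0.4, 5, 6),
    row("post_progression", "carb_gem", 0.4, "gemcitabine", "per_m2", 1000, 30,
        "200;1000;2000", "18;80;155", 6),
    row("post_progression", "topotecan", 0.2, "topotecan", "per_m2", 7.5, 30,
        "1;4", "95;330", 6),
    # advanced disease is treated in successive lines essentially while the
    # patient occupies an eligible state: cycles NA = no duration cap
    pac("advanced", "carb_pac_beva", 0.35, NA),
    carb("advanced", "carb_pac_beva", 0.35, 6, NA),
    row("advanced", "carb_pac_beva", 0.35, "bevacizumab", "per_kg", 15, 60,
        "100;400", "310;1180", NA),
    carb("advanced", "carb_pld", 0.25, 5, NA),
    row("advanced", "carb_pld", 0.25, "doxorubicin_liposomal", "per_m2", 40, 60,
        "20;50", "420;900", NA),
    row("advanced", "cis_gem", 0.15, "cisplatin", "per_m2", 75, 120,
        "10;50;100", "6;22;40", NA),
    row("advanced", "cis_gem", 0.15, "gemcitabine", "per_m2", 1250, 30,
        "200;1000;2000", "18;80;155", NA),
    row("advanced", "trabectedin_pld", 0.10, "trabectedin", "per_m2", 1.1, 180,
        "0.25;1", "540;1990", NA),
    row("advanced", "trabectedin_pld", 0.10, "doxorubicin_liposomal", "per_m2",
        30, 60, "20;50", "420;900", NA),
    row("advanced", "docetaxel", 0.15, "docetaxel", "per_m2", 75, 60,
        "20;80", "150;480", NA)
  )
  with_seed(seed + 1L, {
    cat$vial_price <- vapply(split_numeric(cat$vial_price), function(v) {
      paste(round(v * stats::runif(1, 0.94, 1.06), 2), collapse = ";")
    }, character(1))
    cat
  })
}

#' Generate a parametric (Gompertz) female life table
#'
#' Annual all-cause mortality rates `r(age) = a * exp(b * age)` on integer
#' ages 0-100, standing in for the general female population life table. The
#' defaults give rates of about 0.0035 at age 57 and 0.012 at age 70,
#' matching the order of magnitude of a modern southern-European female
#' population. Lookups beyond age 100 clamp to the last rate.
#'
#' @param a Gompertz level parameter (>= 0; 0 gives an immortal test table)
#' @param b Gompertz slope parameter (> 0)
#' @return data.frame (`age`, `annual_mortality_rate`)
#' @export
generate_life_table <- function(a = 1.55e-5, b = 0.095) {
  if (is.na(a) || is.na(b) || a < 0 || b <= 0)
    stop("Gompertz parameters must be a >= 0, b > 0", call. = FALSE)
  age <- 0:100
  data.frame(age = age, annual_mortality_rate = a * exp(b * age))
}

#' Generate the synthetic labour schedule
#'
#' Deterministic (per seed) female employment rates and gross annual wages by
#' age, with employment 0 at and beyond the retirement age of 65. Used by
#' the human-capital productivity-loss calculations.
#'
#' @param seed integer seed
#' @param retirement_age age from which employment is 0
#' @return data.frame (`age`, `employment_rate`, `annual_wage`)
#' @export
generate_labour_schedule <- function(seed = 1L, retirement_age = 65) {
  age <- 16:100
  emp <- ifelse(age < 20, 0.15,
         ifelse(age < 25, 0.45,
         ifelse(age < 55, 0.72,
         ifelse(age < 60, 0.58,
         ifelse(age < retirement_age, 0.35, 0)))))
  wage <- ifelse(age < 25, 14000,
          ifelse(age < 35, 20000,
          ifelse(age < 45, 25000,
          ifelse(age < 55, 28000,
          ifelse(age < retirement_age, 26000, 0)))))
  with_seed(seed + 2L, {
    jitter <- stats::runif(length(age), 0.97, 1.03)
    data.frame(age = age,
               employment_rate = pmin(1, emp * jitter),
               annual_wage = round(wage * jitter, 2))
  })
}

#' Printed stage-by-category results fixture
#'
#' Returns the published stage x cost-category results table verbatim (totals
#' in euros, within-stage percentages and average annual cost per patient),
#' with one printed thousands-separator anomaly normalized (the stage IV
#' hospitalizations cell). Used exclusively to verify the aggregation layer;
#' never fed back into the model.
#'
#' @return data.frame with item and subtotal rows, one column triple
#'   (`total_*`, `pct_*`, `avg_*`) per stage
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_printed.csv", package = "eocburden",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assemble the full synthetic fixture bundle
#'
#' @param seed integer seed governing all generators
#' @return list with the stage-parameter and printed-results fixtures, the
#'   synthetic unit-cost table, drug catalogue, life table, labour schedule,
#'   and the generation seed
#' @export
fixture_bundle <- function(seed = 1L) {
  list(table1 = default_stage_parameters(),
       table2 = table2_fixture(),
       unit_costs = generate_unit_costs(seed),
       drug_catalogue = generate_drug_catalogue(seed),
       life_table = generate_life_table(),
       labour = generate_labour_schedule(seed),
       seed = as.integer(seed))
}

#' Write the synthetic tables as CSV files
#'
#' Each file carries a provenance header (generator version and seed) marking
#' it as a synthetic placeholder.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed
#' @return invisible character vector of paths written
#' @export
write_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- fixture_bundle(seed)
  tabs <- list(unit_costs = b$unit_costs, drug_catalogue = b$drug_catalogue,
               life_table = b$life_table, labour_schedule = b$labour)
  paths <- character(0)
  for (nm in names(tabs)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# synthetic placeholder table (%s); generator eocburden %s, seed %d",
                       nm, as.character(utils::packageVersion("eocburden")), b$seed), con)
    utils::write.csv(tabs[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
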