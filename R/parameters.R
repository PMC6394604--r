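#' Stage-level epidemiology and treatment parameters
#'
#' Returns the packaged stage-level parameter table for epithelial ovarian
#' cancer (EOC) by FIGO stage: incidence split, median progression-free and
#' overall survival (years, exponential parameterization), mean age at
#' diagnosis, anthropometry, semiannual hospitalization/emergency rates, and
#' the initial treatment and surgery mixes.
#'
#' The treatment mix of stage III sums to 99.9% as printed in its source
#' table; the loader renormalizes mixes whose sum is within 0.5% of 1.
#'
#' @return named list (one element per stage `"I".."IV"`) of stage parameter
#'   lists with fields `stage_label`, `incidence_count`, `incidence_share`,
#'   `median_pfs`, `median_os`, `mean_age_dx`, `mean_weight`, `mean_height`,
#'   `hosp_per_6mo`, `pct_hospitalized`, `er_per_6mo`, `pct_er`,
#'   `treatment_mix`, `surgery_mix`
#' @export
default_stage_parameters <- function() {
  path <- system.file("extdata", "stage_parameters.csv", package = "eocburden",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- as.list(tab[i, ])
    mix <- c(none = r$mix_none, surgery_only = r$mix_surgery,
             neoadjuvant_plus_surgery = r$mix_neoadjuvant,
             surgery_plus_adjuvant = r$mix_adjuvant)
    smix <- c(laparotomy = r$surg_laparotomy, omentectomy = r$surg_omentectomy,
              hysterectomy = r$surg_hysterectomy,
              salpingo_oophorectomy = r$surg_salpingo,
              lymphadenectomy = r$surg_lymphadenectomy)
    s <- sum(mix)
    if (abs(s - 1) > 0.005)
      stop_field(paste0("stages$", r$stage, "$treatment_mix"),
                 "does not sum to 1")
    mix <- mix / s
    list(stage_label = r$stage,
         incidence_count = r$incidence_count,
         incidence_share = r$incidence_share,
         median_pfs = r$median_pfs, median_os = r$median_os,
         mean_age_dx = r$mean_age_dx,
         mean_weight = r$mean_weight, mean_height = r$mean_height,
         hosp_per_6mo = r$hosp_per_6mo, pct_hospitalized = r$pct_hospitalized,
         er_per_6mo = r$er_per_6mo, pct_er = r$pct_er,
         treatment_mix = mix, surgery_mix = smix)
  })
  names(out) <- tab$stage
  out
}

#' Economic settings defaults
#'
#' Base-year 2016 euros; 3% annual discount rate; medicine CPI 0.77%/yr and
#' general CPI 1.97%/yr for updating historical unit costs; 1% annual labour
#' productivity growth; 4% VAT on drugs with a 7.5% statutory deduction on
#' list prices; 21-day model cycles over a 10-year horizon (18 cycles per
#' reporting year); retirement at 65.
#'
#' @return named list of settings
#' @export
default_economic_settings <- function() {
  list(
    discount_rate_annual = 0.03,
    medicine_cpi = 0.0077,
    general_cpi = 0.0197,
    productivity_growth = 0.01,
    vat_drugs = 0.04,
    drug_deduction_rate = 0.075,
    base_year = 2016,
    horizon_years = 10,
    cycle_days = 21,
    retirement_age = 65,
    admin_cost_per_min = 0.32,
    admin_prep_minutes = 30,
    gfr_ml_min = 100,
    half_cycle_correction = FALSE,
    informal_care_window = "post_progression",
    discount_premature_mortality = TRUE,
    temp_leave_days_over = 70,
    unit_cost_column = "unit_cost",
    drug_price_factor = 1,
    weight_factor = 1,
    age_factor = 1,
    informal_hours_factor = 1
  )
}

cycle_years <- function(settings) settings$cycle_days / 365.25

cycles_per_year <- function(settings) as.integer(ceiling(365.25 / settings$cycle_days))

#' Build the fully-resolved default parameter set
#'
#' Assembles stage parameters, economic settings, the incidence projection
#' spec, care/palliative/genetic-cascade assumptions and the synthetic input
#' tables (unit costs, drug catalogue, life table, labour schedule) into one
#' model-parameter object.
#'
#' @param seed integer seed driving the synthetic table generators
#' @return object of class `eoc_params`
#' @export
default_parameters <- function(seed = 1L) {
  seed <- as.integer(seed)
  p <- list(
    stages = default_stage_parameters(),
    settings = default_economic_settings(),
    projection = list(
      year1_oc = 3497, annual_increment = 0, epithelial_fraction = 0.90,
      stage_counts_year1 = c(I = 1155, II = 195, III = 1116, IV = 681),
      integer_counts = TRUE
    ),
    care = list(pct_private = 0.174, pct_public = 0.095, pct_informal = 0.934,
                hours_public = 1.5, hours_private = 8, hours_informal = 10.3,
                wage_per_hour = 13.56, formal_care_days = 48),
    cascade = list(pct_tested = 0.20, counselling_visits = 2,
                   pct_positive = 0.05, relatives_per_positive = 5,
                   surveillance_per_year = 2, surveillance_years = 10),
    palliative = list(duration_days = 48, pct_outpatient = 0.933,
                      pct_home_team = 0.067, home_visits = 9.5,
                      outpatient_nurse_visits = 7, primary_care_visits = 4,
                      pct_terminal_home = 0.596, pct_terminal_hospital = 0.404,
                      terminal_home_days = 3, terminal_hospital_days = 3,
                      nurse_visits_per_day = 2, pct_sedation = 0.14),
    leave = list(pct_losing_60 = 0.30, days_60 = 60,
                 pct_losing_70 = 0.70),
    followup_schedule = default_followup_schedule(),
    diagnosis_items = default_diagnosis_items(),
    unit_costs = generate_unit_costs(seed),
    drug_catalogue = generate_drug_catalogue(seed),
    life_table = generate_life_table(),
    labour = generate_labour_schedule(seed),
    seed = seed
  )
  class(p) <- "eoc_params"
  validate_parameters(p)
}

#' Follow-up visit/test schedule defaults
#'
#' Annual counts of follow-up resources by health state. Stable patients are
#' followed less intensively than post-progression patients; both schedules
#' are editable (column `per_year`).
#'
#' @return data.frame with columns `state`, `item_id`, `per_year`
#' @export
default_followup_schedule <- function() {
  data.frame(
    state = c(rep("stable", 4), rep("post_progression", 3)),
    item_id = c("oncology_visit", "ca125_test", "tvus", "ct_scan",
                "oncology_visit", "ca125_test", "ct_scan"),
    per_year = c(4, 4, 2, 1, 8, 8, 2),
    stringsAsFactors = FALSE
  )
}

# diagnostic work-up bundle charged once per incident patient
default_diagnosis_items <- function() {
  data.frame(
    item_id = c("ovarian_biopsy", "biochemistry_panel", "vaginal_ultrasound",
                "ct_scan", "specialist_visit", "ca125_test"),
    count = c(1, 1, 1, 1, 2, 1),
    stringsAsFactors = FALSE
  )
}

#' Validate a model-parameter object
#'
#' Enforces every structural invariant: per-stage `median_os > median_pfs > 0`,
#' fractions in \code{[0,1]}, treatment mixes on the simplex, non-negative
#' rates and prices, contiguous life-table ages, unique unit-cost ids and
#' per-category drug market shares summing to 1.
#'
#' @param p `eoc_params` object
#' @return the object, invisibly unchanged, or an error naming the field
#' @export
validate_parameters <- function(p) {
  for (sl in stage_labels()) {
    st <- p$stages[[sl]]
    if (is.null(st)) stop_field(paste0("stages$", sl), "missing stage")
    pre <- paste0("stages$", sl, "$")
    check_positive(st$median_pfs, paste0(pre, "median_pfs"))
    check_positive(st$median_os, paste0(pre, "median_os"))
    if (st$median_os <= st$median_pfs)
      stop_field(paste0(pre, "median_os"), "must exceed median_pfs")
    check_nonneg(st$incidence_count, paste0(pre, "incidence_count"))
    check_fraction(st$incidence_share, paste0(pre, "incidence_share"))
    check_fraction(st$pct_hospitalized, paste0(pre, "pct_hospitalized"))
    check_fraction(st$pct_er, paste0(pre, "pct_er"))
    check_nonneg(st$hosp_per_6mo, paste0(pre, "hosp_per_6mo"))
    check_nonneg(st$er_per_6mo, paste0(pre, "er_per_6mo"))
    check_positive(st$mean_age_dx, paste0(pre, "mean_age_dx"))
    check_positive(st$mean_weight, paste0(pre, "mean_weight"))
    check_positive(st$mean_height, paste0(pre, "mean_height"))
    check_fraction(st$treatment_mix, paste0(pre, "treatment_mix"))
    if (abs(sum(st$treatment_mix) - 1) > 1e-9)
      stop_field(paste0(pre, "treatment_mix"), "must sum to 1")
    check_fraction(st$surgery_mix, paste0(pre, "surgery_mix"))
  }
  s <- p$settings
  for (f in c("discount_rate_annual", "medicine_cpi", "general_cpi",
              "productivity_growth", "vat_drugs", "drug_deduction_rate"))
    check_nonneg(s[[f]], paste0("settings$", f))
  check_positive(s$horizon_years, "settings$horizon_years")
  check_positive(s$cycle_days, "settings$cycle_days")
  if (!s$informal_care_window %in% c("post_progression", "last_48_days"))
    stop_field("settings$informal_care_window", "unknown window")
  lt <- p$life_table
  if (any(diff(lt$age) != 1)) stop_field("life_table$age", "ages must be contiguous")
  check_nonneg(lt$annual_mortality_rate, "life_table$annual_mortality_rate")
  uc <- p$unit_costs
  if (anyDuplicated(uc$item_id)) stop_field("unit_costs$item_id", "ids must be unique")
  check_nonneg(uc$unit_cost, "unit_costs$unit_cost")
  if (!all(uc$cpi_category %in% c("medicine", "general", "none")))
    stop_field("unit_costs$cpi_category", "must be medicine/general/none")
  cat_shares <- tapply(
    p$drug_catalogue$market_share[!duplicated(p$drug_catalogue[c("category", "regimen_id")])],
    p$drug_catalogue$category[!duplicated(p$drug_catalogue[c("category", "regimen_id")])],
    sum)
  if (any(abs(cat_shares - 1) > 1e-9))
    stop_field("drug_catalogue$market_share",
               "regimen market shares must sum to 1 within each category")
  check_fraction(p$care$pct_private, "care$pct_private")
  check_fraction(p$care$pct_public, "care$pct_public")
  check_fraction(p$care$pct_informal, "care$pct_informal")
  check_nonneg(p$labour$annual_wage, "labour$annual_wage")
  check_fraction(p$labour$employment_rate, "labour$employment_rate")
  pl <- p$palliative
  if (abs(pl$pct_outpatient + pl$pct_home_team - 1) > 1e-9)
    stop_field("palliative$pct_outpatient", "branches must sum to 1")
  if (abs(pl$pct_terminal_home + pl$pct_terminal_hospital - 1) > 1e-9)
    stop_field("palliative$pct_terminal_home", "terminal split must sum to 1")
  invisible(p)
}

#' Load model parameters from a config file
#'
#' Reads a JSON or YAML config (selected by file extension), overlays it on
#' the package defaults, optionally swaps in user CSV tables
#' (`unit_costs_csv`, `drug_catalogue_csv`, `life_table_csv`, `labour_csv`)
#' and validates the result. An empty or missing config yields the full
#' default parameter set.
#'
#' @param config_path path to a `.json`/`.yaml`/`.yml` file, or `NULL` for
#'   all defaults
#' @param seed synthetic-table seed used where the config is silent
#' @return validated `eoc_params` object
#' @export
load_parameters <- function(config_path = NULL, seed = 1L) {
  cfg <- list()
  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop("config file not found: ", config_path, call. = FALSE)
    ext <- tolower(tools::file_ext(config_path))
    cfg <- switch(ext,
      json = jsonlite::fromJSON(config_path, simplifyVector = TRUE),
      yaml = , yml = yaml::read_yaml(config_path),
      stop("unsupported config extension: ", ext, call. = FALSE))
    if (is.null(cfg)) cfg <- list()
  }
  seed <- as.integer(cfg$seed %||% seed)
  p <- default_parameters(seed)
  for (key in c("settings", "projection", "care", "cascade", "palliative", "leave"))
    p[[key]] <- merge_config(p[[key]], cfg[[key]])
  if (!is.null(cfg$projection$stage_counts_year1))
    p$projection$stage_counts_year1 <-
      stats::setNames(as.numeric(cfg$projection$stage_counts_year1), stage_labels())
  if (!is.null(cfg$stages)) {
    for (sl in names(cfg$stages)) {
      if (!sl %in% stage_labels())
        stop_field(paste0("stages$", sl), "unknown stage label")
      ov <- cfg$stages[[sl]]
      for (f in names(ov)) {
        if (f %in% c("treatment_mix", "surgery_mix"))
          p$stages[[sl]][[f]][names(ov[[f]])] <- unlist(ov[[f]])
        else p$stages[[sl]][[f]] <- ov[[f]]
      }
    }
  }
  for (tab in c("unit_costs", "drug_catalogue", "life_table", "labour")) {
    key <- paste0(tab, "_csv")
    if (!is.null(cfg[[key]]))
      p[[tab]] <- utils::read.csv(cfg[[key]], stringsAsFactors = FALSE)
  }
  p$seed <- seed
  validate_parameters(p)
}

#' Serialize / reload model parameters
#'
#' `save_parameters()` writes the complete parameter object to a single JSON
#' file at full numeric precision; `read_parameters()` restores it. The
#' round trip is value-identical.
#'
#' @param p `eoc_params` object
#' @param path JSON file path
#' @return `read_parameters()` returns the restored `eoc_params`
#' @export
save_parameters <- function(p, path) {
  x <- unclass(p)
  # I(17) significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_parameters
#' @export
read_parameters <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (tab in c("followup_schedule", "diagnosis_items", "unit_costs",
                "drug_catalogue", "life_table", "labour"))
    x[[tab]] <- as.data.frame(x[[tab]], stringsAsFactors = FALSE)
  x$drug_catalogue$deduction_rate <- as.numeric(x$drug_catalogue$deduction_rate)
  mix_names <- c("none", "surgery_only", "neoadjuvant_plus_surgery",
                 "surgery_plus_adjuvant")
  surg_names <- c("laparotomy", "omentectomy", "hysterectomy",
                  "salpingo_oophorectomy", "lymphadenectomy")
  for (sl in names(x$stages)) {
    x$stages[[sl]]$treatment_mix <-
      stats::setNames(unlist(x$stages[[sl]]$treatment_mix), mix_names)
    x$stages[[sl]]$surgery_mix <-
      stats::setNames(unlist(x$stages[[sl]]$surgery_mix), surg_names)
  }
  x$projection$stage_counts_year1 <-
    stats::setNames(unlist(x$projection$stage_counts_year1), stage_labels())
  class(x) <- "eoc_params"
  validate_parameters(x)
}

#' Update a historical cost to base-year (2016) euros
#'
#' Compounds the category CPI over the elapsed years:
#' `amount * (1 + rate)^(2016 - source_year)`, with the medicine CPI for
#' healthcare tariffs, the general CPI for non-healthcare costs, and no
#' change for items already expressed in 2016 euros (`category = "none"`).
#'
#' @param amount euros in `source_year`
#' @param source_year year the cost was observed (must not exceed base year)
#' @param cpi_category one of `"medicine"`, `"general"`, `"none"`
#' @param settings economic settings list (rates and base year)
#' @return euros in base-year terms
#' @export
inflate_to_base_year <- function(amount, source_year, cpi_category,
                                 settings = default_economic_settings()) {
  check_nonneg(amount, "amount")
  if (any(source_year > settings$base_year))
    stop("source_year must not exceed the base year", call. = FALSE)
  rate <- switch(cpi_category,
    medicine = settings$medicine_cpi,
    general = settings$general_cpi,
    none = 0,
    stop("unknown cpi_category: ", cpi_category, call. = FALSE))
  amount * (1 + rate)^(settings$base_year - source_year)
}

#' Public price of a drug from its list price
#'
#' Applies the statutory deduction on the list price and then drug VAT:
#' `list_price * (1 - deduction_rate) * (1 + vat)`.
#'
#' @param list_price manufacturer list price (euros)
#' @param deduction_rate statutory deduction fraction (default 7.5%)
#' @param vat value-added tax fraction on drugs (default 4%)
#' @return public price in euros
#' @export
drug_public_price <- function(list_price, deduction_rate = 0.075, vat = 0.04) {
  check_nonneg(list_price, "list_price")
  if (any(deduction_rate < 0) || any(deduction_rate >= 1))
    stop_field("deduction_rate", "must be in [0, 1)")
  if (any(vat < 0) || any(vat >= 1)) stop_field("vat", "must be in [0, 1)")
  list_price * (1 - deduction_rate) * (1 + vat)
}

# unit-cost lookup in 2016 euros; column selects the median or the
# min/max Autonomous-Community price (one sensitivity scenario)
unit_cost <- function(p, item_id, column = NULL) {
  column <- column %||% p$settings$unit_cost_column
  uc <- p$unit_costs
  i <- match(item_id, uc$item_id)
  if (anyNA(i)) stop("unknown unit-cost item(s): ",
                     paste(item_id[is.na(i)], collapse = ", "), call. = FALSE)
  vapply(seq_along(i), function(k) {
    inflate_to_base_year(uc[[column]][i[k]], uc$source_year[i[k]],
                         uc$cpi_category[i[k]], p$settings)
  }, numeric(1))
}
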