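# One-way deterministic sensitivity analysis: named scenarios perturb a
# single registered parameter (one or two bounds) and the full model is
# re-run; outputs feed a tornado diagram.

# registry of perturbable parameters; each setter returns a modified copy
set_scenario_target <- function(p, target, value) {
  switch(target,
    pct_tested = { p$cascade$pct_tested <- value },
    weight_factor = { p$settings$weight_factor <- value },
    productivity_growth = { p$settings$productivity_growth <- value },
    drug_price_factor = { p$settings$drug_price_factor <- value },
    drug_deduction_rate = { p$settings$drug_deduction_rate <- value },
    unit_cost_column = { p$settings$unit_cost_column <- value },
    age_factor = { p$settings$age_factor <- value },
    bevacizumab_dose = {
      p$drug_catalogue$dose_value[p$drug_catalogue$drug_id == "bevacizumab"] <- value
    },
    wage_per_hour = { p$care$wage_per_hour <- value },
    informal_hours_factor = { p$settings$informal_hours_factor <- value },
    # alias: sweep the model discount rate instead of the drug deduction
    discount_rate_annual = { p$settings$discount_rate_annual <- value },
    stop("unknown scenario parameter: ", target, call. = FALSE)
  )
  p
}

#' Apply one scenario side to a parameter set
#'
#' Returns an independent copy of the parameters with only the scenario's
#' target changed; the base object is never mutated. A `NULL` side value
#' means "base case" (one-sided scenarios).
#'
#' @param p `eoc_params` object
#' @param scenario scenario spec: list with `name`, `target`, `low`, `high`
#' @param side `"low"` or `"high"`
#' @return perturbed `eoc_params` (validated)
#' @export
apply_scenario <- function(p, scenario, side = c("low", "high")) {
  side <- match.arg(side)
  value <- scenario[[side]]
  if (is.null(value)) return(p)
  validate_parameters(set_scenario_target(p, scenario$target, value))
}

#' The ten default one-way scenarios
#'
#' Genetic-counselling referral 35-70%, patient weight +/-10%, productivity
#' growth 0-2%, manufacturer drug price -10%, drug deduction rate 0-6%,
#' test/visit prices at the regional minimum and maximum, age at diagnosis
#' +/-10%, bevacizumab at 7.5 mg/kg, caregiver wage 7.5 euros/h, and
#' informal-care hours +/-30%. One-sided scenarios have a `NULL` side
#' (evaluated at base).
#'
#' @return named list of 10 scenario specs
#' @export
default_scenario_suite <- function() {
  sc <- function(name, target, low, high)
    list(name = name, target = target, low = low, high = high)
  list(
    genetic_counselling = sc("genetic_counselling", "pct_tested", 0.35, 0.70),
    patient_weight = sc("patient_weight", "weight_factor", 0.9, 1.1),
    productivity_growth = sc("productivity_growth", "productivity_growth", 0, 0.02),
    drug_price = sc("drug_price", "drug_price_factor", 0.9, NULL),
    drug_deduction_rate = sc("drug_deduction_rate", "drug_deduction_rate", 0, 0.06),
    test_visit_prices = sc("test_visit_prices", "unit_cost_column",
                           "unit_cost_min", "unit_cost_max"),
    age_at_diagnosis = sc("age_at_diagnosis", "age_factor", 0.9, 1.1),
    bevacizumab_dose = sc("bevacizumab_dose", "bevacizumab_dose", 7.5, NULL),
    caregiver_wage = sc("caregiver_wage", "wage_per_hour", 7.5, NULL),
    informal_care_hours = sc("informal_care_hours", "informal_hours_factor",
                             0.7, 1.3)
  )
}

#' Run the one-way sensitivity suite (tornado dataset)
#'
#' Re-runs the full model at each scenario bound and reports the 10-year
#' total burden and the overall average annual cost per patient; rows are
#' sorted by total-burden range width (widest first, alphabetical
#' tie-break). Base-case values are attached as attributes `base_total` and
#' `base_avg`.
#'
#' @param p `eoc_params` object
#' @param suite list of scenario specs (default: the ten standard scenarios)
#' @return data.frame (`scenario`, `low_total`, `high_total`, `low_avg`,
#'   `high_avg`, `range_total`)
#' @export
run_tornado <- function(p, suite = default_scenario_suite()) {
  if (length(suite) == 0) stop("scenario suite is empty", call. = FALSE)
  base <- run_burden_model(p)
  base_total <- base$breakdown$grand_total
  base_avg <- base$breakdown$overall_avg_per_patient
  rows <- lapply(suite, function(scn) {
    eval_side <- function(side) {
      if (is.null(scn[[side]])) return(c(base_total, base_avg))
      r <- run_burden_model(apply_scenario(p, scn, side))
      c(r$breakdown$grand_total, r$breakdown$overall_avg_per_patient)
    }
    lo <- eval_side("low"); hi <- eval_side("high")
    data.frame(scenario = scn$name, low_total = lo[1], high_total = hi[1],
               low_avg = lo[2], high_avg = hi[2],
               range_total = abs(hi[1] - lo[1]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range_total, out$scenario), ]
  rownames(out) <- NULL
  attr(out, "base_total") <- base_total
  attr(out, "base_avg") <- base_avg
  out
}
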