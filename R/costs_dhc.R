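# Direct healthcare costing: dose formulas, vial optimization,
# administration, treatment/surgery mixes, hospitalizations, the genetic
# counselling cascade, follow-up schedules and the palliative pathway.

#' Body surface area (Du Bois)
#'
#' `BSA = 0.007184 * height^0.725 * weight^0.425` (height in cm, weight in
#' kg), used for per-square-metre chemotherapy dosing.
#'
#' @param height_cm height in cm (> 0)
#' @param weight_kg weight in kg (> 0)
#' @return body surface area in m^2
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be > 0", call. = FALSE)
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Carboplatin dose (Calvert)
#'
#' `dose (mg) = target AUC * (GFR + 25)`.
#'
#' @param target_auc target area under the concentration curve (mg/mL*min)
#' @param gfr_ml_min glomerular filtration rate (mL/min)
#' @return dose in mg
#' @export
carboplatin_dose_calvert <- function(target_auc, gfr_ml_min) {
  if (any(target_auc < 0) || any(gfr_ml_min < 0))
    stop("inputs must be >= 0", call. = FALSE)
  target_auc * (gfr_ml_min + 25)
}

#' Cheapest whole-vial combination covering a dose
#'
#' Vials are not shared between patients, so each administration must be
#' covered by whole vials. Finds the minimum-cost combination (exhaustive
#' search with cost pruning over the small per-drug option sets); ties on
#' cost are broken by fewest vials.
#'
#' @param dose_mg required dose in mg (> 0)
#' @param vial_mg vector of vial sizes in mg
#' @param vial_price vector of vial prices in euros (same length)
#' @return list with `counts` (vials per option) and `cost` (euros)
#' @export
vials_and_drug_cost <- function(dose_mg, vial_mg, vial_price) {
  if (length(vial_mg) == 0) stop("at least one vial option required", call. = FALSE)
  if (length(vial_mg) != length(vial_price))
    stop("vial_mg and vial_price must have the same length", call. = FALSE)
  if (dose_mg <= 0) stop("dose must be > 0", call. = FALSE)
  ord <- order(vial_mg, decreasing = TRUE)
  mg <- vial_mg[ord]; pr <- vial_price[ord]
  n <- length(mg)
  best_cost <- Inf; best_n <- Inf; best_counts <- rep(0L, n)
  counts <- integer(n)
  recurse <- function(i, remaining, cost) {
    if (cost > best_cost || (cost == best_cost && sum(counts[seq_len(i - 1)]) >= best_n))
      return(invisible(NULL))
    if (remaining <= 0) {
      nv <- sum(counts)
      if (cost < best_cost || (cost == best_cost && nv < best_n)) {
        best_cost <<- cost; best_n <<- nv; best_counts <<- counts
      }
      return(invisible(NULL))
    }
    if (i > n) return(invisible(NULL))
    cmax <- ceiling(remaining / mg[i])
    for (k in cmax:0) {
      counts[i] <<- k
      recurse(i + 1, remaining - k * mg[i], cost + k * pr[i])
    }
    counts[i] <<- 0L
  }
  recurse(1, dose_mg, 0)
  out <- integer(length(vial_mg))
  out[ord] <- best_counts
  list(counts = out, cost = best_cost)
}

#' Intravenous administration cost
#'
#' Day-hospital time priced per minute over the infusion plus a fixed
#' 30-minute preparation.
#'
#' @param infusion_minutes infusion duration (>= 0)
#' @param rate_per_min euros per minute (default 0.32)
#' @param prep_minutes preparation time in minutes (default 30)
#' @return euros per administration
#' @export
administration_cost <- function(infusion_minutes, rate_per_min = 0.32,
                                prep_minutes = 30) {
  if (any(infusion_minutes < 0)) stop("minutes must be >= 0", call. = FALSE)
  rate_per_min * (infusion_minutes + prep_minutes)
}

# dose in mg for one catalogue row given patient anthropometry
component_dose <- function(row, patient) {
  switch(row$dose_rule,
    per_m2 = row$dose_value * bsa_du_bois(patient$height, patient$weight),
    auc_based = carboplatin_dose_calvert(row$dose_value, patient$gfr),
    per_kg = row$dose_value * patient$weight,
    flat = row$dose_value,
    stop("unknown dose rule: ", row$dose_rule, call. = FALSE))
}

#' Cost of administering one catalogue drug for one cycle
#'
#' Computes the dose from the drug's rule (BSA-based, Calvert AUC,
#' weight-based or flat), prices it through the cheapest whole-vial
#' combination at public prices (list price, statutory deduction, drug VAT),
#' and adds the administration cost.
#'
#' @param row one drug row of the catalogue (list or single-row data.frame)
#' @param patient list with `weight` (kg), `height` (cm), `gfr` (mL/min)
#' @param settings economic settings (deduction, VAT, administration rate,
#'   drug price factor)
#' @return euros for one administration
#' @export
chemo_cycle_cost <- function(row, patient, settings = default_economic_settings()) {
  row <- as.list(row)
  if (row$dose_rule %in% c("per_m2") &&
      (is.null(patient$height) || is.null(patient$weight)))
    stop("per_m2 dosing requires height and weight", call. = FALSE)
  if (row$dose_rule == "per_kg" && is.null(patient$weight))
    stop("per_kg dosing requires weight", call. = FALSE)
  dose <- component_dose(row, patient)
  mg <- split_numeric(row$vial_mg)[[1]]
  lp <- split_numeric(row$vial_price)[[1]] * settings$drug_price_factor
  ded <- if (!is.na(row$deduction_rate)) row$deduction_rate else settings$drug_deduction_rate
  eff <- drug_public_price(lp, ded, settings$vat_drugs)
  vials_and_drug_cost(dose, mg, eff)$cost +
    administration_cost(row$infusion_minutes, settings$admin_cost_per_min,
                        settings$admin_prep_minutes)
}

# market-share-weighted cost of one cycle of a chemotherapy category for a
# stage's mean patient; also returns the category cycle count
category_cycle_cost <- function(p, category, stage) {
  rows <- p$drug_catalogue[p$drug_catalogue$category == category, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown chemotherapy category: ", category, call. = FALSE)
  patient <- list(weight = stage$mean_weight * p$settings$weight_factor,
                  height = stage$mean_height,
                  gfr = p$settings$gfr_ml_min)
  cost <- 0
  for (reg in unique(rows$regimen_id)) {
    rr <- rows[rows$regimen_id == reg, , drop = FALSE]
    reg_cost <- sum(vapply(seq_len(nrow(rr)), function(i)
      chemo_cycle_cost(rr[i, ], patient, p$settings), numeric(1)))
    cost <- cost + rr$market_share[1] * reg_cost
  }
  list(per_cycle = cost, cycles = rows$cycles[1])
}

#' Expected initial-treatment cost per patient for a stage
#'
#' Expectation over the stage's treatment mix: the surgical bundle (sum of
#' procedure costs weighted by the per-procedure probabilities) for every
#' operated patient, 3 + 3 cycles of the neoadjuvant regimen for the
#' neoadjuvant-plus-surgery pathway, and the adjuvant regimen (stages I-III)
#' for the surgery-plus-adjuvant pathway. At stage IV post-surgical
#' chemotherapy belongs to the advanced category and is costed against
#' state occupancy in the pipeline, not here.
#'
#' @param stage stage-parameter list
#' @param p `eoc_params` object
#' @return list with `surgery`, `chemo` and `total` euros per incident
#'   patient
#' @export
stage_treatment_cost <- function(stage, p) {
  mix <- stage$treatment_mix
  proc_items <- c(laparotomy = "laparotomy", omentectomy = "omentectomy",
                  hysterectomy = "hysterectomy",
                  salpingo_oophorectomy = "salpingo_oophorectomy",
                  lymphadenectomy = "lymphadenectomy")
  surgery_bundle <- sum(stage$surgery_mix[names(proc_items)] *
                        unit_cost(p, unname(proc_items)))
  surgery <- (1 - mix[["none"]]) * surgery_bundle
  chemo <- 0
  if (mix[["neoadjuvant_plus_surgery"]] > 0) {
    neo <- category_cycle_cost(p, "neoadjuvant", stage)
    chemo <- chemo + mix[["neoadjuvant_plus_surgery"]] * neo$cycles * neo$per_cycle
  }
  if (mix[["surgery_plus_adjuvant"]] > 0 && stage$stage_label != "IV") {
    adj <- category_cycle_cost(p, "adjuvant", stage)
    chemo <- chemo + mix[["surgery_plus_adjuvant"]] * adj$cycles * adj$per_cycle
  }
  list(surgery = unname(surgery), chemo = unname(chemo),
       total = unname(surgery + chemo))
}

#' Expected hospitalization and emergency cost per alive patient-cycle
#'
#' The stage's semiannual expectation (share of patients hospitalized times
#' stays per half-year times the stay cost, and likewise for emergencies)
#' divided by the number of model cycles in six months; applied to the
#' alive (stable + post-progression) occupancy in the pipeline.
#'
#' @param stage stage-parameter list
#' @param p `eoc_params` object
#' @return list with `hospitalization` and `emergency` euros per
#'   patient-cycle
#' @export
hospitalization_er_cost_per_cycle <- function(stage, p) {
  cycles_per_6mo <- (365.25 / 2) / p$settings$cycle_days
  hosp <- stage$pct_hospitalized * stage$hosp_per_6mo * unit_cost(p, "hospital_stay")
  er <- stage$pct_er * stage$er_per_6mo * unit_cost(p, "er_visit")
  list(hospitalization = hosp / cycles_per_6mo, emergency = er / cycles_per_6mo)
}

#' Genetic testing and counselling cascade cost
#'
#' A fraction of incident patients is referred to germline BRCA1/2 testing
#' with two counselling visits; for the fraction testing positive, an
#' average of five relatives receive counselling plus biannual surveillance
#' (transvaginal ultrasound and CA125) over the surveillance window.
#'
#' @param eoc_patients number of incident patients
#' @param p `eoc_params` object (cascade assumptions and unit costs)
#' @param years_of_surveillance relatives' surveillance window in years
#' @return list with `patients` and `relatives` euros (the two reporting
#'   rows) and `n_relatives`
#' @export
genetic_cascade_cost <- function(eoc_patients, p,
                                 years_of_surveillance = p$cascade$surveillance_years) {
  cs <- p$cascade
  check_nonneg(eoc_patients, "eoc_patients")
  patient_side <- cs$pct_tested * eoc_patients *
    (unit_cost(p, "brca_test") +
     cs$counselling_visits * unit_cost(p, "genetic_counselling_visit"))
  n_rel <- cs$pct_tested * cs$pct_positive * cs$relatives_per_positive * eoc_patients
  rel_side <- n_rel *
    (unit_cost(p, "genetic_counselling_visit") +
     cs$surveillance_per_year * years_of_surveillance *
       (unit_cost(p, "tvus") + unit_cost(p, "ca125_test")))
  list(patients = patient_side, relatives = rel_side, n_relatives = n_rel)
}

#' Expected palliative-care cost per dying patient
#'
#' Covers the last 48 days of life: an outpatient-hospital branch (nurse
#' follow-up) versus a palliative home-care team branch (9.5 home visits),
#' four primary-care visits for everyone, the terminal-phase location split
#' (home with twice-daily nurse visits over the last 3 days versus
#' hospital), and sedation drugs for 14% of patients. Attached to the new
#' deaths of each cycle in the pipeline.
#'
#' @param p `eoc_params` object (palliative pathway and unit costs)
#' @return euros per dying patient
#' @export
palliative_cost_per_death <- function(p) {
  pl <- p$palliative
  for (f in c("pct_outpatient", "pct_home_team", "pct_terminal_home",
              "pct_terminal_hospital", "pct_sedation"))
    check_fraction(pl[[f]], paste0("palliative$", f))
  pl$pct_outpatient * pl$outpatient_nurse_visits * unit_cost(p, "nurse_visit") +
    pl$pct_home_team * pl$home_visits * unit_cost(p, "palliative_home_visit") +
    pl$primary_care_visits * unit_cost(p, "primary_care_visit") +
    pl$pct_terminal_home * pl$terminal_home_days * pl$nurse_visits_per_day *
      unit_cost(p, "nurse_visit") +
    pl$pct_terminal_hospital * pl$terminal_hospital_days *
      unit_cost(p, "palliative_hospital_day") +
    pl$pct_sedation * unit_cost(p, "sedation_drugs")
}

#' Follow-up cost per patient-cycle by health state
#'
#' Converts the annual follow-up schedule (visits and tests per year, less
#' frequent in the stable state) into an expected cost per model cycle.
#'
#' @param state `"stable"` or `"post_progression"`
#' @param p `eoc_params` object (schedule and unit costs)
#' @return euros per patient-cycle
#' @export
followup_cost_per_cycle <- function(state, p) {
  sch <- p$followup_schedule[p$followup_schedule$state == state, , drop = FALSE]
  if (nrow(sch) == 0) return(0)
  sum(sch$per_year * unit_cost(p, sch$item_id)) / cycles_per_year(p$settings)
}
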