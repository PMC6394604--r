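# Direct non-healthcare costs (formal and informal care, proxy-good method)
# and indirect costs (temporary/permanent leave and premature mortality,
# human-capital method). All streams are evaluated on the cohort trace at
# the stage's mean age and discounted from model start.
#
# Every stream function can return either the cohort total or (with
# `by_cycle = TRUE`) the discounted euros accrued during each model cycle
# c = 0..n-1, which the pipeline buckets into reporting years. Occupancy
# during cycle c is the state membership at the cycle start; events of
# cycle c (progressions, deaths) are discounted at the cycle end.

labour_at_age <- function(labour, age) {
  a <- pmin(pmax(floor(age), min(labour$age)), max(labour$age))
  i <- match(a, labour$age)
  list(employment = labour$employment_rate[i], wage = labour$annual_wage[i])
}

# growth-indexed gross daily wage at an attained age, `elapsed` years after
# model start
daily_wage <- function(p, age, elapsed) {
  lb <- labour_at_age(p$labour, age)
  lb$wage / 365.25 * (1 + p$settings$productivity_growth)^elapsed
}

#' Formal (professional) care cost per dying patient
#'
#' Public and private professional care over the last 48 days of life:
#' `days * wage * (share * hours/day)` for each branch, valued at the common
#' caregiver wage.
#'
#' @param care care assumptions list (see [default_parameters()])
#' @return list with `public`, `private` and `total` euros per death
#' @export
formal_care_cost_per_death <- function(care) {
  check_fraction(care$pct_public, "care$pct_public")
  check_fraction(care$pct_private, "care$pct_private")
  pub <- care$formal_care_days * care$wage_per_hour * care$pct_public * care$hours_public
  priv <- care$formal_care_days * care$wage_per_hour * care$pct_private * care$hours_private
  list(public = pub, private = priv, total = pub + priv)
}

#' Informal care cost for one cohort
#'
#' Non-remunerated care valued by the proxy-good method at the caregiver
#' wage. Under the default window the cost accrues over post-progression
#' occupancy (share cared for x hours/day x wage x days per cycle),
#' discounted at accrual time; the alternative `"last_48_days"` window
#' attaches a fixed 48-day block to each death instead.
#'
#' @param trace `cohort_trace` (fractions; scaled by its `size` attribute)
#' @param p `eoc_params` object
#' @param entry_offset years between model start and cohort entry
#' @param by_cycle return the per-cycle discounted vector instead of the sum
#' @return discounted euros for the cohort (or per-cycle vector)
#' @export
informal_care_cost <- function(trace, p, entry_offset = 0, by_cycle = FALSE) {
  care <- p$care
  size <- attr(trace, "size") %||% 1
  t <- cycle_years(p$settings)
  r <- p$settings$discount_rate_annual
  hours <- care$hours_informal * p$settings$informal_hours_factor
  per_day <- care$pct_informal * hours * care$wage_per_hour
  n <- nrow(trace) - 1
  cyc <- seq_len(n) - 1
  if (p$settings$informal_care_window == "post_progression") {
    disc <- (1 + r)^-(entry_offset + cyc * t)
    v <- size * trace$frac_postprog[cyc + 1] * per_day *
      p$settings$cycle_days * disc
  } else {
    disc <- (1 + r)^-(entry_offset + (cyc + 1) * t)
    v <- size * trace$new_deaths[cyc + 2] * per_day *
      care$formal_care_days * disc
  }
  if (by_cycle) v else sum(v)
}

#' Temporary-leave productivity loss at diagnosis
#'
#' Human-capital method: every employed patient diagnosed before retirement
#' loses an expected `0.30 * 60 + 0.70 * 70 = 67` working days (the split is
#' configurable), valued at the age-specific gross daily wage with annual
#' productivity growth, discounted at the entry time. Zero for cohorts
#' diagnosed at or above the retirement age.
#'
#' @param trace `cohort_trace`
#' @param p `eoc_params` object
#' @param entry_offset years between model start and cohort entry
#' @return discounted euros for the cohort
#' @export
temporary_leave_cost <- function(trace, p, entry_offset = 0) {
  size <- attr(trace, "size") %||% 1
  age <- trace$attained_age[1]
  if (age >= p$settings$retirement_age) return(0)
  lv <- p$leave
  days <- lv$pct_losing_60 * lv$days_60 +
    lv$pct_losing_70 * p$settings$temp_leave_days_over
  lb <- labour_at_age(p$labour, age)
  disc <- (1 + p$settings$discount_rate_annual)^-entry_offset
  size * lb$employment * days * daily_wage(p, age, entry_offset) * disc
}

# post-progression occupancy restricted to time-since-progression < max_lag
# cycles, per trace row (exact decomposition: post-progression only exits
# through death, so each progression cohort decays by prps)
pp_occupancy_within <- function(trace, max_lag) {
  P <- attr(trace, "probs")
  n <- nrow(trace)
  out <- numeric(n)
  np <- trace$new_progressions
  for (m in seq_len(n)) {
    if (np[m] <= 0) next
    surv <- np[m]
    jmax <- min(n, m + max_lag - 1)
    for (j in m:jmax) {
      out[j] <- out[j] + surv
      if (j < jmax) surv <- surv * P$prps[j]
    }
  }
  out
}

#' Sick leave from progression to death or retirement
#'
#' Patients at advanced disease are on sick leave from progression until
#' death or the retirement age, valued at age-specific wages for the
#' employed fraction. Leave person-time within the first year after
#' progression is booked as (temporary-style) progression sick leave; time
#' beyond one year books to the permanent-disability row. Both are zero once
#' the attained age reaches retirement.
#'
#' @param trace `cohort_trace`
#' @param p `eoc_params` object
#' @param entry_offset years between model start and cohort entry
#' @param by_cycle return per-cycle discounted vectors instead of sums
#' @return list with discounted `progression` (first-year) and `permanent`
#'   euros for the cohort (scalars or per-cycle vectors)
#' @export
permanent_and_progression_leave_cost <- function(trace, p, entry_offset = 0,
                                                 by_cycle = FALSE) {
  size <- attr(trace, "size") %||% 1
  t <- cycle_years(p$settings)
  r <- p$settings$discount_rate_annual
  cpy <- cycles_per_year(p$settings)
  n <- nrow(trace) - 1
  prog <- perm <- numeric(n)
  working <- trace$attained_age[seq_len(n)] < p$settings$retirement_age
  if (any(working) && size > 0) {
    within1 <- pp_occupancy_within(trace, cpy)
    for (j in which(working)) {  # row j accrues during cycle j-1
      age <- trace$attained_age[j]
      elapsed <- entry_offset + (j - 1) * t
      lb <- labour_at_age(p$labour, age)
      value <- lb$employment * daily_wage(p, age, elapsed) *
        p$settings$cycle_days * (1 + r)^-elapsed * size
      prog[j] <- within1[j] * value
      perm[j] <- (trace$frac_postprog[j] - within1[j]) * value
    }
  }
  if (by_cycle) list(progression = prog, permanent = perm)
  else list(progression = sum(prog), permanent = sum(perm))
}

# present value at death of gross earnings lost from age `a` to retirement
pv_future_earnings <- function(p, a, elapsed) {
  ret <- p$settings$retirement_age
  if (a >= ret) return(0)
  r <- if (p$settings$discount_premature_mortality)
    p$settings$discount_rate_annual else 0
  g <- p$settings$productivity_growth
  pv <- 0
  y <- 0
  while (a + y < ret) {
    frac <- min(1, ret - (a + y))
    lb <- labour_at_age(p$labour, a + y)
    pv <- pv + frac * lb$employment * lb$wage * (1 + g)^(elapsed + y) * (1 + r)^-y
    y <- y + 1
  }
  pv
}

#' Premature-mortality productivity loss
#'
#' For each death occurring before the retirement age, the discounted stream
#' of expected gross earnings (employment rate x wage, with annual
#' productivity growth) from the age at death to retirement; zero for
#' deaths at or beyond retirement.
#'
#' @param trace `cohort_trace`
#' @param p `eoc_params` object
#' @param entry_offset years between model start and cohort entry
#' @param by_cycle return the per-cycle discounted vector instead of the sum
#' @return discounted euros for the cohort (or per-cycle vector)
#' @export
premature_mortality_cost <- function(trace, p, entry_offset = 0,
                                     by_cycle = FALSE) {
  size <- attr(trace, "size") %||% 1
  t <- cycle_years(p$settings)
  r <- p$settings$discount_rate_annual
  n <- nrow(trace) - 1
  v <- numeric(n)
  if (size > 0) {
    for (c in seq_len(n) - 1) {  # deaths during cycle c land at row c + 2
      a <- trace$attained_age[c + 2]
      if (a >= p$settings$retirement_age) break
      if (trace$new_deaths[c + 2] <= 0) next
      elapsed <- entry_offset + (c + 1) * t
      v[c + 1] <- size * trace$new_deaths[c + 2] *
        pv_future_earnings(p, a, elapsed) * (1 + r)^-elapsed
    }
  }
  if (by_cycle) v else sum(v)
}
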