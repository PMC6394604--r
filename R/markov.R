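# Three-state Markov cohort engine: stable -> post-progression -> dead, with
# per-cycle transition probabilities built from stage PFS/OS medians under an
# exponential survival assumption plus age-dependent natural mortality.

#' Exponential hazard from a median survival time
#'
#' Under an exponential survival curve the hazard is `ln(2) / median`.
#'
#' @param median median survival in years (> 0)
#' @return hazard rate per year
#' @export
exp_rate_from_median <- function(median) {
  if (any(is.na(median)) || any(median <= 0))
    stop("median must be > 0", call. = FALSE)
  log(2) / median
}

#' Per-cycle probability of progression from the stable state
#'
#' `1 - exp(-lambda * t)` with `lambda = ln(2) / median_pfs`: the
#' discretized exponential progression-free survival curve.
#'
#' @param median_pfs median progression-free survival (years, > 0)
#' @param t elapsed time (years, >= 0); one model cycle in the engine
#' @return probability of progressing within `t`
#' @export
prob_progress <- function(median_pfs, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  1 - exp(-exp_rate_from_median(median_pfs) * t)
}

#' Per-cycle probability of dying in the post-progression state
#'
#' Post-progression survival is exponential with median
#' `median_os - median_pfs`; the natural-mortality probability `pnd` is
#' added and the result capped at 1.
#'
#' @param median_os median overall survival (years)
#' @param median_pfs median progression-free survival (years, < `median_os`)
#' @param t elapsed time (years)
#' @param pnd per-cycle natural death probability in `[0, 1]`
#' @return probability in `[0, 1]`
#' @export
prob_death_postprog <- function(median_os, median_pfs, t, pnd = 0) {
  if (any(median_os <= median_pfs))
    stop("median_os must exceed median_pfs", call. = FALSE)
  if (any(pnd < 0) || any(pnd > 1)) stop("pnd must be in [0, 1]", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  pmin(1, 1 - exp(-exp_rate_from_median(median_os - median_pfs) * t) + pnd)
}

#' Per-cycle natural death probability at an attained age
#'
#' Looks up the annual all-cause mortality rate at `floor(attained_age)`
#' (clamped to the life-table range) and converts it to a probability over
#' `t` years: `1 - exp(-rate * t)`.
#'
#' @param attained_age age in years (fractional allowed)
#' @param life_table data.frame (`age`, `annual_mortality_rate`)
#' @param t cycle length in years
#' @return probability in `[0, 1)`
#' @export
natural_death_prob <- function(attained_age, life_table, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  a <- pmin(pmax(floor(attained_age), min(life_table$age)), max(life_table$age))
  rate <- life_table$annual_mortality_rate[match(a, life_table$age)]
  1 - exp(-rate * t)
}

#' All five transition probabilities for one stage at one attained age
#'
#' Stable-state death is natural mortality only; progression follows the
#' stage PFS curve; post-progression death follows the OS-minus-PFS curve
#' plus natural mortality. Rows are guaranteed to lie on the probability
#' simplex: if `pdss + ppss` exceeds 1 (degenerate parameters) the pair is
#' renormalized with a warning.
#'
#' @param stage stage-parameter list (see [default_stage_parameters()])
#' @param attained_age age in years at the start of the cycle
#' @param settings economic settings (cycle length)
#' @param life_table life table for natural mortality
#' @return list with `prss`, `pdss`, `ppss`, `prps`, `pdps`
#' @export
cycle_probabilities <- function(stage, attained_age, settings, life_table) {
  t <- cycle_years(settings)
  pdss <- natural_death_prob(attained_age, life_table, t)
  ppss <- prob_progress(stage$median_pfs, t)
  if (pdss + ppss > 1) {
    warning("degenerate parameters: pdss + ppss > 1 at age ",
            round(attained_age, 1), "; renormalized", call. = FALSE)
    tot <- pdss + ppss
    pdss <- pdss / tot
    ppss <- ppss / tot
  }
  prss <- 1 - pdss - ppss
  pdps <- prob_death_postprog(stage$median_os, stage$median_pfs, t, pnd = pdss)
  list(prss = prss, pdss = pdss, ppss = ppss, prps = 1 - pdps, pdps = pdps)
}

# probability rows for cycles 0..(n_cycles-1); row j governs the j -> j+1
# transition at attained age age_dx + j * t
stage_prob_matrix <- function(stage, n_cycles, settings, life_table) {
  t <- cycle_years(settings)
  age <- stage$mean_age_dx * settings$age_factor + (seq_len(n_cycles) - 1) * t
  pdss <- natural_death_prob(age, life_table, t)
  ppss <- rep(prob_progress(stage$median_pfs, t), n_cycles)
  bad <- pdss + ppss > 1
  if (any(bad)) {
    warning("degenerate parameters: pdss + ppss > 1 in ", sum(bad),
            " cycle(s); renormalized", call. = FALSE)
    tot <- pdss[bad] + ppss[bad]
    pdss[bad] <- pdss[bad] / tot
    ppss[bad] <- ppss[bad] / tot
  }
  pdps <- prob_death_postprog(stage$median_os, stage$median_pfs, t, pnd = 0)
  pdps <- pmin(1, pdps + pdss)
  data.frame(cycle_index = seq_len(n_cycles) - 1, attained_age = age,
             prss = 1 - pdss - ppss, pdss = pdss, ppss = ppss,
             prps = 1 - pdps, pdps = pdps)
}

#' Run the deterministic cohort trace for one stage and entry year
#'
#' Expected-value (cohort) evaluation: the occupancy vector (stable,
#' post-progression, dead) starts at (1, 0, 0) and is advanced by the
#' per-cycle probability rows; no Monte Carlo. New progressions and deaths
#' per cycle are recorded for event-linked costing. The per-cycle
#' probability rows are attached as attribute `"probs"`.
#'
#' @param stage stage-parameter list
#' @param entry_year calendar year the cohort is diagnosed
#' @param size cohort size in patients (0 gives an all-zero trace)
#' @param settings economic settings
#' @param life_table life table
#' @param n_cycles number of cycles to simulate (default: full horizon)
#' @return data.frame of class `cohort_trace` with columns `cycle_index`,
#'   `attained_age`, `frac_stable`, `frac_postprog`, `frac_dead`,
#'   `new_progressions`, `new_deaths` (fractions of the cohort); attributes
#'   `stage_label`, `entry_year`, `size`, `probs`
#' @export
run_cohort_trace <- function(stage, entry_year, size, settings, life_table,
                             n_cycles = NULL) {
  if (size < 0) stop("size must be >= 0", call. = FALSE)
  n_cycles <- n_cycles %||% (settings$horizon_years * cycles_per_year(settings))
  P <- stage_prob_matrix(stage, n_cycles, settings, life_table)
  t <- cycle_years(settings)
  s <- pp <- d <- np <- nd <- numeric(n_cycles + 1)
  s[1] <- if (size > 0) 1 else 0
  for (j in seq_len(n_cycles)) {
    np[j + 1] <- s[j] * P$ppss[j]
    nd[j + 1] <- s[j] * P$pdss[j] + pp[j] * P$pdps[j]
    s[j + 1] <- s[j] * P$prss[j]
    pp[j + 1] <- pp[j] * P$prps[j] + np[j + 1]
    d[j + 1] <- d[j] + nd[j + 1]
  }
  out <- data.frame(
    cycle_index = 0:n_cycles,
    attained_age = stage$mean_age_dx * settings$age_factor + (0:n_cycles) * t,
    frac_stable = s, frac_postprog = pp, frac_dead = d,
    new_progressions = np, new_deaths = nd
  )
  attr(out, "stage_label") <- stage$stage_label
  attr(out, "entry_year") <- entry_year
  attr(out, "size") <- size
  attr(out, "probs") <- P
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Project incident cohorts over the model horizon
#'
#' Year-1 ovarian-cancer incidence and a constant annual increment define a
#' linear projection; the epithelial fraction (default 90%) converts it to
#' EOC cases, which are split over the four stages with an unchanged stage
#' distribution. Stage counts are integers by the largest-remainder method
#' (so they sum to the EOC total) unless `integer_counts` is `FALSE`; the
#' year-1 counts default to the packaged stage table.
#'
#' @param p `eoc_params` object (uses `p$projection`, `p$settings`)
#' @return data.frame (`year`, `oc_incidence`, `eoc_incidence`, one column
#'   per stage)
#' @export
project_incidence <- function(p) {
  pr <- p$projection
  h <- p$settings$horizon_years
  years <- p$settings$base_year + seq_len(h)
  oc <- pr$year1_oc + pr$annual_increment * (seq_len(h) - 1)
  if (any(oc < 0)) stop("projected incidence is negative", call. = FALSE)
  eoc <- pr$epithelial_fraction * oc
  shares <- pr$stage_counts_year1 / sum(pr$stage_counts_year1)
  counts <- matrix(0, nrow = h, ncol = 4, dimnames = list(NULL, stage_labels()))
  for (y in seq_len(h)) {
    if (pr$integer_counts) {
      if (y == 1 && sum(pr$stage_counts_year1) == round(eoc[y])) {
        counts[y, ] <- pr$stage_counts_year1
      } else {
        counts[y, ] <- round_largest_remainder(eoc[y], shares)
      }
    } else {
      counts[y, ] <- eoc[y] * shares
    }
  }
  eoc_out <- if (pr$integer_counts) rowSums(counts) else eoc
  cbind(data.frame(year = years, oc_incidence = oc, eoc_incidence = eoc_out),
        as.data.frame(counts))
}

#' Run every (stage, entry-year) cohort over the horizon
#'
#' One trace per stage and diagnosis year; a cohort entering in model year
#' `k` is simulated for `horizon - k + 1` years so that all traces stop at
#' the calendar end of the horizon.
#'
#' @param p `eoc_params` object
#' @return named list of `cohort_trace` objects (`"<stage>_<year>"`), with
#'   the incidence projection attached as attribute `"projection"`
#' @export
run_multi_cohort <- function(p) {
  proj <- project_incidence(p)
  cpy <- cycles_per_year(p$settings)
  h <- p$settings$horizon_years
  out <- list()
  for (sl in stage_labels()) {
    for (k in seq_len(h)) {
      tr <- run_cohort_trace(p$stages[[sl]], proj$year[k], proj[[sl]][k],
                             p$settings, p$life_table,
                             n_cycles = (h - k + 1) * cpy)
      out[[paste0(sl, "_", proj$year[k])]] <- tr
    }
  }
  attr(out, "projection") <- proj
  out
}

#' Export traces as a tidy table
#'
#' @param traces list of `cohort_trace` objects (from [run_multi_cohort()])
#' @return data.frame with one row per (stage, entry year, cycle)
#' @export
traces_to_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    cbind(data.frame(stage = attr(tr, "stage_label"),
                     entry_year = attr(tr, "entry_year"),
                     size = attr(tr, "size")),
          as.data.frame(tr))
  }))
}
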