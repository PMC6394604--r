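# shared fixtures, built once per test run

default_p <- default_parameters(seed = 1L)

# immortal variant: zero natural mortality isolates the disease curves
immortal_p <- local({
  p <- default_p
  p$life_table <- generate_life_table(a = 0, b = 0.1)
  p
})

# hand-buildable trace for unit-testing cost streams: constant per-cycle
# state fractions with explicit events
make_trace <- function(p, stage_label = "III", n_cycles = 18, size = 1,
                       frac_stable = NULL, frac_postprog = NULL,
                       new_progressions = NULL, new_deaths = NULL,
                       age_dx = NULL, prps = NULL) {
  stage <- p$stages[[stage_label]]
  t <- p$settings$cycle_days / 365.25
  age0 <- age_dx %||% stage$mean_age_dx
  zeros <- numeric(n_cycles + 1)
  tr <- data.frame(
    cycle_index = 0:n_cycles,
    attained_age = age0 + (0:n_cycles) * t,
    frac_stable = frac_stable %||% c(1, rep(0, n_cycles)),
    frac_postprog = frac_postprog %||% zeros,
    frac_dead = zeros,
    new_progressions = new_progressions %||% zeros,
    new_deaths = new_deaths %||% zeros
  )
  attr(tr, "stage_label") <- stage_label
  attr(tr, "entry_year") <- p$settings$base_year + 1
  attr(tr, "size") <- size
  attr(tr, "probs") <- data.frame(
    cycle_index = 0:(n_cycles - 1),
    prss = rep(1, n_cycles), pdss = rep(0, n_cycles), ppss = rep(0, n_cycles),
    prps = prps %||% rep(1, n_cycles), pdps = rep(0, n_cycles)
  )
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force oracle for the vial solver: full enumeration of
# all count combinations up to the covering count per option
vial_oracle <- function(dose_mg, vial_mg, vial_price) {
  grids <- lapply(vial_mg, function(s) 0:ceiling(dose_mg / s))
  combos <- as.matrix(expand.grid(grids))
  covered <- combos %*% vial_mg >= dose_mg
  costs <- combos %*% vial_price
  min(costs[covered])
}
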