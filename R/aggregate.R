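# Discounting, per-patient averaging and the stage x category breakdown.

#' Discount a cost to present value
#'
#' `amount * (1 + rate)^(-elapsed)`, elapsed measured in years from model
#' start to the accrual cycle.
#'
#' @param amount euros
#' @param elapsed years since model start (may be fractional)
#' @param rate annual discount rate (>= 0; default 3%)
#' @return discounted euros
#' @export
discount <- function(amount, elapsed, rate = 0.03) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  amount * (1 + rate)^(-elapsed)
}

#' Average annual cost per patient
#'
#' One reporting year's cost divided by the number of patients in care that
#' year: those alive at the beginning of the year plus the incident
#' patients of that year.
#'
#' @param year_cost euros accrued in the year
#' @param alive_at_year_start patients alive when the year starts
#' @param incident_in_year newly diagnosed patients in the year
#' @return euros per patient
#' @export
average_annual_cost_per_patient <- function(year_cost, alive_at_year_start,
                                            incident_in_year) {
  den <- alive_at_year_start + incident_in_year
  if (any(den <= 0)) stop("patient denominator must be > 0", call. = FALSE)
  year_cost / den
}

#' Build the stage x category cost breakdown
#'
#' Aggregates per-year cost matrices into the reporting structure: total
#' euros per stage and cost row, within-stage percentages, average annual
#' cost per patient (mean over reporting years of year cost divided by the
#' year's patient denominator), DHC/DNHC/IC subtotals, stage totals and the
#' grand total.
#'
#' @param by_year named list (one per stage `"I".."IV"`) of cost-row x year
#'   matrices of discounted euros
#' @param denominators stage x year matrix of patient denominators (alive at
#'   year start + incident)
#' @return object of class `cost_breakdown`: list with `cells` (data.frame
#'   with item and subtotal rows; `total_*`, `pct_*`, `avg_*` columns per
#'   stage), `grand_total`, `overall_avg_per_patient` (NA when denominators
#'   are not supplied), `by_year`, `denominators`
#' @export
build_breakdown <- function(by_year, denominators = NULL) {
  rows <- cost_row_names()
  for (sl in stage_labels()) {
    if (is.null(by_year[[sl]]))
      stop("missing cost streams for stage ", sl, call. = FALSE)
    missing_rows <- setdiff(rows, rownames(by_year[[sl]]))
    if (length(missing_rows) > 0)
      stop("missing cost stream row(s): ", paste(missing_rows, collapse = ", "),
           call. = FALSE)
  }
  ctype <- cost_type_of_row()
  cells <- data.frame(row = rows, cost_type = unname(ctype[rows]),
                      stringsAsFactors = FALSE)
  for (sl in stage_labels()) {
    tot <- rowSums(by_year[[sl]])[rows]
    stage_total <- sum(tot)
    avg <- if (!is.null(denominators)) {
      apply(by_year[[sl]][rows, , drop = FALSE], 1,
            function(v) mean(v / denominators[sl, ]))
    } else rep(NA_real_, length(rows))
    cells[[paste0("total_", sl)]] <- unname(tot)
    cells[[paste0("pct_", sl)]] <-
      if (stage_total > 0) unname(100 * tot / stage_total) else 0 * unname(tot)
    cells[[paste0("avg_", sl)]] <- unname(avg)
  }
  out <- breakdown_from_cells(cells)
  out$by_year <- by_year
  out$denominators <- denominators
  if (!is.null(denominators)) {
    year_tot <- Reduce(`+`, lapply(by_year, colSums))
    out$overall_avg_per_patient <- mean(year_tot / colSums(denominators))
  }
  out
}

#' Assemble a breakdown from item cells
#'
#' Pure aggregation layer: given the item-level cells (total euros and
#' average annual cost per patient for each stage), recomputes DHC/DNHC/IC
#' subtotals, stage totals, within-stage percentages and the grand total,
#' enforcing the structural invariants. Used both by the model pipeline and
#' to verify the packaged printed-results fixture.
#'
#' @param cells data.frame with columns `row`, `cost_type` and per-stage
#'   `total_*` / `avg_*` (item rows; any subtotal rows present are dropped
#'   and recomputed)
#' @return `cost_breakdown` object
#' @export
breakdown_from_cells <- function(cells) {
  rows <- cost_row_names()
  items <- cells[cells$row %in% rows, , drop = FALSE]
  if (length(setdiff(rows, items$row)) > 0)
    stop("missing cost stream row(s): ",
         paste(setdiff(rows, items$row), collapse = ", "), call. = FALSE)
  items <- items[match(rows, items$row), ]
  ctype <- cost_type_of_row()
  subtotal <- function(type, label) {
    sel <- items$cost_type == type
    r <- data.frame(row = label, cost_type = type, stringsAsFactors = FALSE)
    for (sl in stage_labels()) {
      r[[paste0("total_", sl)]] <- sum(items[[paste0("total_", sl)]][sel])
      r[[paste0("pct_", sl)]] <- NA_real_
      r[[paste0("avg_", sl)]] <- sum(items[[paste0("avg_", sl)]][sel])
    }
    r
  }
  tot_row <- data.frame(row = "total", cost_type = "TOTAL",
                        stringsAsFactors = FALSE)
  for (sl in stage_labels()) {
    tot_row[[paste0("total_", sl)]] <- sum(items[[paste0("total_", sl)]])
    tot_row[[paste0("pct_", sl)]] <- 100
    tot_row[[paste0("avg_", sl)]] <- sum(items[[paste0("avg_", sl)]])
  }
  full <- items
  for (sl in stage_labels()) {
    st <- tot_row[[paste0("total_", sl)]]
    full[[paste0("pct_", sl)]] <-
      if (st > 0) 100 * full[[paste0("total_", sl)]] / st
      else 0 * full[[paste0("total_", sl)]]
  }
  sub <- rbind(subtotal("DHC", "total_dhc"), subtotal("DNHC", "total_dnhc"),
               subtotal("IC", "total_ic"))
  for (sl in stage_labels()) {
    st <- tot_row[[paste0("total_", sl)]]
    sub[[paste0("pct_", sl)]] <-
      if (st > 0) 100 * sub[[paste0("total_", sl)]] / st else 0
  }
  cells_out <- rbind(full, sub, tot_row)
  stage_totals <- vapply(stage_labels(), function(sl)
    tot_row[[paste0("total_", sl)]], numeric(1))
  out <- list(cells = cells_out,
              stage_totals = stage_totals,
              grand_total = sum(stage_totals),
              overall_avg_per_patient = NA_real_)
  class(out) <- "cost_breakdown"
  out
}

#' Share decompositions of a cost breakdown
#'
#' Cost-type shares of the grand total (DHC / DNHC / IC), per-stage shares,
#' the informal-care share of DNHC, and the internal split of indirect
#' costs over temporary leave, permanent leave and premature mortality.
#' Percentages on the 0-100 scale.
#'
#' @param b `cost_breakdown` object
#' @return list with `cost_type_pct`, `stage_pct`, `informal_pct_of_dnhc`,
#'   `ic_split_pct`
#' @export
decompose_shares <- function(b) {
  if (b$grand_total <= 0) stop("grand total must be > 0", call. = FALSE)
  cells <- b$cells
  row_total <- function(r) sum(vapply(stage_labels(), function(sl)
    cells[[paste0("total_", sl)]][cells$row == r], numeric(1)))
  type_total <- function(type) sum(vapply(stage_labels(), function(sl)
    sum(cells[[paste0("total_", sl)]][cells$cost_type == type &
                                      !grepl("^total", cells$row)]), numeric(1)))
  dhc <- type_total("DHC"); dnhc <- type_total("DNHC"); ic <- type_total("IC")
  ic_rows <- c("temp_disability", "perm_disability", "premature_mortality")
  ic_parts <- vapply(ic_rows, row_total, numeric(1))
  list(
    cost_type_pct = 100 * c(DHC = dhc, DNHC = dnhc, IC = ic) / b$grand_total,
    stage_pct = 100 * b$stage_totals / b$grand_total,
    informal_pct_of_dnhc = if (dnhc > 0) 100 * row_total("informal") / dnhc else NA_real_,
    ic_split_pct = if (ic > 0) 100 * ic_parts / ic else 0 * ic_parts
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Cost breakdown (euros, discounted)\n")
  cat(sprintf("  grand total: %.1f million\n", x$grand_total / 1e6))
  for (sl in stage_labels())
    cat(sprintf("  stage %-3s total: %15.0f\n", sl, x$stage_totals[[sl]]))
  invisible(x)
}

#' Write report files for a model run
#'
#' Emits the breakdown as a wide (reporting-table-shaped) CSV, a tidy
#' long-format CSV, the stacked-bar dataset (cost type x stage), and a JSON
#' summary (grand totals, shares, per-patient averages).
#'
#' @param run `eoc_run` object from [run_burden_model()]
#' @param dir output directory (created if needed)
#' @return invisible character vector of the files written
#' @export
write_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- run$breakdown
  wide <- file.path(dir, "breakdown_wide.csv")
  utils::write.csv(b$cells, wide, row.names = FALSE)
  long <- do.call(rbind, lapply(stage_labels(), function(sl) {
    data.frame(stage = sl, row = b$cells$row, cost_type = b$cells$cost_type,
               total_eur = b$cells[[paste0("total_", sl)]],
               pct_of_stage = b$cells[[paste0("pct_", sl)]],
               avg_annual_per_patient_eur = b$cells[[paste0("avg_", sl)]],
               stringsAsFactors = FALSE)
  }))
  longp <- file.path(dir, "breakdown_long.csv")
  utils::write.csv(long, longp, row.names = FALSE)
  stacked <- long[long$row %in% c("total_dhc", "total_dnhc", "total_ic"),
                  c("stage", "row", "total_eur")]
  stackp <- file.path(dir, "cost_type_by_stage.csv")
  utils::write.csv(stacked, stackp, row.names = FALSE)
  sh <- decompose_shares(b)
  summ <- list(
    grand_total_eur = b$grand_total,
    grand_total_million_eur = b$grand_total / 1e6,
    stage_totals_eur = as.list(b$stage_totals),
    overall_avg_annual_cost_per_patient_eur = b$overall_avg_per_patient,
    avg_annual_cost_per_patient_by_stage_eur = as.list(vapply(
      stage_labels(), function(sl)
        b$cells[[paste0("avg_", sl)]][b$cells$row == "total"], numeric(1))),
    cost_type_pct = as.list(sh$cost_type_pct),
    stage_pct = as.list(sh$stage_pct),
    informal_pct_of_dnhc = sh$informal_pct_of_dnhc,
    ic_split_pct = as.list(sh$ic_split_pct)
  )
  summp <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, summp, auto_unbox = TRUE, digits = NA)
  invisible(c(wide, longp, stackp, summp))
}
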