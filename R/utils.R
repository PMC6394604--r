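# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_labels <- function() c("I", "II", "III", "IV")

#' Abort with a field-aware message
#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(TRUE))
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_field(field, "must be a fraction in [0, 1]")
  invisible(TRUE)
}

check_nonneg <- function(x, field) {
  if (any(is.na(x)) || any(x < 0)) stop_field(field, "must be >= 0")
  invisible(TRUE)
}

check_positive <- function(x, field) {
  if (any(is.na(x)) || any(x <= 0)) stop_field(field, "must be > 0")
  invisible(TRUE)
}

#' Largest-remainder rounding
#'
#' Distributes `total` over `shares` (renormalized internally) so the
#' integer parts sum exactly to `round(total)`. Used for the per-stage
#' split of projected incident cases.
#'
#' @param total number to distribute (may be fractional; the integer
#'   result sums to `round(total)`)
#' @param shares non-negative weights
#' @return integer vector, same length as `shares`
#' @export
round_largest_remainder <- function(total, shares) {
  if (any(shares < 0)) stop("shares must be non-negative")
  s <- sum(shares)
  if (s <= 0) stop("shares must have a positive sum")
  target <- round(total)
  raw <- target * shares / s
  base <- floor(raw)
  rem <- target - sum(base)
  if (rem > 0) {
    # ties broken by position for determinism
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# deep merge of override list into defaults (scalars and nested lists;
# data.frames and atomic vectors are replaced wholesale)
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]]) &&
        is.list(override[[nm]]) && !is.data.frame(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# parse "a;b;c" numeric lists in catalogue CSV cells
split_numeric <- function(x) lapply(strsplit(as.character(x), ";", fixed = TRUE),
                                    function(v) as.numeric(v))
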