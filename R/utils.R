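## Internal helpers shared across modules.

#' Population (divide-by-n) standard deviation
#'
#' Both Z-score stages use the population convention so that a standardized
#' vector has SD exactly 1; `stats::sd()` uses n - 1.
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed clinical tables round half
#' away from zero (47.25 -> 47.3), so reported percentages use this rule.
#' @noRd
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent error class
#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("epipanel_config_error", "error")))
}

#' Check that a value is a single non-missing number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' Expand a scalar or length-2 range to c(lo, hi)
#' @noRd
as_range <- function(x, what) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 2L) || anyNA(x)) {
    stop_config(what, " must be a number or a length-2 range")
  }
  if (length(x) == 1L) x <- c(x, x)
  if (x[2] < x[1]) stop_config(what, " range has upper bound below lower bound")
  x
}
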