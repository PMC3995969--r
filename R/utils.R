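# Shared small helpers: seasons, logging, validation.

#' Map a month index to a Zambian climate season
#'
#' Months are calendar month indices; indices beyond 12 wrap around, so a
#' 24-month series maps months 13..24 back onto January..December.
#' Seasons follow the southern-Africa convention used throughout the package:
#' rainy (January--April), cold-dry (May--August), hot-dry
#' (September--December).
#'
#' @param month Integer vector of month indices (1 = January).
#' @return Factor with levels `rainy`, `cold_dry`, `hot_dry`.
#' @export
#' @examples
#' season_of(c(2, 6, 9))
season_of <- function(month) {
  if (!is.numeric(month) || any(is.na(month)) || any(month < 1) ||
      any(month != round(month))) {
    abort("`month` must be positive whole month indices.", class = "geomoran_validation_error")
  }
  m <- ((as.integer(month) - 1L) %% 12L) + 1L
  s <- cut(m, breaks = c(0, 4, 8, 12),
           labels = c("rainy", "cold_dry", "hot_dry"))
  factor(as.character(s), levels = c("rainy", "cold_dry", "hot_dry"))
}

#' Convert a log10 rate to its natural (multiplicative) scale
#'
#' Demographic rates in the Moran-curve decomposition live on the log10
#' scale, where losses add. The natural-scale equivalent of a log10 rate `x`
#' is the multiplicative factor `10^x`: a monthly fertility of 0.23
#' corresponds to a maximum multiplication rate of about 1.70 per month.
#'
#' @param log_value Numeric vector of log10-scale values.
#' @return `10^log_value`.
#' @export
#' @examples
#' to_natural_scale(c(0, 0.23, 0.459))
to_natural_scale <- function(log_value) {
  stopifnot(is.numeric(log_value))
  10^log_value
}

# stderr logging used by readers/builders; record counts and drop reasons.
log_note <- function(...) {
  message(sprintf(...))
}

`%||%` <- rlang::`%||%`
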