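#' Round half away from zero
#'
#' Rounding used for all reported percentages: exact halves round up
#' (79.25 -> 79.3), unlike [base::round()]'s round-half-to-even. A tiny
#' epsilon absorbs binary representation error in values such as
#' `100 * 83 / 93`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(62.55, 1) # 62.6
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), digits >= 0)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# stop with a classed condition so tests can assert on error class
stop_crowdlex <- function(message, class, ...) {
  abort(message, class = c(class, "crowdlex_error"), ...)
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

# scalar NA-tolerant coalesce for record fields
na_or <- function(x, default) if (is.null(x) || (length(x) == 1 && is.na(x))) default else x
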