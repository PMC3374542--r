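#' Round half away from zero
#'
#' Printed trial tables round 0.5 up (so 88.245 -> 88.25), unlike R's
#' banker's rounding. Used only at the presentation layer; internal values
#' stay unrounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Express a proportion as a display percentage
#'
#' @param p proportion in \[0, 1\].
#' @param digits decimal places (default 2, matching printed trial tables).
#' @return numeric percentage, rounded half-up.
#' @export
as_pct <- function(p, digits = 2) round_half_up(100 * p, digits)

# classed abort so callers can condition on failure mode
cb_abort <- function(message, class) {
  rlang::abort(message, class = c(paste0("cessbounds_", class), "cessbounds_error"))
}

check_count <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    cb_abort(sprintf("`%s` must contain non-negative integers.", name), "input_error")
  }
  invisible(x)
}

check_proportion <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    cb_abort(sprintf("`%s` must lie in [0, 1].", name), "input_error")
  }
  invisible(x)
}
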