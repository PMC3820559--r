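#' Round half away from zero
#'
#' Rounding convention used for all percentages quoted at printed precision:
#' ties go away from zero (`round_half_up(0.15, 1)` is 0.2), unlike base
#' [round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.5, 3.5, 35.26), c(0, 0, 1))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Percentage at fixed decimals, half-up (matches how clinical tables print).
pct <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-value scalar checks used by constructors/validators
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

is_probability <- function(x) {
  is_scalar_number(x) && x >= 0 && x <= 1
}

stop_input <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

# fold user-supplied enum tokens: trim, lower-case, "" -> NA (names kept)
fold_token <- function(x) {
  nm <- names(x)
  x <- trimws(tolower(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  names(x) <- nm
  x
}
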