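#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01 at 2 digits), the
#' convention used for the printed census percentages. Base R's `round()`
#' rounds half to even, which does not reproduce them.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# The twenty standard residues (no ambiguity codes).
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
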