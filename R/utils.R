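`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.35 -> 0.4 at one
#' decimal), matching how percentages are conventionally printed in tables.
#' Base \code{round()} uses round-half-even, which disagrees at ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# full-precision numeric formatting: 17 significant digits round-trips
# IEEE doubles exactly through as.numeric()
format_full <- function(x) sprintf("%.17g", x)
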