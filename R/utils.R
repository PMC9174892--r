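#' Wrap phase values into (-pi, pi]
#'
#' Maps arbitrary phase angles onto the principal interval used by
#' phase-contrast MRI reconstruction. The boundary convention is that +pi is
#' kept and -pi maps to +pi, matching `Arg(-1) == pi`.
#'
#' @param x numeric array of phase values (rad).
#' @return array of the same shape with values in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; printed-table reproduction needs
#' conventional half-up rounding (2.85 -> 2.9).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Median with midpoint interpolation for even counts (stats::median already
# does this for numeric input); kept as a named helper so regional reductions
# document the tie rule explicitly.
median_midpoint <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

# Derive a stream of 32-bit-safe child seeds from one master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
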