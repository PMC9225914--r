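# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used for the orthogonal-design tables (2 decimals,
#' half-up), where [base::round()]'s round-half-to-even rule would differ.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with the offending field named, so config errors are actionable
stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, positive = FALSE, nonneg = FALSE,
                      lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || !all(is.finite(x)))
    stop_field(field, "must be a finite numeric value")
  if (positive && any(x <= 0)) stop_field(field, "must be > 0")
  if (nonneg && any(x < 0)) stop_field(field, "must be >= 0")
  if (any(x < lower) || any(x > upper))
    stop_field(field, sprintf("must be in [%g, %g]", lower, upper))
  invisible(x)
}

# Celsius -> Kelvin; all tissue-side temperatures are stored in degrees C and
# converted only where the Stefan-Boltzmann law needs absolute temperature.
C_to_K <- function(temp_C) temp_C + 273.15

#' @importFrom stats approx optim rnorm runif sd setNames uniroot
#' @importFrom utils modifyList read.csv
NULL
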