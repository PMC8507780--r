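# Shared constants and small helpers.

#' The 20 canonical amino acids
#'
#' One-letter codes, alphabetical. Used as the row space of every
#' position-weight matrix and for sequence validation.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ratio conventions for species detected in a single SILAC channel:
# 256 for heavy-only (resistant line only), 0.01 for light-only.
RATIO_CAP_HEAVY <- 256
RATIO_CAP_LIGHT <- 0.01

#' Integer percentage, rounding half away from zero
#'
#' Computes `100 * numerator / denominator` and rounds to the nearest
#' integer, with exact halves rounded away from zero (so 86.5 -> 87), the
#' convention under which every summary percentage in this pipeline is
#' reported. Integer inputs are handled in exact integer arithmetic so
#' half-way cases are never decided by floating-point representation.
#'
#' @param numerator,denominator Nonnegative counts; `denominator` must be
#'   positive. Vectorized.
#' @return Integer percentage(s).
#' @examples
#' summary_percentages(1301, 1993)  # 65
#' summary_percentages(423, 489)    # 87 (86.50... rounds up)
#' @export
summary_percentages <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("summary_percentages(): denominator must be positive")
  }
  if (any(numerator < 0)) {
    stop("summary_percentages(): numerator must be nonnegative")
  }
  integral <- function(x) all(x == trunc(x)) && all(abs(x) < 2^52)
  if (integral(numerator) && integral(denominator)) {
    # floor((100*num + den/2) / den) done without division error
    as.integer((200 * numerator + denominator) %/% (2 * denominator))
  } else {
    as.integer(floor(100 * numerator / denominator + 0.5))
  }
}

# stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

# is a scalar probability-like value
is_fraction <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1
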