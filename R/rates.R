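# Success-rate arithmetic and binomial interval.

#' Round half away from zero
#'
#' Printed percentages use commercial rounding (half up), not banker's
#' rounding, so 72.85 prints as 72.9.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Eradication success rate
#'
#' `100 * n_success / (n_success + n_failed)`, the percentage of completed
#' success-or-fail operations that succeeded. Reinvaded and to-be-confirmed
#' events must already be excluded by the caller: a reinvasion is a
#' restoration failure, not an operational one, and enters neither count.
#'
#' @param n_success,n_failed non-negative counts (vectorised).
#' @param digits decimal places for the printed-value rounding (half up);
#'   `NULL` returns the unrounded percentage.
#' @return Percentage in `[0, 100]`; `NA` when both counts are zero
#'   (undefined, deliberately neither 0 nor 100).
#' @export
#' @examples
#' success_rate(545, 74)   # 88.0
#' success_rate(1081, 146) # 88.1
success_rate <- function(n_success, n_failed, digits = 1) {
  stopifnot(all(n_success >= 0, na.rm = TRUE), all(n_failed >= 0, na.rm = TRUE))
  denom <- n_success + n_failed
  pct <- ifelse(denom == 0, NA_real_, 100 * n_success / denom)
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval: never degenerate at 0 or 1 successes
#' and respects the `[0, 1]` range, which is why it is used for the annual
#' success-rate confidence shading.
#'
#' @param n_success successes (vectorised).
#' @param n_total trials, at least 1.
#' @param conf confidence level in (0, 1).
#' @return Tibble with columns `low`, `high` (proportions).
#' @export
rate_interval <- function(n_success, n_total, conf = 0.95) {
  stopifnot(conf > 0, conf < 1)
  if (any(n_total < 1)) stop("n_total must be at least 1")
  if (any(n_success < 0 | n_success > n_total)) {
    stop("n_success must lie in [0, n_total]")
  }
  z <- qnorm(1 - (1 - conf) / 2)
  p <- n_success / n_total
  denom <- 1 + z^2 / n_total
  centre <- (p + z^2 / (2 * n_total)) / denom
  half <- z * sqrt(p * (1 - p) / n_total + z^2 / (4 * n_total^2)) / denom
  tibble(low = pmax(0, centre - half), high = pmin(1, centre + half))
}
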