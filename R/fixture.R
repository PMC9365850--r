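# Published global summary counts (1872-2019), shipped as a fixture.

#' Published group count fixture
#'
#' The published global summary of invasive vertebrate eradication events,
#' 1872--2019: for each of the 13 target groups, the number of species and
#' islands targeted, total events, and events by outcome, plus the printed
#' success rate, with a totals row. Count columns for events and outcomes are
#' additive over groups; the islands total (998) counts each island once even
#' when it hosted events for several groups, so the islands column is not.
#' Area and habitation statistics are not carried (several printed cells are
#' typographically ambiguous in circulating copies); the fixture is a count
#' fixture.
#'
#' @return Tibble with one row per group plus a `total` row; columns `group`,
#'   `n_species`, `n_islands`, `n_events`, `n_successful`, `n_reinvaded`,
#'   `n_failed`, `success_rate_pct` (`NA` where fewer than 10 success or
#'   fail records).
#' @export
#' @examples
#' table1_fixture()
table1_fixture <- function() {
  rows <- tibble(
    group = group_levels(),
    n_species    = c(4L, 12L, 2L, 1L, 3L, 4L, 5L, 11L, 1L, 10L, 4L, 1L, 1L),
    n_islands    = c(666L, 147L, 105L, 86L, 80L, 64L, 60L, 32L, 29L, 16L, 15L, 3L, 1L),
    n_events     = c(820L, 185L, 117L, 91L, 89L, 69L, 66L, 39L, 30L, 24L, 15L, 4L, 1L),
    n_successful = c(545L, 150L, 80L, 51L, 74L, 59L, 49L, 25L, 24L, 14L, 8L, 1L, 1L),
    n_reinvaded  = c(135L, 4L, 5L, 7L, 1L, 2L, 7L, 0L, 1L, 0L, 4L, 1L, 0L),
    n_failed     = c(74L, 13L, 12L, 19L, 7L, 7L, 2L, 5L, 2L, 3L, 2L, 0L, 0L),
    success_rate_pct = c(88.0, 92.0, 87.0, 72.9, 91.4, 89.4, 96.1, 83.3,
                         92.3, 82.4, 80.0, NA, NA)
  )
  rows <- rows[order(-rows$n_events), , drop = FALSE]
  total <- tibble(
    group = "total",
    n_species = 59L, n_islands = 998L,
    n_events = 1550L, n_successful = 1081L, n_reinvaded = 167L,
    n_failed = 146L, success_rate_pct = 88.1)
  bind_rows(rows, total)
}
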