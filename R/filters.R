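# The five inclusion rules and their bookkeeping.

filter_rules <- function() {
  list(
    quality      = function(e) e$data_quality %in% c("good", "satisfactory"),
    whole_island = function(e) !is.na(e$whole_island) & e$whole_island,
    feral        = function(e) !is.na(e$feral) & e$feral,
    purpose      = function(e) !is.na(e$purpose_eradication) & e$purpose_eradication,
    status       = function(e) e$status %in% status_levels()
  )
}

#' Apply the standard inclusion filters
#'
#' Keeps events that pass all five inclusion rules: (1) data quality good or
#' satisfactory, (2) the entire island was treated, (3) the invasive
#' population was feral or semi-feral, (4) the purpose was eradication
#' (not a trial), and (5) the eradication status is one of the seven
#' recognised categories. Each excluded event is attributed to the first
#' failing rule in the fixed order quality, whole_island, feral, purpose,
#' status, so exclusion counts are well defined and sum to the number
#' excluded.
#'
#' @param events event tibble from [parse_events()].
#' @return A `filter_report`: list with `kept` (tibble), `excluded_by_rule`
#'   (named integer), `n_input`, `n_kept`.
#' @export
apply_inclusion_filters <- function(events) {
  rules <- filter_rules()
  n <- nrow(events)
  excluded <- setNames(integer(length(rules)), names(rules))
  alive <- rep(TRUE, n)
  for (r in names(rules)) {
    pass <- rules[[r]](events)
    fail_here <- alive & !pass
    excluded[[r]] <- sum(fail_here)
    alive <- alive & pass
  }
  structure(
    list(kept = events[alive, , drop = FALSE],
         excluded_by_rule = excluded,
         n_input = n,
         n_kept = sum(alive)),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Inclusion filter report\n")
  cat("  input events:", x$n_input, "\n")
  cat("  kept events: ", x$n_kept, "\n")
  for (r in names(x$excluded_by_rule)) {
    cat(sprintf("  excluded by %-12s %d\n", paste0(r, ":"), x$excluded_by_rule[[r]]))
  }
  invisible(x)
}

#' Write a filter report as key-count records
#'
#' @param report a `filter_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    key = c("n_input", "n_kept",
            paste0("excluded_", names(report$excluded_by_rule))),
    count = c(report$n_input, report$n_kept,
              unname(report$excluded_by_rule)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
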