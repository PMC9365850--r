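# Annual and cumulative metric series over the event table.

#' Assign fallback end years to undated non-final events
#'
#' Events still in the pipeline (in progress, to be confirmed, planned) often
#' have no end year; for the timeline analysis these are assigned a fallback
#' year (the final year of the study window) so contemporary activity is not
#' dropped. Undated events with any other status are left missing and
#' reported as issues, never guessed.
#'
#' @param events event tibble.
#' @param fallback_year year assigned to undated non-final events.
#' @return List with `events` (end years filled where the rule applies) and
#'   `issues` (tibble of rows left undated).
#' @export
assign_end_years <- function(events, fallback_year = 2019) {
  eligible <- c("in_progress", "to_be_confirmed", "planned")
  missing_year <- is.na(events$end_year)
  fill <- missing_year & events$status %in% eligible
  events$end_year[fill] <- as.integer(fallback_year)
  left <- which(missing_year & !fill)
  issues <- tibble(
    row = left,
    field = rep("end_year", length(left)),
    value = rep(NA_character_, length(left)),
    message = rep("missing end year on a completed/incomplete event", length(left)))
  list(events = events, issues = issues)
}

mode_statuses <- function(mode = c("all", "completed", "successful")) {
  mode <- match.arg(mode)
  switch(mode,
         all = status_levels(),
         completed = completed_statuses(),
         successful = "successful")
}

#' Annual metric series
#'
#' Buckets events by end year over an inclusive window and computes one of
#' the activity metrics: `events` (count), `area` (total hectares treated),
#' `countries` (distinct country codes active), `taxa` (distinct target
#' species), or `success_rate` (annual success proportion over completed
#' success-or-fail events, with a Wilson interval, defined only for years
#' with at least `min_events` such events). `mode` restricts the event set:
#' all seven statuses, the four completed statuses, or successful only;
#' the rate metric always uses successful + failed events.
#'
#' @param events event tibble with end years assigned.
#' @param metric one of `"events"`, `"area"`, `"countries"`, `"taxa"`,
#'   `"success_rate"`.
#' @param mode one of `"all"`, `"completed"`, `"successful"`.
#' @param window inclusive `c(start, end)` year window; events dated before
#'   the window (or undated) are excluded and counted in the attributes.
#' @param min_events minimum annual success+fail denominator for the rate.
#' @param conf confidence level for the rate interval.
#' @return An `annual_series` tibble with columns `year`, `value` (plus
#'   `n_success`, `n_failed`, `ci_low`, `ci_high` for the rate metric) and
#'   attributes `metric`, `mode`, `window`, `n_before_window`, `n_undated`.
#' @export
annual_series <- function(events,
                          metric = c("events", "area", "countries", "taxa",
                                     "success_rate"),
                          mode = c("all", "completed", "successful"),
                          window = c(1900, 2019),
                          min_events = 5,
                          conf = 0.95) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(length(window) == 2, window[1] <= window[2])
  years <- seq.int(window[1], window[2])

  n_undated <- sum(is.na(events$end_year))
  dated <- events[!is.na(events$end_year), , drop = FALSE]
  n_before <- sum(dated$end_year < window[1])
  n_after <- sum(dated$end_year > window[2])
  ev <- dated[dated$end_year >= window[1] & dated$end_year <= window[2], ,
              drop = FALSE]

  if (metric == "success_rate") {
    sf <- ev[ev$status %in% c("successful", "failed"), , drop = FALSE]
    n_s <- tapply_count(sf$end_year[sf$status == "successful"], years)
    n_f <- tapply_count(sf$end_year[sf$status == "failed"], years)
    denom <- n_s + n_f
    rate <- ifelse(denom >= min_events, n_s / denom, NA_real_)
    ci <- tibble(low = rep(NA_real_, length(years)),
                 high = rep(NA_real_, length(years)))
    ok <- which(denom >= min_events)
    if (length(ok)) ci[ok, ] <- rate_interval(n_s[ok], denom[ok], conf)
    out <- tibble(year = years, value = rate,
                  n_success = as.integer(n_s), n_failed = as.integer(n_f),
                  ci_low = ci$low, ci_high = ci$high)
  } else {
    ev <- ev[ev$status %in% mode_statuses(mode), , drop = FALSE]
    value <- switch(
      metric,
      events = tapply_count(ev$end_year, years),
      area = {
        v <- rep(0, length(years))
        if (nrow(ev)) {
          s <- tapply(ev$area_ha, factor(ev$end_year, levels = years), sum)
          v <- ifelse(is.na(s), 0, s)
        }
        as.numeric(v)
      },
      countries = distinct_count(ev$end_year, ev$country, years),
      taxa = distinct_count(ev$end_year, ev$target_species, years)
    )
    out <- tibble(year = years, value = value)
  }
  structure(out, metric = metric, mode = mode, window = window,
            n_before_window = n_before, n_after_window = n_after,
            n_undated = n_undated,
            class = c("annual_series", class(out)))
}

tapply_count <- function(event_years, years) {
  as.numeric(table(factor(event_years, levels = years)))
}

distinct_count <- function(event_years, keys, years) {
  if (!length(event_years)) return(rep(0, length(years)))
  u <- !duplicated(paste(event_years, keys, sep = "\r"))
  tapply_count(event_years[u], years)
}

#' Cumulative series
#'
#' Running sum of an annual count or area series. Rates cannot be cumulated.
#'
#' @param series an `annual_series` (or tibble with `year`, `value`).
#' @return The series with `value` replaced by its cumulative sum.
#' @export
cumulative_series <- function(series) {
  if (identical(attr(series, "metric"), "success_rate")) {
    stop("cumulating a rate series is meaningless")
  }
  series$value <- cumsum(series$value)
  series
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("Annual series: metric=%s mode=%s window=%d-%d\n",
              attr(x, "metric"), attr(x, "mode"),
              attr(x, "window")[1], attr(x, "window")[2]))
  NextMethod()
}

#' Annotate events with country-level classifications
#'
#' Left-joins a user-supplied lookup keyed by ISO 3166-1 alpha-2 code with
#' columns `sids` (Small Island Developing State flag) and `income`
#' (income category). Unmatched codes are annotated `unknown`, never dropped.
#'
#' @param events event tibble.
#' @param lookup data frame with columns `country`, `sids`, `income`.
#' @return The events with `sids` and `income` columns added.
#' @export
annotate_countries <- function(events, lookup) {
  need <- c("country", "sids", "income")
  if (!is.data.frame(lookup) || !all(need %in% names(lookup))) {
    stop("lookup must be a data frame with columns: ",
         paste(need, collapse = ", "))
  }
  lk <- as_tibble(lookup[, need])
  lk$country <- toupper(trimws(lk$country))
  if (anyDuplicated(lk$country)) stop("lookup has duplicated country codes")
  out <- left_join(events, lk, by = "country")
  out$sids[is.na(out$sids)] <- NA
  out$income[is.na(out$income)] <- "unknown"
  out
}
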