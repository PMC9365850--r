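# Group-level outcome summaries in the published-table layout.

#' Summarise events by target group
#'
#' For each target group: distinct species and islands targeted, events by
#' outcome, the success rate (successful / [successful + failed], reported
#' only for groups with at least `min_records` such records), area statistics
#' over successful events (median, mean, 5th/95th percentile, total, in
#' hectares), the uninhabited/inhabited split over successful events, and the
#' modal primary method over successful events with its count and share.
#' Rows are ordered by descending event count with a totals row last; in the
#' totals row, species and islands are distinct counts over all events (an
#' island targeted for several groups counts once), so those two columns are
#' not additive over groups.
#'
#' @param events filtered event tibble; groups are assigned from
#'   `target_species` via [assign_group()] unless a `target_group` column is
#'   already present.
#' @param min_records minimum success+fail records for a group rate.
#' @param dictionary species dictionary for group assignment.
#' @return Tibble with one row per (non-empty) group plus a `total` row.
#' @export
group_summary <- function(events, min_records = 10,
                          dictionary = species_dictionary()) {
  if (!nrow(events)) {
    return(empty_group_summary())
  }
  if (!"target_group" %in% names(events)) {
    events$target_group <- assign_group(events$target_species, dictionary)
  }
  rows <- lapply(split(events, factor(events$target_group, group_levels())),
                 summarise_one_group, min_records = min_records)
  out <- bind_rows(rows, .id = "group")
  out <- out[out$n_events > 0, , drop = FALSE]
  out <- out[order(-out$n_events), , drop = FALSE]

  total <- summarise_one_group(events, min_records = min_records)
  total$group <- "total"
  # distinct counts across all events, not sums of per-group distincts
  bind_rows(out, total[, names(out)])
}

summarise_one_group <- function(ev, min_records) {
  succ <- ev[ev$status == "successful", , drop = FALSE]
  n_s <- sum(ev$status == "successful")
  n_f <- sum(ev$status == "failed")
  area <- succ$area_ha[!is.na(succ$area_ha)]
  modal <- modal_method(succ$primary_method)
  tibble(
    n_species = n_distinct(ev$target_species),
    n_islands = n_distinct(ev$island_id),
    n_events = nrow(ev),
    n_successful = n_s,
    n_reinvaded = sum(ev$status == "reinvaded"),
    n_failed = n_f,
    success_rate_pct = if (n_s + n_f >= min_records)
      success_rate(n_s, n_f) else NA_real_,
    area_median_ha = if (length(area)) median(area) else NA_real_,
    area_mean_ha = if (length(area)) mean(area) else NA_real_,
    area_p5_ha = if (length(area)) unname(quantile(area, 0.05, type = 7)) else NA_real_,
    area_p95_ha = if (length(area)) unname(quantile(area, 0.95, type = 7)) else NA_real_,
    area_total_ha = if (length(area)) sum(area) else NA_real_,
    n_uninhabited = sum(succ$habitation == "0", na.rm = TRUE),
    n_inhabited = sum(!succ$habitation %in% c("0", "not_found"), na.rm = TRUE),
    primary_method = modal$method,
    primary_method_n = modal$n,
    primary_method_pct = modal$pct
  )
}

modal_method <- function(methods) {
  methods <- methods[!is.na(methods) & methods != "unknown"]
  if (!length(methods)) {
    return(list(method = NA_character_, n = 0L, pct = NA_real_))
  }
  tab <- sort(table(methods), decreasing = TRUE)
  list(method = names(tab)[1], n = as.integer(tab[1]),
       pct = round_half_up(100 * tab[[1]] / length(methods), 0))
}

empty_group_summary <- function() {
  tibble(group = character(), n_species = integer(), n_islands = integer(),
         n_events = integer(), n_successful = integer(),
         n_reinvaded = integer(), n_failed = integer(),
         success_rate_pct = numeric(), area_median_ha = numeric(),
         area_mean_ha = numeric(), area_p5_ha = numeric(),
         area_p95_ha = numeric(), area_total_ha = numeric(),
         n_uninhabited = integer(), n_inhabited = integer(),
         primary_method = character(), primary_method_n = integer(),
         primary_method_pct = numeric())
}
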