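# Controlled vocabularies: eradication statuses, target groups, and the
# packaged species -> group dictionary.

#' Eradication status categories
#'
#' The seven recognised eradication statuses. An operation is *completed*
#' when its outcome is final enough to enter success-rate accounting:
#' successful, reinvaded (successful but the target later re-established),
#' to-be-confirmed, or failed. In-progress, incomplete, and planned
#' operations are not completed.
#'
#' @return Character vector of the seven status codes.
#' @export
#' @examples
#' status_levels()
status_levels <- function() {
  c("successful", "reinvaded", "failed", "to_be_confirmed",
    "in_progress", "incomplete", "planned")
}

#' @rdname status_levels
#' @export
completed_statuses <- function() {
  c("successful", "reinvaded", "failed", "to_be_confirmed")
}

#' @param status character vector of status codes.
#' @rdname status_levels
#' @export
is_completed_status <- function(status) {
  status %in% completed_statuses()
}

# Raw DIISE-dialect status strings -> canonical codes. Matching is
# case/punctuation-insensitive (see normalize_token).
status_alias_table <- function() {
  c(
    "successful"                             = "successful",
    "success"                                = "successful",
    "successful and subsequently reinvaded"  = "reinvaded",
    "successful but subsequently reinvaded"  = "reinvaded",
    "reinvaded"                              = "reinvaded",
    "failed"                                 = "failed",
    "failure"                                = "failed",
    "to be confirmed"                        = "to_be_confirmed",
    "in progress"                            = "in_progress",
    "ongoing"                                = "in_progress",
    "incomplete"                             = "incomplete",
    "planned"                                = "planned"
  )
}

# lowercase, collapse punctuation/underscores to single spaces
normalize_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]_]+", " ", x)
  gsub("[[:space:]]+", " ", x)
}

canonical_status <- function(raw) {
  tab <- status_alias_table()
  names(tab) <- normalize_token(names(tab))
  unname(tab[normalize_token(raw)])
}

#' Invasive target groups
#'
#' The 13 taxon groups used to summarise eradication targets: nine invasive
#' mammal groups (rats cover the genus *Rattus* only; mice cover
#' *Mus musculus* only), birds split by flight capability, and one group
#' each for frogs/toads and lizards.
#'
#' @return Character vector of the 13 group codes.
#' @export
group_levels <- function() {
  c("rats", "ungulates", "cats", "mice", "rabbits_hares", "dogs_foxes",
    "stoats_weasels_mink_mongoose", "other_mammals", "pigs",
    "flying_birds", "non_flying_birds", "frogs_toads", "lizards")
}

#' Packaged species-to-group dictionary
#'
#' Reads the species dictionary shipped with the package (or a user-supplied
#' extension in the same format). One row per scientific name with its target
#' group, taxon class, and, for birds, a flight-capability flag that routes
#' the species to the flying or non-flying bird group.
#'
#' @param path optional path to a dictionary CSV with columns
#'   `species,group,taxon_class,flying`; defaults to the packaged table.
#' @return A tibble with columns `species`, `group`, `taxon_class`, `flying`.
#' @export
species_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_groups.csv", package = "islerad")
  }
  dict <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("species", "group", "taxon_class", "flying")
  if (!all(need %in% names(dict))) {
    stop("species dictionary must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(dict$group), group_levels())
  if (length(bad)) stop("unknown groups in dictionary: ", paste(bad, collapse = ", "))
  dict
}

#' Assign a target species to its group
#'
#' Case-insensitive lookup against the species dictionary. Birds are routed
#' to `flying_birds`/`non_flying_birds` by the dictionary's flight flag.
#' Species missing from the dictionary are "unmapped": with
#' `unmapped = "error"` (default) this is a hard error; with
#' `unmapped = "other_mammals_if_mammal"` unmapped species declared to be
#' mammals via `taxon_class` fall back to `other_mammals` and anything else
#' still errors; with `unmapped = "na"` an `NA` is returned.
#'
#' @param species character vector of scientific names.
#' @param dictionary dictionary tibble, see [species_dictionary()].
#' @param unmapped one of `"error"`, `"other_mammals_if_mammal"`, `"na"`.
#' @param taxon_class optional character vector (recycled) giving the taxon
#'   class of each species, used only by the mammal fallback.
#' @return Character vector of group codes (factor levels per [group_levels()]).
#' @export
#' @examples
#' assign_group(c("Rattus norvegicus", "Mus musculus", "Gallirallus australis"))
assign_group <- function(species,
                         dictionary = species_dictionary(),
                         unmapped = c("error", "other_mammals_if_mammal", "na"),
                         taxon_class = NULL) {
  unmapped <- match.arg(unmapped)
  key <- normalize_token(species)
  idx <- match(key, normalize_token(dictionary$species))
  out <- dictionary$group[idx]
  miss <- is.na(idx)
  if (any(miss)) {
    if (unmapped == "error") {
      stop("unmapped species: ", paste(unique(species[miss]), collapse = ", "))
    }
    if (unmapped == "other_mammals_if_mammal") {
      cls <- if (is.null(taxon_class)) rep(NA_character_, length(species)) else
        rep_len(tolower(taxon_class), length(species))
      is_mam <- miss & !is.na(cls) & cls == "mammal"
      out[is_mam] <- "other_mammals"
      still <- miss & !is_mam
      if (any(still)) {
        stop("unmapped non-mammal species: ",
             paste(unique(species[still]), collapse = ", "))
      }
    }
  }
  out
}
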