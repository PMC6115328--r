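#' Read a species registry table
#'
#' Expected columns: `species_id`, `name`, `who_category` (1 or 2),
#' `has_eor` (logical). Optional: `antivenom_available`.
#'
#' @param path CSV file path.
#' @return A tibble, schema-checked.
#' @export
read_species_registry <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species_id", "name", "who_category", "has_eor")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("registry %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (!all(df$who_category %in% c(1L, 2L))) {
    abort("who_category must be 1 or 2 for every species")
  }
  df$species_id <- as.character(df$species_id)
  df$has_eor <- as.logical(df$has_eor)
  df
}

#' Read occurrence records
#'
#' Expected columns: `species_id`, `year`, `lat`, `lon`; optional `source`.
#' Coordinates are parsed as numeric; malformed values become `NA` and the
#' affected records are later removed (with a tally) by
#' [dedup_occurrences()].
#'
#' @param path CSV file path.
#' @return A tibble of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species_id", "year", "lat", "lon")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("occurrence file %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  df$species_id <- as.character(df$species_id)
  df$lat <- suppressWarnings(as.numeric(df$lat))
  df$lon <- suppressWarnings(as.numeric(df$lon))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df
}

#' Clean and deduplicate occurrence records
#'
#' Removes records missing either coordinate, records with out-of-range
#' coordinates (|lat| > 90 or |lon| > 180), and duplicates. Two records of
#' one species are duplicates when their (collection year, latitude,
#' longitude) tuples coincide, with coordinates compared after rounding to
#' 6 decimal places; records with a missing year only collide with other
#' missing-year records at the same coordinates. The first occurrence of
#' each tuple is retained, in input order. The operation is idempotent.
#'
#' @param records Tibble with columns `species_id`, `year`, `lat`, `lon`.
#' @param quiet Suppress the drop-tally message.
#' @return The retained records, with attribute `"dropped"` holding a tibble
#'   of per-reason drop counts.
#' @export
dedup_occurrences <- function(records, quiet = FALSE) {
  n0 <- nrow(records)
  bad_missing <- is.na(records$lat) | is.na(records$lon)
  bad_range <- !bad_missing &
    (records$lat < -90 | records$lat > 90 |
       records$lon < -180 | records$lon > 180)
  keep <- records[!(bad_missing | bad_range), , drop = FALSE]
  key <- paste(keep$species_id,
               ifelse(is.na(keep$year), "<NA>", as.character(keep$year)),
               sprintf("%.6f", round(keep$lat, 6)),
               sprintf("%.6f", round(keep$lon, 6)),
               sep = "|")
  dup <- duplicated(key)
  out <- keep[!dup, , drop = FALSE]
  dropped <- tibble(
    reason = c("missing_coordinate", "out_of_range", "duplicate"),
    n = c(sum(bad_missing), sum(bad_range), sum(dup)))
  if (!quiet && n0 > nrow(out)) {
    inform(sprintf(
      "dedup_occurrences: kept %d of %d (%d missing coordinate, %d out of range, %d duplicate)",
      nrow(out), n0, dropped$n[1], dropped$n[2], dropped$n[3]))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Assign data-availability groups
#'
#' Species fall into three groups: A (no expert-opinion range map and no
#' occurrence records — excluded from mapping), B (range map but fewer than
#' `min_records` post-deduplication records), and C (range map and at least
#' `min_records` records). Species with records but no range map cannot be
#' mapped and are assigned to the excluded group A with a warning.
#'
#' @param has_eor Logical: an expert-opinion range map exists.
#' @param n_records Nonnegative integer count of deduplicated records.
#' @param min_records Group-C threshold (default 5).
#' @return Character vector of `"A"`, `"B"` or `"C"`.
#' @export
assign_group <- function(has_eor, n_records, min_records = 5) {
  stopifnot(length(has_eor) == length(n_records), all(n_records >= 0))
  out <- ifelse(!has_eor, "A", ifelse(n_records < min_records, "B", "C"))
  orphans <- !has_eor & n_records > 0
  if (any(orphans)) {
    warn(sprintf(
      "%d species have occurrence records but no range map; excluded (group A)",
      sum(orphans)))
  }
  out
}

#' Join antivenom availability onto the registry
#'
#' @param species Registry tibble with `species_id`.
#' @param antivenom_table Tibble with `species_id` and logical
#'   `antivenom_available`, or a named logical vector.
#' @param default Availability assumed for species absent from the table
#'   (default `FALSE`: no listed therapy).
#' @return The registry with an `antivenom_available` column.
#' @export
join_antivenom <- function(species, antivenom_table, default = FALSE) {
  if (!is.data.frame(antivenom_table)) {
    antivenom_table <- tibble(species_id = names(antivenom_table),
                              antivenom_available = as.logical(antivenom_table))
  }
  antivenom_table$species_id <- as.character(antivenom_table$species_id)
  species$antivenom_available <- NULL
  out <- left_join(species, antivenom_table[, c("species_id", "antivenom_available")],
                   by = "species_id")
  out$antivenom_available[is.na(out$antivenom_available)] <- default
  out
}

#' Summarise the registry by group, category and antivenom status
#'
#' @param species Registry tibble with `group` and `who_category` columns
#'   (and optionally `antivenom_available`).
#' @return A one-row tibble of counts: totals per group, the included total
#'   (groups B + C), per-category included counts, and antivenom tallies
#'   over included species when the flag is present.
#' @export
summarize_registry <- function(species) {
  grp <- factor(species$group, levels = c("A", "B", "C"))
  inc <- species[!is.na(grp) & grp %in% c("B", "C"), , drop = FALSE]
  out <- tibble(
    n_total = nrow(species),
    n_group_a = sum(grp == "A", na.rm = TRUE),
    n_group_b = sum(grp == "B", na.rm = TRUE),
    n_group_c = sum(grp == "C", na.rm = TRUE),
    n_included = nrow(inc),
    n_category1 = sum(inc$who_category == 1),
    n_category2 = sum(inc$who_category == 2))
  if ("antivenom_available" %in% names(species)) {
    out$n_antivenom_available <- sum(inc$antivenom_available)
    out$n_no_therapy <- sum(!inc$antivenom_available)
    out$n_no_therapy_cat1 <- sum(!inc$antivenom_available & inc$who_category == 1)
    out$n_no_therapy_cat2 <- sum(!inc$antivenom_available & inc$who_category == 2)
  }
  out
}

#' Build the working registry from raw inputs
#'
#' Convenience wrapper: deduplicates occurrences, counts records per
#' species (records for species absent from the registry are dropped with
#' a warning), assigns groups, and joins antivenom availability.
#'
#' @param registry Registry tibble (see [read_species_registry()]).
#' @param occurrences Occurrence tibble (see [read_occurrences()]).
#' @param antivenom_table Optional availability table for
#'   [join_antivenom()].
#' @param min_records Group-C record threshold.
#' @param quiet Suppress tally messages.
#' @return A list with elements `species` (registry with `n_records`,
#'   `group`, `antivenom_available`), `occurrences` (deduplicated, limited
#'   to registry species), and `summary` ([summarize_registry()] output).
#' @export
build_registry <- function(registry, occurrences, antivenom_table = NULL,
                           min_records = 5, quiet = FALSE) {
  occ <- dedup_occurrences(occurrences, quiet = quiet)
  unknown <- !occ$species_id %in% registry$species_id
  if (any(unknown)) {
    warn(sprintf("%d occurrence records match no registry species; dropped",
                 sum(unknown)))
    occ <- occ[!unknown, , drop = FALSE]
  }
  counts <- occ %>% group_by(.data$species_id) %>%
    summarise(n_records = dplyr::n(), .groups = "drop")
  species <- registry %>%
    left_join(counts, by = "species_id") %>%
    mutate(n_records = as.integer(ifelse(is.na(.data$n_records), 0L, .data$n_records)),
           group = assign_group(.data$has_eor, .data$n_records, min_records))
  if (!is.null(antivenom_table)) {
    species <- join_antivenom(species, antivenom_table)
  }
  list(species = species, occurrences = occ,
       summary = summarize_registry(species))
}
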