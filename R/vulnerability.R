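#' Compose a vulnerability mask
#'
#' A cell is vulnerable when it lies within the range of at least one
#' species in the chosen richness stratum, is more remote than the travel
#' threshold, and falls in one of the selected HAQ deciles. Nodata in any
#' layer makes the cell not vulnerable.
#'
#' @param richness Richness [grid_raster()] (the no-therapy stratum when
#'   vulnerability to untreatable species is wanted).
#' @param travel_mask Logical [grid_raster()] from
#'   [classify_travel_time()].
#' @param decile_raster Integer decile [grid_raster()] from
#'   [rasterize_deciles()].
#' @param deciles Set of decile indices counted as vulnerable (default
#'   1:3, the lowest-quality tercile of deciles).
#' @return A logical [grid_raster()].
#' @export
vulnerability_mask <- function(richness, travel_mask, decile_raster,
                               deciles = 1:3) {
  check_same_grid(richness, travel_mask, "richness", "travel mask")
  check_same_grid(richness, decile_raster, "richness", "decile raster")
  stopifnot(all(deciles %in% 1:10))
  v <- !is.na(richness$values) & richness$values >= 1
  tm <- travel_mask$values; tm[is.na(tm)] <- FALSE
  dm <- matrix(decile_raster$values %in% deciles,
               nrow(decile_raster$values), ncol(decile_raster$values))
  grid_raster(richness$grid, v & tm & dm, name = "vulnerable")
}

#' Total population within range, with optional filters
#'
#' Sums the population over cells with richness of at least one, optionally
#' restricted to remote cells and/or selected HAQ deciles. Adding a filter
#' never increases the total.
#'
#' @param richness Richness [grid_raster()].
#' @param population Population [grid_raster()] (persons per cell).
#' @param travel_mask Optional logical [grid_raster()].
#' @param decile_raster,deciles Optional decile filter.
#' @return A scalar (persons, unrounded).
#' @export
population_within_range <- function(richness, population, travel_mask = NULL,
                                    decile_raster = NULL, deciles = NULL) {
  check_same_grid(richness, population, "richness", "population")
  sel <- !is.na(richness$values) & richness$values >= 1
  if (!is.null(travel_mask)) {
    check_same_grid(richness, travel_mask, "richness", "travel mask")
    tm <- travel_mask$values; tm[is.na(tm)] <- FALSE
    sel <- sel & tm
  }
  if (!is.null(decile_raster)) {
    check_same_grid(richness, decile_raster, "richness", "decile raster")
    sel <- sel & matrix(decile_raster$values %in% deciles,
                        nrow(sel), ncol(sel))
  }
  sum(population$values[sel], na.rm = TRUE)
}

#' Enumerate masked population per admin unit
#'
#' Sums persons over masked cells, assigned to admin units by cell centre.
#' Cells whose centres fall outside every polygon land in an
#' `"unassigned"` row rather than being dropped silently.
#'
#' @param mask Logical [grid_raster()].
#' @param population Population [grid_raster()].
#' @param admin A precomputed [rasterize_admin()] result, or a
#'   [poly_set()] of admin polygons (rasterized on the fly).
#' @return Tibble with `admin_unit` and `population` (unrounded), one row
#'   per unit (zero rows included) plus `"unassigned"` when applicable.
#' @export
enumerate_population <- function(mask, population, admin) {
  check_same_grid(mask, population, "mask", "population")
  if (inherits(admin, "poly_set")) admin <- rasterize_admin(admin, mask$grid)
  check_same_grid(mask, admin$raster, "mask", "admin raster")
  m <- mask$values; m[is.na(m)] <- FALSE
  pop <- population$values; pop[is.na(pop)] <- 0
  idx <- admin$raster$values
  contrib <- pop * m
  sums <- vapply(seq_along(admin$units),
                 function(i) sum(contrib[!is.na(idx) & idx == i]), numeric(1))
  out <- tibble(admin_unit = admin$units, population = sums)
  un <- sum(contrib[is.na(idx)])
  if (un > 0) out <- bind_rows(out, tibble(admin_unit = "unassigned", population = un))
  out
}

#' Build the full vulnerability report
#'
#' Per admin-2 unit: vulnerable population against all included species,
#' vulnerable population against no-therapy species, total population in
#' range of any species, and the share of the unit's population that is
#' vulnerable. Country and decile columns come from the admin-unit lookup
#' table. Populations are kept as reals; rounding to whole persons is
#' deferred to report writing.
#'
#' @param richness_all Richness layer over all included species.
#' @param richness_no_therapy Richness layer over species lacking
#'   antivenom.
#' @param travel_mask Logical remoteness [grid_raster()].
#' @param decile_raster Integer decile [grid_raster()].
#' @param population Population [grid_raster()].
#' @param admin A [rasterize_admin()] result (or `poly_set`) at admin-2
#'   granularity.
#' @param admin_table Tibble keying `admin_unit` to `country` and `decile`.
#' @param deciles Deciles counted as vulnerable (default 1:3).
#' @return A `vulnerability_report` tibble: one row per admin-2 unit with
#'   `admin_unit`, `country`, `decile`, `population_vulnerable_all_species`,
#'   `population_vulnerable_no_therapy`, `population_in_range`,
#'   `population_total`, `percent_of_unit_population`.
#' @export
vulnerability_report <- function(richness_all, richness_no_therapy,
                                 travel_mask, decile_raster, population,
                                 admin, admin_table, deciles = 1:3) {
  if (inherits(admin, "poly_set")) admin <- rasterize_admin(admin, population$grid)
  mask_all <- vulnerability_mask(richness_all, travel_mask, decile_raster, deciles)
  mask_nt <- vulnerability_mask(richness_no_therapy, travel_mask, decile_raster, deciles)
  in_range <- grid_raster(richness_all$grid,
                          !is.na(richness_all$values) & richness_all$values >= 1)
  everywhere <- grid_raster(population$grid,
                            matrix(TRUE, population$grid$nrow, population$grid$ncol))
  tab <- enumerate_population(mask_all, population, admin) %>%
    dplyr::rename(population_vulnerable_all_species = "population") %>%
    left_join(enumerate_population(mask_nt, population, admin) %>%
                dplyr::rename(population_vulnerable_no_therapy = "population"),
              by = "admin_unit") %>%
    left_join(enumerate_population(in_range, population, admin) %>%
                dplyr::rename(population_in_range = "population"),
              by = "admin_unit") %>%
    left_join(enumerate_population(everywhere, population, admin) %>%
                dplyr::rename(population_total = "population"),
              by = "admin_unit")
  tab[is.na(tab)] <- 0
  out <- tab %>%
    left_join(admin_table, by = "admin_unit") %>%
    mutate(percent_of_unit_population = ifelse(
      .data$population_total > 0,
      100 * .data$population_vulnerable_all_species / .data$population_total, 0)) %>%
    relocate("admin_unit", "country", "decile")
  class(out) <- c("vulnerability_report", class(out))
  out
}

#' Aggregate a vulnerability report to countries
#'
#' @param report A [vulnerability_report()] tibble.
#' @return One row per country (each country carries one decile).
#' @export
country_summary <- function(report) {
  report %>%
    filter(!is.na(.data$country)) %>%
    group_by(.data$country, .data$decile) %>%
    summarise(across(dplyr::starts_with("population"), sum), .groups = "drop")
}

#' Country-by-decile vulnerability matrix
#'
#' Pivots per-country vulnerable counts into a wide matrix with one column
#' per HAQ decile and a `Total` row, mirroring tabular reporting of
#' vulnerable population per decile. Each country contributes to exactly
#' one decile column. Counts are rounded half-up to whole persons at this
#' (reporting) step; countries whose counts are all zero are omitted.
#'
#' @param data A [vulnerability_report()], or any tibble with `country`,
#'   `decile` and the value column.
#' @param value Column to tabulate (default
#'   `population_vulnerable_no_therapy`; ignored if absent and a `count`
#'   column exists).
#' @param drop_zero Omit all-zero countries (default `TRUE`).
#' @return Tibble: `country`, `decile_1` ... `decile_10`, with a final
#'   `Total` row; attribute `"grand_total"` holds the overall sum.
#' @export
decile_table <- function(data, value = "population_vulnerable_no_therapy",
                         drop_zero = TRUE) {
  if (!value %in% names(data) && "count" %in% names(data)) value <- "count"
  if (!all(c("country", "decile") %in% names(data))) {
    abort("data needs columns country and decile")
  }
  long <- data %>%
    filter(!is.na(.data$country)) %>%
    group_by(.data$country, .data$decile) %>%
    summarise(n = round_half_up(sum(.data[[value]])), .groups = "drop")
  if (drop_zero) {
    nonzero <- long %>% group_by(.data$country) %>%
      summarise(tot = sum(.data$n), .groups = "drop") %>%
      filter(.data$tot > 0) %>% pull("country")
    long <- long %>% filter(.data$country %in% nonzero)
  }
  wide <- long %>%
    mutate(decile = factor(.data$decile, levels = 1:10)) %>%
    tidyr::pivot_wider(names_from = "decile", values_from = "n",
                       names_prefix = "decile_", values_fill = 0,
                       names_expand = TRUE) %>%
    arrange(.data$country)
  dec_cols <- paste0("decile_", 1:10)
  totals <- vapply(dec_cols, function(cn) sum(wide[[cn]]), numeric(1))
  out <- bind_rows(wide, tibble(country = "Total", !!!as.list(totals)))
  attr(out, "grand_total") <- sum(totals)
  out
}

# round half away from zero (reports print integer persons)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' @export
autoplot.vulnerability_report <- function(object, ...) {
  df <- country_summary(object) %>%
    tidyr::pivot_longer(c("population_vulnerable_all_species",
                          "population_vulnerable_no_therapy"),
                        names_to = "stratum", values_to = "population")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$country, .data$population),
                                   y = .data$population, fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "vulnerable population (persons)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
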