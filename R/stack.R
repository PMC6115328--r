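#' Stack species range rasters into a richness layer
#'
#' Sums per-species presence rasters cell-wise, yielding a species-count
#' (richness) layer. Cells where every contributing raster is nodata are
#' nodata; a cell with any valid input is a valid count (species with
#' nodata there are treated as absent).
#'
#' @param rasters Named list of logical/0-1 [grid_raster()]s, one per
#'   species, sharing one grid. Names are species ids.
#' @param species_ids Optional character vector restricting which rasters
#'   are stacked (a stratum filter); defaults to all.
#' @param name Layer name for the output.
#' @return An integer-valued [grid_raster()].
#' @export
stack_ranges <- function(rasters, species_ids = NULL, name = "richness") {
  stopifnot(length(rasters) >= 1 || !is.null(species_ids))
  if (is.null(species_ids)) species_ids <- names(rasters)
  use <- rasters[intersect(species_ids, names(rasters))]
  grid <- if (length(rasters)) rasters[[1]]$grid else abort("no rasters supplied")
  for (r in use) check_same_grid(grid, r, "analysis grid", "species raster")
  counts <- matrix(0L, grid$nrow, grid$ncol)
  any_valid <- matrix(length(use) == 0, grid$nrow, grid$ncol)
  for (r in use) {
    v <- r$values
    valid <- !is.na(v)
    any_valid <- any_valid | valid
    counts[valid] <- counts[valid] + as.integer(v[valid])
  }
  counts[!any_valid] <- NA_integer_
  grid_raster(grid, counts, name = name)
}

#' Composite richness layers by WHO medical category
#'
#' Produces the three composite layers: all included species, category-one
#' species only, and category-two species only. Because every species is in
#' exactly one category, the category layers add cell-wise to the overall
#' layer.
#'
#' @param rasters Named list of per-species presence rasters.
#' @param species Registry tibble with `species_id` and `who_category`.
#' @return A named list of [grid_raster()]s: `all`, `category1`,
#'   `category2`.
#' @export
composite_layers <- function(rasters, species) {
  ids <- intersect(names(rasters), species$species_id)
  cat1 <- species$species_id[species$who_category == 1]
  cat2 <- species$species_id[species$who_category == 2]
  list(
    all = stack_ranges(rasters, ids, name = "richness_all"),
    category1 = stack_ranges(rasters, intersect(ids, cat1), name = "richness_category1"),
    category2 = stack_ranges(rasters, intersect(ids, cat2), name = "richness_category2"))
}

#' Richness layers restricted to species lacking antivenom
#'
#' @param rasters Named list of per-species presence rasters.
#' @param species Registry tibble with `species_id`, `who_category` and
#'   `antivenom_available`.
#' @return A named list of [grid_raster()]s over no-therapy species:
#'   `all`, `category1`, `category2`. Each is cell-wise bounded above by
#'   the corresponding unrestricted layer.
#' @export
no_therapy_layers <- function(rasters, species) {
  nt <- species[!species$antivenom_available, , drop = FALSE]
  ids <- intersect(names(rasters), nt$species_id)
  list(
    all = stack_ranges(rasters, ids, name = "richness_no_antivenom_all"),
    category1 = stack_ranges(rasters, intersect(ids, nt$species_id[nt$who_category == 1]),
                             name = "richness_no_antivenom_cat1"),
    category2 = stack_ranges(rasters, intersect(ids, nt$species_id[nt$who_category == 2]),
                             name = "richness_no_antivenom_cat2"))
}

#' Per-stratum richness summary
#'
#' @param layers Named list of richness [grid_raster()]s.
#' @return Tibble with one row per stratum: global maximum count, number of
#'   occupied cells, number of valid cells.
#' @export
richness_summary <- function(layers) {
  bind_rows(lapply(names(layers), function(nm) {
    v <- layers[[nm]]$values
    tibble(stratum = nm,
           max_count = if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE),
           occupied_cells = sum(v >= 1, na.rm = TRUE),
           valid_cells = sum(!is.na(v)))
  }))
}
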