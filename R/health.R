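#' Read a health-unit (HAQ Index) table
#'
#' Expected columns: `unit_id`, `parent_country` (empty/NA for national
#' units), `level` (`"national"` or `"subnational"`), `haq_value` (0-100).
#'
#' @param path CSV file path.
#' @return A tibble, schema-checked.
#' @export
read_haq_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("unit_id", "parent_country", "level", "haq_value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("HAQ table %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (!all(df$level %in% c("national", "subnational"))) {
    abort("level must be 'national' or 'subnational'")
  }
  df$unit_id <- as.character(df$unit_id)
  df$parent_country <- as.character(df$parent_country)
  df
}

#' Assign HAQ Index deciles to national units
#'
#' Countries are ranked ascending by HAQ value (ties broken by `unit_id`
#' order, deterministically); the country at rank `r` of `N` receives
#' decile `floor(10 * (r - 1) / N) + 1`, so decile 1 holds the lowest
#' values and group sizes differ by at most one. The per-decile value
#' thresholds (maximum value in each decile) are recorded for subsequent
#' subnational assignment.
#'
#' @param countries Tibble of national units with `unit_id` and
#'   `haq_value`; at least 10 rows.
#' @return The input with a `decile` column, plus attribute
#'   `"thresholds"`: a tibble of `decile` and `upper` value bounds (see
#'   [haq_thresholds()]).
#' @export
assign_haq_deciles <- function(countries) {
  if (nrow(countries) < 10) {
    abort(sprintf("need >= 10 national units to build deciles (got %d)",
                  nrow(countries)))
  }
  ord <- order(countries$haq_value, countries$unit_id)
  n <- nrow(countries)
  decile <- integer(n)
  decile[ord] <- floor(10 * (seq_len(n) - 1) / n) + 1L
  countries$decile <- decile
  thresholds <- countries %>%
    group_by(.data$decile) %>%
    summarise(upper = max(.data$haq_value), .groups = "drop") %>%
    arrange(.data$decile)
  attr(countries, "thresholds") <- thresholds
  countries
}

#' Extract decile thresholds from a decile assignment
#'
#' @param countries Output of [assign_haq_deciles()].
#' @return Tibble with `decile` (1-10) and `upper` (maximum national HAQ
#'   value in that decile).
#' @export
haq_thresholds <- function(countries) {
  th <- attr(countries, "thresholds")
  if (is.null(th)) abort("no thresholds attribute; run assign_haq_deciles() first")
  th
}

#' Assign subnational units to nationally derived deciles
#'
#' Each subnational unit receives the decile whose national value interval
#' `(lower, upper]` contains its HAQ value; values at or below the bottom
#' threshold clamp to decile 1 and values above the top threshold to
#' decile 10. Subnational values never re-rank the national thresholds.
#'
#' @param subnationals Tibble with `unit_id` and `haq_value`.
#' @param thresholds Threshold tibble from [haq_thresholds()].
#' @return The input with a `decile` column.
#' @export
assign_subnational_deciles <- function(subnationals, thresholds) {
  upper <- thresholds$upper[order(thresholds$decile)]
  dec <- sort(thresholds$decile)
  subnationals$decile <- vapply(subnationals$haq_value, function(v) {
    hit <- which(v <= upper)
    as.integer(if (length(hit) == 0) dec[length(dec)] else dec[hit[1]])
  }, integer(1))
  subnationals
}

#' Assign deciles to a mixed national/subnational HAQ table
#'
#' @param units HAQ tibble (see [read_haq_table()]).
#' @return The table with deciles: nationals via [assign_haq_deciles()],
#'   subnationals via [assign_subnational_deciles()]; thresholds attached
#'   as the `"thresholds"` attribute.
#' @export
assign_deciles <- function(units) {
  nat <- assign_haq_deciles(units[units$level == "national", , drop = FALSE])
  th <- haq_thresholds(nat)
  sub <- units[units$level == "subnational", , drop = FALSE]
  if (nrow(sub) > 0) sub <- assign_subnational_deciles(sub, th)
  out <- bind_rows(nat, sub)
  attr(out, "thresholds") <- th
  out
}

#' Rasterize admin polygons to a unit-index raster
#'
#' Each cell is assigned to the first listed feature containing its centre
#' (a deterministic tie rule for shared borders); cells outside every
#' polygon are nodata.
#'
#' @param polys A [poly_set()] whose `feature_id`s key admin units.
#' @param grid A [grid_spec()].
#' @return A list: `raster` (integer [grid_raster()] of indices into
#'   `units`), `units` (character vector of feature ids in assignment
#'   order).
#' @export
rasterize_admin <- function(polys, grid) {
  units <- unique(polys$feature_id)
  cc <- cell_centres(grid)
  idx <- rep(NA_integer_, nrow(cc))
  for (i in seq_along(units)) {
    feat <- polys[polys$feature_id == units[i], ]
    open <- is.na(idx)
    if (!any(open)) break
    hit <- points_in_poly(feat, cc$x[open], cc$y[open])
    idx[which(open)[hit]] <- i
  }
  list(raster = grid_raster(grid, matrix(idx, grid$nrow, grid$ncol, byrow = TRUE),
                            name = "admin_unit"),
       units = units)
}

#' Rasterize decile assignments over admin polygons
#'
#' @param units Decile-assigned tibble (with `unit_id` and `decile`).
#' @param polys A [poly_set()] whose `feature_id`s match `unit_id`s.
#' @param grid A [grid_spec()].
#' @return An integer [grid_raster()] of deciles (nodata outside all
#'   polygons).
#' @export
rasterize_deciles <- function(units, polys, grid) {
  ra <- rasterize_admin(polys, grid)
  dec_for <- units$decile[match(ra$units, units$unit_id)]
  if (anyNA(dec_for)) {
    abort(sprintf("admin polygons without a decile-assigned unit: %s",
                  paste(ra$units[is.na(dec_for)], collapse = ", ")))
  }
  vals <- matrix(dec_for[ra$raster$values], grid$nrow, grid$ncol)
  grid_raster(grid, vals, name = "haq_decile")
}

#' Threshold a travel-time raster
#'
#' A cell is remote when its travel time strictly exceeds the threshold
#' ("more than" read literally); nodata propagates.
#'
#' @param raster Travel-time [grid_raster()] in minutes.
#' @param threshold_min Threshold in minutes (> 0); defaults to 180
#'   (3 h), with 60 (1 h) the other conventional choice.
#' @return A logical [grid_raster()].
#' @export
classify_travel_time <- function(raster, threshold_min = 180) {
  stopifnot(threshold_min > 0)
  grid_raster(raster$grid, raster$values > threshold_min,
              name = sprintf("travel_gt_%gmin", threshold_min))
}

#' Linear delay-mortality scaling
#'
#' Scales treatment delay to an expected increase in mortality, using the
#' reported 1.01 percentage points per hour of delay between envenomation
#' and antivenom administration, extrapolated linearly. The linearity
#' assumption far beyond the source cohort's observed delays is a
#' documented caveat; the attribute `"assumption"` carries it in output
#' metadata.
#'
#' @param delay_hours Nonnegative delay(s) in hours.
#' @param slope_pct_per_hour Percentage-point increase per hour (default
#'   1.01).
#' @return Percentage-point increase(s) in mortality, with an
#'   `"assumption"` attribute.
#' @export
delay_mortality_scaling <- function(delay_hours, slope_pct_per_hour = 1.01) {
  if (any(delay_hours < 0, na.rm = TRUE)) abort("delay must be nonnegative")
  out <- slope_pct_per_hour * delay_hours
  attr(out, "assumption") <- "linear extrapolation of a cohort-derived per-hour mortality increase"
  out
}
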