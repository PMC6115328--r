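#' Run the full vulnerability pipeline on an input directory
#'
#' Orchestrates every stage: registry cleaning and grouping, per-species
#' environmental screening and range refinement (group C only; group B
#' keeps the unamended expert range), rasterization, richness stacking,
#' HAQ decile assignment and rasterization, travel-time thresholding,
#' vulnerability masking and population enumeration. All rasters must
#' share the covariate grid; a mismatch is a hard error.
#'
#' Expected input tree (as written by [simulate_scenario()]):
#' `registry.csv`, `occurrences.csv`, `antivenom.csv`, `haq.csv`,
#' `eor.geojson`, `admin.geojson` (admin-2 features with a `country`
#' property), `covariates/` (ASCII grids + `bands.csv`),
#' `population.asc`, `travel_minutes.asc`, optional `config.yml`.
#'
#' @param input_dir Input directory.
#' @param output_dir Output directory (created; reports, rasters and a run
#'   manifest are written there). `NULL` skips writing.
#' @param config Configuration list (see [default_config()]); defaults to
#'   `config.yml` in `input_dir` if present.
#' @param quiet Suppress stage banners.
#' @return Invisibly, a list with the registry summary, per-species
#'   ranges, richness layers, decile assignments, the
#'   [vulnerability_report()], the [decile_table()], and headline totals.
#' @export
run_pipeline <- function(input_dir, output_dir = NULL, config = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  need <- c("registry.csv", "occurrences.csv", "antivenom.csv", "haq.csv",
            "eor.geojson", "admin.geojson", "covariates", "population.asc",
            "travel_minutes.asc")
  for (f in need) {
    if (!file.exists(file.path(input_dir, f))) {
      abort(sprintf("missing input: %s", file.path(input_dir, f)))
    }
  }
  if (is.null(config)) {
    cfg_path <- file.path(input_dir, "config.yml")
    config <- read_config(if (file.exists(cfg_path)) cfg_path else NULL)
  }
  validate_config(config)
  t0 <- Sys.time()

  say("== stage: registry ==")
  registry <- read_species_registry(file.path(input_dir, "registry.csv"))
  occurrences <- read_occurrences(file.path(input_dir, "occurrences.csv"))
  antivenom <- readr::read_csv(file.path(input_dir, "antivenom.csv"),
                               show_col_types = FALSE)
  reg <- build_registry(registry, occurrences, antivenom,
                        min_records = config$min_records_group_c, quiet = quiet)
  say("registry: %d species, %d included (B=%d, C=%d)",
      reg$summary$n_total, reg$summary$n_included,
      reg$summary$n_group_b, reg$summary$n_group_c)

  say("== stage: ranges ==")
  covariates <- read_covariates(file.path(input_dir, "covariates"))
  grid <- covariates$grid
  eor_all <- read_geojson(file.path(input_dir, "eor.geojson"))$poly
  included <- reg$species[reg$species$group %in% c("B", "C"), ]
  rasters <- list(); n_amended <- 0L
  for (i in seq_len(nrow(included))) {
    sid <- included$species_id[i]
    eor <- eor_all[eor_all$feature_id == sid, ]
    if (nrow(eor) == 0) abort(sprintf("no expert range polygon for %s", sid))
    class(eor) <- class(eor_all)
    if (included$group[i] == "C") {
      recs <- reg$occurrences[reg$occurrences$species_id == sid, ]
      ref <- refine_species_range(recs, eor, covariates,
                                  buffer_radius_deg = config$buffer_radius_deg,
                                  threshold = config$mess_positive_threshold)
      rng <- ref$range
      if (rng$amended) n_amended <- n_amended + 1L
    } else {
      rng <- build_contemporary_range(
        eor, poly_set(character(0), integer(0), numeric(0), numeric(0)), NULL)
    }
    rasters[[sid]] <- rasterize_range(rng, grid)
  }
  say("ranges: %d species rasterized, %d amended beyond the expert range",
      length(rasters), n_amended)

  say("== stage: stacking ==")
  layers <- composite_layers(rasters, included)
  nt_layers <- no_therapy_layers(rasters, included)

  say("== stage: health metrics ==")
  haq <- read_haq_table(file.path(input_dir, "haq.csv"))
  haq <- assign_deciles(haq)
  adm <- read_geojson(file.path(input_dir, "admin.geojson"))
  admin_table <- adm$attributes %>%
    dplyr::rename(admin_unit = "feature_id") %>%
    select("admin_unit", "country")
  # an admin-2 unit takes its own subnational decile when estimated,
  # otherwise its country's national decile
  unit_dec <- admin_table %>%
    left_join(haq %>% select("unit_id", sub_decile = "decile"),
              by = c("admin_unit" = "unit_id")) %>%
    left_join(haq %>% filter(.data$level == "national") %>%
                select("unit_id", nat_decile = "decile"),
              by = c("country" = "unit_id")) %>%
    mutate(decile = ifelse(is.na(.data$sub_decile), .data$nat_decile,
                           .data$sub_decile))
  if (anyNA(unit_dec$decile)) {
    abort("admin units with no resolvable HAQ decile")
  }
  admin_rast <- rasterize_admin(adm$poly, grid)
  decile_raster <- rasterize_deciles(
    unit_dec %>% select(unit_id = "admin_unit", "decile"), adm$poly, grid)
  travel <- read_ascii_grid(file.path(input_dir, "travel_minutes.asc"),
                            name = "travel_minutes")
  check_same_grid(grid, travel, "covariates", "travel_minutes.asc")
  travel_mask <- classify_travel_time(travel, max(config$travel_thresholds_min))

  say("== stage: vulnerability ==")
  population <- read_ascii_grid(file.path(input_dir, "population.asc"),
                                name = "population")
  check_same_grid(grid, population, "covariates", "population.asc")
  report <- vulnerability_report(
    layers$all, nt_layers$all, travel_mask, decile_raster, population,
    admin_rast, unit_dec %>% select("admin_unit", "country", "decile"),
    deciles = config$vulnerable_deciles)
  table_by_decile <- decile_table(report, drop_zero = TRUE)
  totals <- list(
    population_in_range = population_within_range(layers$all, population),
    population_remote_in_range = population_within_range(
      layers$all, population, travel_mask = travel_mask),
    vulnerable_all = sum(report$population_vulnerable_all_species),
    vulnerable_no_therapy = sum(report$population_vulnerable_no_therapy))
  say("vulnerability: %.0f in range, %.0f remote, %.0f vulnerable (all), %.0f (no therapy)",
      totals$population_in_range, totals$population_remote_in_range,
      totals$vulnerable_all, totals$vulnerable_no_therapy)

  result <- list(config = config, summary = reg$summary,
                 species = reg$species, rasters = rasters,
                 n_amended = n_amended, richness = layers,
                 richness_no_therapy = nt_layers, haq = haq,
                 unit_deciles = unit_dec, decile_raster = decile_raster,
                 travel_mask = travel_mask, report = report,
                 decile_table = table_by_decile, totals = totals)

  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, input_dir, output_dir, t0)
    say("outputs written to %s", output_dir)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, input_dir, output_dir, t0) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$richness)) {
    write_ascii_grid(result$richness[[nm]],
                     file.path(output_dir, sprintf("richness_%s.asc", nm)))
  }
  for (nm in names(result$richness_no_therapy)) {
    write_ascii_grid(result$richness_no_therapy[[nm]],
                     file.path(output_dir, sprintf("richness_no_antivenom_%s.asc", nm)))
  }
  rep_out <- result$report
  num <- vapply(rep_out, is.numeric, logical(1)) &
    grepl("^population", names(rep_out))
  rep_out[num] <- lapply(rep_out[num], round_half_up)
  readr::write_csv(rep_out, file.path(output_dir, "vulnerability_admin2.csv"))
  readr::write_csv(result$decile_table,
                   file.path(output_dir, "vulnerability_country_by_decile.csv"))
  readr::write_csv(richness_summary(c(result$richness,
                                      setNames(result$richness_no_therapy,
                                               paste0("no_antivenom_",
                                                      names(result$richness_no_therapy))))),
                   file.path(output_dir, "richness_summary.csv"))
  readr::write_csv(haq_thresholds(result$haq), file.path(output_dir, "deciles.csv"))
  jsonlite::write_json(
    lapply(result$totals, unname),
    file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  inputs <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("snakevuln")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = result$config,
    input_checksums = as.list(setNames(unname(tools::md5sum(inputs)),
                                       basename(inputs))),
    n_species_included = result$summary$n_included,
    n_amended = result$n_amended)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
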