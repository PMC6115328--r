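#' Synthetic scenario specification
#'
#' Parameters of a fully synthetic, internally consistent study region:
#' covariates, expert ranges, occurrence records with known
#' interpolation/extrapolation labels, population, travel time, HAQ
#' tables, and admin mosaics. The defaults describe a desk-scale world —
#' a 60 x 60 grid at 0.5 degrees, 12 mapped species (9 with enough
#' records for environmental screening, 3 without), 6 mapped countries of
#' 3 admin-2 bands each, and 20 national HAQ units (mapped countries are a
#' subset, mirroring the fact that decile thresholds are built from many
#' more countries than carry snakes) — that runs end to end in seconds.
#'
#' @param seed Integer seed; identical seeds give identical scenarios.
#' @param nrow,ncol Grid extent in cells.
#' @param res Cell size in decimal degrees.
#' @param n_species Number of mapped species.
#' @param n_group_b How many of them lack enough records for screening.
#' @param n_bands Number of environmental covariate bands.
#' @param n_countries Mapped countries (vertical strips).
#' @param admin2_per_country Admin-2 bands per country.
#' @param n_national_units National HAQ units (>= 10; >= `n_countries`).
#' @param buffer_radius_deg Buffer radius used when planting records.
#' @param travel_levels Minutes levels for the piecewise-constant travel
#'   field.
#' @param n_planted_duplicates,n_planted_missing Deliberately dirty
#'   occurrence rows (exact duplicates; missing-coordinate rows) planted to
#'   exercise record cleaning.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1L, nrow = 60L, ncol = 60L, res = 0.5,
                          n_species = 12L, n_group_b = 3L, n_bands = 8L,
                          n_countries = 6L, admin2_per_country = 3L,
                          n_national_units = 20L,
                          buffer_radius_deg = 0.898,
                          travel_levels = c(30, 120, 240),
                          n_planted_duplicates = 5L, n_planted_missing = 3L) {
  stopifnot(n_national_units >= 10, n_national_units >= n_countries,
            n_group_b < n_species, ncol %% n_countries == 0,
            nrow %% admin2_per_country == 0)
  structure(list(seed = as.integer(seed), nrow = as.integer(nrow),
                 ncol = as.integer(ncol), res = res,
                 n_species = as.integer(n_species),
                 n_group_b = as.integer(n_group_b),
                 n_bands = as.integer(n_bands),
                 n_countries = as.integer(n_countries),
                 admin2_per_country = as.integer(admin2_per_country),
                 n_national_units = as.integer(n_national_units),
                 buffer_radius_deg = buffer_radius_deg,
                 travel_levels = travel_levels,
                 n_planted_duplicates = as.integer(n_planted_duplicates),
                 n_planted_missing = as.integer(n_planted_missing)),
            class = "scenario_spec")
}

scenario_grid <- function(spec) {
  grid_spec(xmin = 0, ymax = spec$nrow * spec$res, res = spec$res,
            nrow = spec$nrow, ncol = spec$ncol)
}

#' Generate synthetic environmental covariates
#'
#' Each band is an affine gradient plus a low-frequency sinusoid and a
#' small seeded white-noise term, so that environments drift smoothly:
#' cells near a species' range have near-range environments
#' (interpolation) while distant cells drift outside the training envelope
#' (extrapolation).
#'
#' @param spec A [scenario_spec()].
#' @return A [covariate_stack()].
#' @export
generate_covariates <- function(spec) {
  set.seed(spec$seed + 101L)
  grid <- scenario_grid(spec)
  cc <- cell_centres(grid)
  bands <- list()
  for (b in seq_len(spec$n_bands)) {
    a1 <- runif(1, 0.6, 1.4) * sample(c(-1, 1), 1)
    a2 <- runif(1, 0.6, 1.4) * sample(c(-1, 1), 1)
    amp <- runif(1, 0.5, 1.5)
    lam <- runif(1, 15, 40)
    phase <- runif(1, 0, 2 * pi)
    vals <- a1 * cc$x + a2 * cc$y +
      amp * sin(2 * pi * cc$x / lam + phase) +
      rnorm(nrow(cc), sd = 0.05)
    bands[[sprintf("bio%02d", b)]] <- matrix(vals, grid$nrow, grid$ncol, byrow = TRUE)
  }
  covariate_stack(grid, bands)
}

# --- naive oracle primitives -------------------------------------------
# Deliberately plain per-value loops, written independently of the
# pipeline modules, used for planting ground truth and for the brute-force
# expected outputs.

# univariate piecewise similarity, one value against one training vector
oracle_sim1 <- function(v, tr) {
  lo <- min(tr); hi <- max(tr)
  if (hi == lo) return(if (v == lo) 100 else -100)
  f <- 100 * sum(tr < v) / length(tr)
  if (f == 0) 100 * (v - lo) / (hi - lo)
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (hi - v) / (hi - lo)
}

# min across bands at one cell; training is an n x bands matrix
oracle_sim_cell <- function(cell_vals, training) {
  s <- Inf
  for (j in seq_along(cell_vals)) {
    if (is.na(cell_vals[j])) return(NA_real_)
    s <- min(s, oracle_sim1(cell_vals[j], training[, j]))
  }
  s
}

# point in a regular n-gon disc centred at (cx, cy): all edge cross
# products on one side (vertices at angles 2*pi*k/n, matching the
# buffer construction convention)
oracle_in_disc <- function(px, py, cx, cy, radius, n = 64) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  vx <- cx + radius * cos(ang); vy <- cy + radius * sin(ang)
  j <- c(seq(2, n), 1)
  cross <- (vx[j] - vx) * (py - vy) - (vy[j] - vy) * (px - vx)
  all(cross >= 0) || all(cross <= 0)
}

#' Generate the species layer of a scenario
#'
#' Places one rectangular expert range per species and plants occurrence
#' records with known labels: within-range training records (covering the
#' range corners so the training envelope spans the range), outside
#' records on interpolation cells, and outside records on extrapolation
#' cells. Labels are fixed at generation time by evaluating the similarity
#' formula directly (naive per-cell code), requiring a |score| margin of
#' 1e-6 so classification is unambiguous. Dirty rows (duplicates,
#' missing coordinates) are appended to the occurrence table.
#'
#' @param spec A [scenario_spec()].
#' @param covariates The stack from [generate_covariates()].
#' @return A list: `registry` (with one extra unmappable group-A species),
#'   `occurrences` (dirty, as a field export would be), `eor` (a
#'   [poly_set()]), `truth` (per-record labels and per-species expected
#'   amendment flags).
#' @export
generate_species_scenario <- function(spec, covariates) {
  set.seed(spec$seed + 202L)
  grid <- covariates$grid
  xmax <- grid$xmin + grid$ncol * grid$res
  ymin <- grid$ymax - grid$nrow * grid$res
  ids <- sprintf("SP%02d", seq_len(spec$n_species))
  group_b <- sample(ids, spec$n_group_b)
  eor_rows <- list(); occ <- list(); labels <- list(); rects <- list()
  n_inside_all <- integer(0); n_interp_all <- integer(0); n_extrap_all <- integer(0)

  band_mats <- covariates$bands
  cell_env <- function(r, c) vapply(band_mats, function(m) m[r, c], numeric(1))

  for (i in seq_along(ids)) {
    sid <- ids[i]
    w <- runif(1, 5, 8); h <- runif(1, 5, 8)
    rx <- runif(1, grid$xmin + 2, xmax - 2 - w)
    ry <- runif(1, ymin + 2, grid$ymax - 2 - h)
    rect <- c(xmin = rx, xmax = rx + w, ymin = ry, ymax = ry + h)
    rects[[sid]] <- rect
    eor_rows[[sid]] <- rect_poly(rect["xmin"], rect["xmax"],
                                 rect["ymin"], rect["ymax"], feature_id = sid)

    cc <- cell_centres(grid)
    strictly_in <- cc$x > rect["xmin"] & cc$x < rect["xmax"] &
      cc$y > rect["ymin"] & cc$y < rect["ymax"]
    inside_cells <- cc[strictly_in, ]
    is_b <- sid %in% group_b
    n_inside <- if (is_b) sample(2:4, 1) else sample(6:9, 1)
    # corner-most inside cells first, so the envelope spans the range
    corner_rank <- order(pmin(
      (inside_cells$x - rect["xmin"])^2 + (inside_cells$y - rect["ymin"])^2,
      (inside_cells$x - rect["xmax"])^2 + (inside_cells$y - rect["ymax"])^2,
      (inside_cells$x - rect["xmin"])^2 + (inside_cells$y - rect["ymax"])^2,
      (inside_cells$x - rect["xmax"])^2 + (inside_cells$y - rect["ymin"])^2))
    pick <- unique(c(corner_rank[seq_len(min(4, n_inside))],
                     sample(nrow(inside_cells), n_inside)))[seq_len(n_inside)]
    train_cells <- inside_cells[pick, ]
    training <- do.call(rbind, lapply(seq_len(nrow(train_cells)), function(k)
      cell_env(train_cells$row[k], train_cells$col[k])))

    n_interp_target <- if (is_b) 0L else sample(0:3, 1)
    n_extrap_target <- if (is_b) 0L else sample(0:2, 1)
    out_interp <- out_extrap <- NULL
    if (!is_b) {
      outside <- cc[!(cc$x >= rect["xmin"] & cc$x <= rect["xmax"] &
                        cc$y >= rect["ymin"] & cc$y <= rect["ymax"]), ]
      sims <- vapply(seq_len(nrow(outside)), function(k)
        oracle_sim_cell(cell_env(outside$row[k], outside$col[k]), training),
        numeric(1))
      interp_pool <- which(!is.na(sims) & sims > 1e-6)
      extrap_pool <- which(!is.na(sims) & sims < -1e-6)
      if (length(interp_pool) > 0 && n_interp_target > 0) {
        take <- sample(interp_pool, min(n_interp_target, length(interp_pool)))
        out_interp <- outside[take, ]
      }
      if (length(extrap_pool) > 0 && n_extrap_target > 0) {
        take <- sample(extrap_pool, min(n_extrap_target, length(extrap_pool)))
        out_extrap <- outside[take, ]
      }
    }
    n_interp <- if (is.null(out_interp)) 0L else nrow(out_interp)
    n_extrap <- if (is.null(out_extrap)) 0L else nrow(out_extrap)
    n_inside_all <- c(n_inside_all, n_inside)
    n_interp_all <- c(n_interp_all, n_interp)
    n_extrap_all <- c(n_extrap_all, n_extrap)

    mk <- function(cells, lab) {
      if (is.null(cells) || nrow(cells) == 0) return(NULL)
      tibble(species_id = sid,
             year = ifelse(runif(nrow(cells)) < 0.15, NA_integer_,
                           sample(1990:2016, nrow(cells), replace = TRUE)),
             lat = cells$y, lon = cells$x, source = "synthetic",
             truth_label = lab)
    }
    occ[[sid]] <- bind_rows(mk(train_cells, "inside"),
                            mk(out_interp, "mess_positive"),
                            mk(out_extrap, "mess_negative"))
  }

  occ_all <- bind_rows(occ)
  truth_records <- occ_all
  clean <- occ_all %>% select(-"truth_label")
  # plant exact duplicates and missing-coordinate rows
  if (spec$n_planted_duplicates > 0) {
    dup <- clean[sample(nrow(clean), spec$n_planted_duplicates, replace = FALSE), ]
    clean <- bind_rows(clean, dup)
  }
  if (spec$n_planted_missing > 0) {
    miss <- clean[sample(nrow(clean), spec$n_planted_missing), ]
    miss$lon <- NA_real_
    clean <- bind_rows(clean, miss)
  }
  clean <- clean[sample(nrow(clean)), ]  # shuffle, as a field export would be

  registry <- tibble(
    species_id = c(ids, "SP_A1"),
    name = c(sprintf("Synthetus species%02d", seq_along(ids)), "Synthetus absentis"),
    who_category = c(sample(c(1L, 2L), length(ids), replace = TRUE), 2L),
    has_eor = c(rep(TRUE, length(ids)), FALSE))
  antivenom <- tibble(species_id = ids,
                      antivenom_available = runif(length(ids)) < 0.5)

  eor <- bind_rows(eor_rows)
  class(eor) <- c("poly_set", class(eor))
  truth_species <- tibble(species_id = ids,
                          group = ifelse(ids %in% group_b, "B", "C"),
                          n_inside = n_inside_all,
                          n_outside_interp = n_interp_all,
                          n_outside_extrap = n_extrap_all,
                          amendable = n_interp_all > 0)
  list(registry = registry, occurrences = clean, antivenom = antivenom,
       eor = eor, rects = rects,
       truth = list(records = truth_records, species = truth_species,
                    n_amendable = sum(truth_species$amendable),
                    n_planted_duplicates = spec$n_planted_duplicates,
                    n_planted_missing = spec$n_planted_missing))
}

#' Generate population, travel-time, HAQ and admin layers
#'
#' Countries are vertical strips, each split into horizontal admin-2
#' bands. Population is piecewise constant per admin-2 unit; travel time
#' is piecewise constant on 10 x 10 cell blocks drawn from
#' `spec$travel_levels`. The HAQ table holds `n_national_units` national
#' units (the mapped countries are assigned evenly spread ranks so the
#' mapped world spans low and high deciles) and subnational values for the
#' first country's admin-2 units.
#'
#' @param spec A [scenario_spec()].
#' @return A list: `population` and `travel` ([grid_raster()]s), `haq`
#'   (tibble), `admin` (a [poly_set()]), `admin_table` (unit, country),
#'   `truth` (per-unit population totals and travel cell counts).
#' @export
generate_health_layers <- function(spec) {
  set.seed(spec$seed + 303L)
  grid <- scenario_grid(spec)
  cols_per <- spec$ncol / spec$n_countries
  rows_per <- spec$nrow / spec$admin2_per_country
  countries <- sprintf("C%d", seq_len(spec$n_countries))

  admin_rows <- list(); admin_tab <- list(); dens <- list()
  pop <- matrix(0, grid$nrow, grid$ncol)
  for (j in seq_len(spec$n_countries)) {
    x0 <- grid$xmin + (j - 1) * cols_per * grid$res
    x1 <- x0 + cols_per * grid$res
    for (k in seq_len(spec$admin2_per_country)) {
      y1 <- grid$ymax - (k - 1) * rows_per * grid$res
      y0 <- y1 - rows_per * grid$res
      uid <- sprintf("%s_A%d", countries[j], k)
      admin_rows[[uid]] <- rect_poly(x0, x1, y0, y1, feature_id = uid)
      admin_tab[[uid]] <- tibble(admin_unit = uid, country = countries[j])
      d <- round(runif(1, 5, 50))
      dens[[uid]] <- d
      rr <- ((k - 1) * rows_per + 1):(k * rows_per)
      cc <- ((j - 1) * cols_per + 1):(j * cols_per)
      pop[rr, cc] <- d
    }
  }
  travel <- matrix(0, grid$nrow, grid$ncol)
  block <- 10L
  for (br in seq_len(spec$nrow %/% block)) {
    for (bc in seq_len(spec$ncol %/% block)) {
      travel[((br - 1) * block + 1):(br * block),
             ((bc - 1) * block + 1):(bc * block)] <-
        sample(spec$travel_levels, 1)
    }
  }

  nat_ids <- c(countries,
               sprintf("NAT%02d", seq_len(spec$n_national_units - spec$n_countries)))
  vals <- sort(runif(spec$n_national_units, 20, 95))
  # spread the mapped countries across the ranked list
  mapped_ranks <- round(seq(1, spec$n_national_units, length.out = spec$n_countries))
  haq_vals <- numeric(spec$n_national_units)
  haq_vals[seq_len(spec$n_countries)] <- vals[mapped_ranks]
  haq_vals[-seq_len(spec$n_countries)] <- vals[-mapped_ranks]
  haq <- tibble(unit_id = nat_ids, parent_country = NA_character_,
                level = "national", haq_value = haq_vals)
  # subnational values for the first country's admin-2 units
  sub_units <- names(admin_rows)[seq_len(spec$admin2_per_country)]
  haq <- bind_rows(haq, tibble(
    unit_id = sub_units, parent_country = countries[1], level = "subnational",
    haq_value = pmin(95, pmax(20, haq_vals[1] + runif(length(sub_units), -12, 12)))))

  admin <- bind_rows(admin_rows)
  class(admin) <- c("poly_set", class(admin))
  dens_tbl <- tibble(admin_unit = names(dens),
                     density = unname(unlist(dens)),
                     population_total = unname(unlist(dens)) * rows_per * cols_per)
  list(population = grid_raster(grid, pop, name = "population"),
       travel = grid_raster(grid, travel, name = "travel_minutes"),
       haq = haq, admin = admin, admin_table = bind_rows(admin_tab),
       truth = list(density = dens_tbl,
                    total_population = sum(pop),
                    n_cells_gt60 = sum(travel > 60),
                    n_cells_gt180 = sum(travel > 180)))
}

#' Generate a complete synthetic scenario
#'
#' @param spec A [scenario_spec()].
#' @return A `scenario` list bundling covariates, species inputs, health
#'   layers and all ground truth.
#' @export
generate_scenario <- function(spec = scenario_spec()) {
  covariates <- generate_covariates(spec)
  sp <- generate_species_scenario(spec, covariates)
  hl <- generate_health_layers(spec)
  structure(c(list(spec = spec, covariates = covariates), sp, hl[-1],
              list(population = hl$population, travel = hl$travel,
                   health_truth = hl$truth)),
            class = "scenario")
}

#' Brute-force expected vulnerability report
#'
#' Recomputes the whole overlay independently of the pipeline modules, by
#' explicit per-cell looping over the scenario's known structure: species
#' membership from the planted rectangles, buffer discs and the naive
#' similarity evaluator; deciles from a re-derived ranking; population
#' and travel from the planted piecewise-constant fields. Used as the
#' acceptance oracle for ground-truth recovery.
#'
#' @param scenario A [generate_scenario()] result.
#' @param deciles Deciles counted as vulnerable (default 1:3).
#' @param travel_threshold_min Remoteness threshold (default 180).
#' @return A list: `admin2` (expected per-unit report), `totals` (named
#'   scalars: population in range, remote-in-range, vulnerable all /
#'   no-therapy), `decile_by_unit` (expected decile per admin-2 unit).
#' @export
expected_vulnerable_population <- function(scenario, deciles = 1:3,
                                           travel_threshold_min = 180) {
  spec <- scenario$spec
  grid <- scenario$covariates$grid
  reg <- scenario$registry
  reg <- reg[reg$has_eor, ]
  av <- setNames(scenario$antivenom$antivenom_available,
                 scenario$antivenom$species_id)
  truth_sp <- scenario$truth$species
  rects <- scenario$rects

  # naive decile assignment, re-derived
  nat <- scenario$haq[scenario$haq$level == "national", ]
  ord <- order(nat$haq_value, nat$unit_id)
  nat_dec <- integer(nrow(nat))
  nat_dec[ord] <- floor(10 * (seq_len(nrow(nat)) - 1) / nrow(nat)) + 1L
  names(nat_dec) <- nat$unit_id
  upper <- vapply(1:10, function(d) {
    v <- nat$haq_value[nat_dec == d]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  sub <- scenario$haq[scenario$haq$level == "subnational", ]
  sub_dec <- vapply(sub$haq_value, function(v) {
    hit <- which(!is.na(upper) & v <= upper)
    if (length(hit)) hit[1] else max(which(!is.na(upper)))
  }, integer(1))
  names(sub_dec) <- sub$unit_id

  unit_ids <- scenario$admin_table$admin_unit
  unit_country <- setNames(scenario$admin_table$country, unit_ids)
  unit_decile <- vapply(unit_ids, function(u) {
    as.integer(if (u %in% names(sub_dec)) sub_dec[[u]] else nat_dec[[unit_country[[u]]]])
  }, integer(1))

  # per-species training matrices (from the planted inside records)
  band_mats <- scenario$covariates$bands
  cell_env <- function(r, c) vapply(band_mats, function(m) m[r, c], numeric(1))
  recs <- scenario$truth$records
  # record positions are cell centres; recover indices by direct arithmetic
  naive_row <- function(y) as.integer(round((grid$ymax - y) / grid$res + 0.5))
  naive_col <- function(x) as.integer(round((x - grid$xmin) / grid$res + 0.5))
  trainings <- list(); pos_records <- list()
  for (sid in reg$species_id) {
    tr <- recs[recs$species_id == sid & recs$truth_label == "inside", ]
    trainings[[sid]] <- do.call(rbind, lapply(seq_len(nrow(tr)), function(k)
      cell_env(naive_row(tr$lat[k]), naive_col(tr$lon[k]))))
    pos_records[[sid]] <- recs[recs$species_id == sid &
                                 recs$truth_label == "mess_positive", ]
  }

  cols_per <- spec$ncol / spec$n_countries
  rows_per <- spec$nrow / spec$admin2_per_country
  pop <- scenario$population$values
  travel <- scenario$travel$values

  n_units <- length(unit_ids)
  vul_all <- setNames(numeric(n_units), unit_ids)
  vul_nt <- setNames(numeric(n_units), unit_ids)
  in_range_pop <- setNames(numeric(n_units), unit_ids)
  unit_pop <- setNames(numeric(n_units), unit_ids)
  tot_in_range <- 0; tot_remote_in_range <- 0

  for (r in seq_len(grid$nrow)) {
    for (c in seq_len(grid$ncol)) {
      x <- grid$xmin + (c - 0.5) * grid$res
      y <- grid$ymax - (r - 0.5) * grid$res
      cj <- floor((c - 1) / cols_per) + 1
      ck <- floor((r - 1) / rows_per) + 1
      uid <- sprintf("C%d_A%d", cj, ck)
      unit_pop[uid] <- unit_pop[uid] + pop[r, c]

      env <- NULL
      present_all <- FALSE; present_nt <- FALSE
      for (sid in reg$species_id) {
        rect <- rects[[sid]]
        inside <- x >= rect["xmin"] && x <= rect["xmax"] &&
          y >= rect["ymin"] && y <= rect["ymax"]
        if (!inside && truth_sp$amendable[truth_sp$species_id == sid]) {
          pr <- pos_records[[sid]]
          for (k in seq_len(nrow(pr))) {
            if (oracle_in_disc(x, y, pr$lon[k], pr$lat[k], spec$buffer_radius_deg)) {
              if (is.null(env)) env <- cell_env(r, c)
              if (oracle_sim_cell(env, trainings[[sid]]) >= 0) inside <- TRUE
              break
            }
          }
        }
        if (inside) {
          present_all <- TRUE
          if (!av[[sid]]) present_nt <- TRUE
          if (present_all && present_nt) break
        }
      }
      if (!present_all) next
      p <- pop[r, c]
      tot_in_range <- tot_in_range + p
      in_range_pop[uid] <- in_range_pop[uid] + p
      remote <- travel[r, c] > travel_threshold_min
      if (remote) tot_remote_in_range <- tot_remote_in_range + p
      if (remote && unit_decile[[uid]] %in% deciles) {
        vul_all[uid] <- vul_all[uid] + p
        if (present_nt) vul_nt[uid] <- vul_nt[uid] + p
      }
    }
  }

  admin2 <- tibble(admin_unit = unit_ids,
                   country = unname(unit_country[unit_ids]),
                   decile = unname(unit_decile[unit_ids]),
                   population_vulnerable_all_species = unname(vul_all[unit_ids]),
                   population_vulnerable_no_therapy = unname(vul_nt[unit_ids]),
                   population_in_range = unname(in_range_pop[unit_ids]),
                   population_total = unname(unit_pop[unit_ids]))
  list(admin2 = admin2,
       totals = c(population_in_range = tot_in_range,
                  population_remote_in_range = tot_remote_in_range,
                  vulnerable_all = sum(vul_all),
                  vulnerable_no_therapy = sum(vul_nt)),
       decile_by_unit = tibble(admin_unit = unit_ids,
                               decile = unname(unit_decile[unit_ids])))
}

#' Write a scenario to an input directory
#'
#' Produces the complete plain-text input tree the pipeline consumes —
#' registry, occurrence, antivenom and HAQ CSVs, expert-range and admin
#' GeoJSON, covariate/population/travel ASCII grids, a YAML config — plus
#' `ground_truth.json` with the planted labels and expected totals.
#'
#' @param scenario A [generate_scenario()] result (or a
#'   [scenario_spec()], generated on the fly).
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
simulate_scenario <- function(scenario, dir) {
  if (inherits(scenario, "scenario_spec")) scenario <- generate_scenario(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(scenario$registry, file.path(dir, "registry.csv"))
  readr::write_csv(scenario$occurrences, file.path(dir, "occurrences.csv"))
  readr::write_csv(scenario$antivenom, file.path(dir, "antivenom.csv"))
  readr::write_csv(scenario$haq, file.path(dir, "haq.csv"))
  write_geojson(scenario$eor, file.path(dir, "eor.geojson"))
  write_geojson(scenario$admin, file.path(dir, "admin.geojson"),
                attributes = scenario$admin_table %>%
                  dplyr::rename(feature_id = "admin_unit"))
  write_covariates(scenario$covariates, file.path(dir, "covariates"))
  write_ascii_grid(scenario$population, file.path(dir, "population.asc"))
  write_ascii_grid(scenario$travel, file.path(dir, "travel_minutes.asc"))
  cfg <- default_config()
  cfg$buffer_radius_deg <- scenario$spec$buffer_radius_deg
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  truth <- list(
    n_amendable = scenario$truth$n_amendable,
    species = scenario$truth$species,
    records = scenario$truth$records,
    total_population = scenario$health_truth$total_population,
    density = scenario$health_truth$density,
    n_cells_gt60 = scenario$health_truth$n_cells_gt60,
    n_cells_gt180 = scenario$health_truth$n_cells_gt180)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
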