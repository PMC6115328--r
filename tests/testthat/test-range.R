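test_that("outside-record selection excludes boundary points", {
  eor <- rect_poly(0, 5, 0, 5)
  recs <- make_records("sp",
                       lon = c(1, 2, 3, 4, 5.0, 6, 7, 8, 9, 10) / 2,
                       lat = c(rep(2, 4), 0.0, rep(7, 5)))
  # 4 clearly inside, 1 on the boundary (inside by convention), 5 outside
  out <- select_outside_records(recs, eor)
  expect_equal(nrow(out), 5)
  expect_true(all(out$lat == 7))
})

test_that("a range with no valid outside records equals the expert range", {
  grid <- grid_spec(0, 20, res = 1, nrow = 20, ncol = 20)
  eor <- rect_poly(5, 12, 5, 12)
  empty <- poly_set(character(0), integer(0), numeric(0), numeric(0))
  rng <- build_contemporary_range(eor, empty, NULL)
  expect_false(rng$amended)
  expect_equal(rasterize_range(rng, grid)$values,
               rasterize_range(eor, grid)$values)
})

test_that("buffers over pure extrapolation add nothing; interpolation adds the masked part", {
  grid <- grid_spec(0, 20, res = 1, nrow = 20, ncol = 20)
  eor <- rect_poly(2, 8, 2, 8)
  # hand-built surface: interpolation in the west half only (cols 1..10)
  sim <- matrix(-5, 20, 20); sim[, 1:10] <- 5
  surf <- structure(list(similarity = grid_raster(grid, sim),
                         mask = grid_raster(grid, sim >= 0), threshold = 0),
                    class = "mess_surface")
  # disc centred east, fully over extrapolation cells
  buf_east <- buffer_records(tibble::tibble(x = 15, y = 15), radius_deg = 2)
  rng_e <- build_contemporary_range(eor, buf_east, surf)
  expect_equal(sum(rasterize_range(rng_e, grid)$values),
               sum(rasterize_range(eor, grid)$values))

  # disc straddling the interpolation boundary at x = 10: only the west
  # half survives the mask; compare against a per-cell counting oracle
  buf_mid <- buffer_records(tibble::tibble(x = 10, y = 15), radius_deg = 3)
  rng_m <- build_contemporary_range(eor, buf_mid, surf)
  got <- rasterize_range(rng_m, grid)
  cc <- cell_centres(grid)
  in_eor <- cc$x >= 2 & cc$x <= 8 & cc$y >= 2 & cc$y <= 8
  in_disc <- points_in_poly(buf_mid, cc$x, cc$y)
  interp <- sim[cbind(cc$row, cc$col)] >= 0
  want <- matrix(in_eor | (in_disc & interp), 20, 20, byrow = TRUE)
  expect_equal(got$values, want)
  # and the surviving amendment is entirely west of the mask boundary
  added <- which(got$values & !matrix(in_eor, 20, 20, byrow = TRUE), arr.ind = TRUE)
  expect_true(all(added[, "col"] <= 10))
})

test_that("the contemporary range always contains the expert range", {
  withr::local_seed(8)
  grid <- grid_spec(0, 30, res = 0.5, nrow = 60, ncol = 60)
  covs <- covariate_stack(grid, list(
    b1 = matrix(runif(3600, 0, 30), 60, 60),
    b2 = matrix(runif(3600, 0, 30), 60, 60)))
  for (k in 1:5) {
    eor <- rect_poly(runif(1, 2, 10), runif(1, 15, 25),
                     runif(1, 2, 10), runif(1, 15, 25), "sp")
    recs <- make_records("sp", lon = runif(12, 0, 30), lat = runif(12, 0, 30))
    ref <- refine_species_range(recs, eor, covs, buffer_radius_deg = 2)
    r_eor <- rasterize_range(eor, grid)$values
    r_new <- rasterize_range(ref$range, grid)$values
    expect_true(all(r_new[r_eor]))
    if (!ref$range$amended) expect_equal(r_new, r_eor)
  }
})

test_that("amendment happens exactly for species with MESS-positive outside records", {
  sc <- generate_scenario(scenario_spec(seed = 13))
  reg <- suppressMessages(build_registry(sc$registry, sc$occurrences, sc$antivenom))
  truth <- sc$truth$species
  n_amended <- 0L
  for (sid in truth$species_id[truth$group == "C"]) {
    eor <- sc$eor[sc$eor$feature_id == sid, ]
    class(eor) <- class(sc$eor)
    recs <- reg$occurrences[reg$occurrences$species_id == sid, ]
    ref <- refine_species_range(recs, eor, sc$covariates,
                                buffer_radius_deg = sc$spec$buffer_radius_deg)
    expect_equal(ref$range$amended,
                 truth$amendable[truth$species_id == sid],
                 info = sid)
    n_amended <- n_amended + ref$range$amended
  }
  expect_equal(n_amended, sc$truth$n_amendable)
})
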