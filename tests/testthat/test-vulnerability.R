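test_that("the vulnerability mask is the cell-wise conjunction of its layers", {
  grid <- grid_spec(0, 40, res = 1, nrow = 40, ncol = 40)
  withr::local_seed(53)
  rich <- grid_raster(grid, matrix(sample(0:4, 1600, TRUE), 40, 40))
  travel <- grid_raster(grid, matrix(runif(1600, 0, 400), 40, 40))
  tmask <- classify_travel_time(travel, 180)
  dec <- grid_raster(grid, matrix(sample(1:10, 1600, TRUE), 40, 40))
  got <- vulnerability_mask(rich, tmask, dec, deciles = 1:3)
  want <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    want[r, c] <- rich$values[r, c] >= 1 && travel$values[r, c] > 180 &&
      dec$values[r, c] %in% 1:3
  }
  expect_equal(got$values, want)

  # single-cell sanity: decile outside the chosen set switches it off
  one <- grid_spec(0, 1, res = 1, nrow = 1, ncol = 1)
  expect_true(vulnerability_mask(grid_raster(one, 2),
                                 grid_raster(one, TRUE),
                                 grid_raster(one, 2), 1:3)$values[1, 1])
  expect_false(vulnerability_mask(grid_raster(one, 2),
                                  grid_raster(one, TRUE),
                                  grid_raster(one, 4), 1:3)$values[1, 1])
})

test_that("population enumeration sums persons over masked cells per unit", {
  grid <- grid_spec(0, 10, res = 1, nrow = 10, ncol = 10)
  pop <- grid_raster(grid, matrix(10, 10, 10))
  m <- matrix(FALSE, 10, 10); m[1:5, 1:8] <- TRUE  # 40 cells; 37 in-unit below
  mask <- grid_raster(grid, m)
  unit <- rect_poly(0, 10, 0, 10, "only")
  got <- enumerate_population(mask, pop, unit)
  expect_equal(got$population, 400)

  m37 <- matrix(FALSE, 10, 10); m37[seq_len(37)] <- TRUE
  expect_equal(enumerate_population(grid_raster(grid, m37), pop, unit)$population,
               370)

  none <- enumerate_population(grid_raster(grid, FALSE), pop, unit)
  expect_equal(none$population, 0)

  # cells outside every polygon surface in an explicit unassigned bucket
  west <- rect_poly(0, 5, 0, 10, "west")
  got2 <- enumerate_population(mask, pop, west)
  expect_setequal(got2$admin_unit, c("west", "unassigned"))
  expect_equal(sum(got2$population), 400)
})

test_that("filtered population totals are monotone non-increasing", {
  withr::local_seed(59)
  grid <- grid_spec(0, 20, res = 1, nrow = 20, ncol = 20)
  rich <- grid_raster(grid, matrix(sample(0:3, 400, TRUE), 20, 20))
  pop <- grid_raster(grid, matrix(runif(400, 0, 100), 20, 20))
  travel <- classify_travel_time(grid_raster(grid, matrix(runif(400, 0, 300), 20, 20)), 180)
  dec <- grid_raster(grid, matrix(sample(1:10, 400, TRUE), 20, 20))
  p0 <- population_within_range(rich, pop)
  p1 <- population_within_range(rich, pop, travel_mask = travel)
  p2 <- population_within_range(rich, pop, travel_mask = travel,
                                decile_raster = dec, deciles = 1:3)
  p3 <- population_within_range(rich, pop, travel_mask = travel,
                                decile_raster = dec, deciles = 1:10)
  expect_lte(p1, p0)
  expect_lte(p2, p1)
  expect_lte(p2, p3)
  expect_equal(population_within_range(grid_raster(grid, 0), pop), 0)
  expect_equal(population_within_range(grid_raster(grid, 1), pop),
               sum(pop$values))
})

test_that("the decile table pivots countries into their single decile column", {
  rep1 <- tibble::tibble(country = "A", decile = 2,
                         population_vulnerable_no_therapy = 1234.4)
  t1 <- decile_table(rep1)
  expect_equal(t1$decile_2, c(1234, 1234))
  expect_equal(attr(t1, "grand_total"), 1234)

  rep5 <- tibble::tibble(
    country = rep(c("A", "B", "C", "D", "E"), each = 2),
    decile = rep(c(1L, 1L, 2L, 3L, 3L), each = 2),
    population_vulnerable_no_therapy = c(10, 5, 7, 3, 0, 0, 20, 1, 2, 2))
  t5 <- decile_table(rep5)
  # column totals match a row-sum oracle over the long data
  long_tot <- tapply(rep5$population_vulnerable_no_therapy, rep5$decile, sum)
  tot_row <- t5[t5$country == "Total", ]
  expect_equal(tot_row$decile_1, unname(long_tot["1"]))
  expect_equal(tot_row$decile_2, unname(long_tot["2"]))
  expect_equal(tot_row$decile_3, unname(long_tot["3"]))
  # the all-zero country is omitted
  expect_false("C" %in% t5$country)
  expect_equal(attr(t5, "grand_total"), sum(rep5$population_vulnerable_no_therapy))
})

test_that("report aggregation conserves totals from admin-2 to country to decile", {
  sc <- generate_scenario(scenario_spec(seed = 19))
  d <- withr::local_tempdir()
  simulate_scenario(sc, d)
  res <- run_pipeline(d, output_dir = NULL, quiet = TRUE)
  rep <- res$report
  expect_true(all(rep$population_vulnerable_no_therapy <=
                    rep$population_vulnerable_all_species + 1e-9))
  expect_true(all(rep$population_vulnerable_all_species <=
                    rep$population_in_range + 1e-9))
  expect_true(all(rep$population_in_range <= rep$population_total + 1e-9))
  cs <- country_summary(rep)
  expect_equal(sum(cs$population_vulnerable_no_therapy),
               sum(rep$population_vulnerable_no_therapy))
  tot_row <- res$decile_table[res$decile_table$country == "Total", ]
  expect_equal(sum(tot_row[paste0("decile_", 1:10)]),
               round(sum(rep$population_vulnerable_no_therapy)))
})
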