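nat_units <- function(values, ids = sprintf("U%02d", seq_along(values))) {
  tibble::tibble(unit_id = ids, parent_country = NA_character_,
                 level = "national", haq_value = values)
}

test_that("national decile assignment follows the rank formula", {
  ten <- assign_haq_deciles(nat_units(1:10))
  expect_equal(ten$decile, 1:10)

  twenty <- assign_haq_deciles(nat_units(sample(1:20)))
  expect_equal(as.integer(table(twenty$decile)), rep(2L, 10))

  expect_error(assign_haq_deciles(nat_units(1:9)), ">= 10")

  withr::local_seed(37)
  v <- runif(37, 0, 100)
  got <- assign_haq_deciles(nat_units(v))
  # oracle: explicit sort + floor formula
  ord <- order(v, got$unit_id)
  want <- integer(37); want[ord] <- floor(10 * (0:36) / 37) + 1L
  expect_equal(got$decile, want)
  sizes <- table(got$decile)
  expect_lte(diff(range(sizes)), 1)
  # monotone in value
  expect_true(all(diff(got$decile[order(got$haq_value)]) >= 0))
})

test_that("subnational units land in the national decile interval (lower, upper]", {
  nat <- assign_haq_deciles(nat_units(seq(5, 95, by = 10)))  # deciles 1..10
  th <- haq_thresholds(nat)
  sub <- tibble::tibble(unit_id = c("s1", "s2", "s3", "s4", "s5"),
                        haq_value = c(25, 30, 1, 99, 35))
  got <- assign_subnational_deciles(sub, th)
  # 25 equals the decile-3 national value -> decile 3; 30 is between
  # decile-3 and decile-4 thresholds -> decile 4; extremes clamp
  expect_equal(got$decile, c(3L, 4L, 1L, 10L, 4L))

  withr::local_seed(41)
  sub25 <- tibble::tibble(unit_id = sprintf("s%02d", 1:25),
                          haq_value = runif(25, 0, 100))
  got25 <- assign_subnational_deciles(sub25, th)
  want <- vapply(sub25$haq_value, function(v) {
    d <- 1L
    while (d < 10 && v > th$upper[d]) d <- d + 1L
    d
  }, integer(1))
  expect_equal(got25$decile, want)
})

test_that("decile rasterization assigns by cell centre with a first-listed tie rule", {
  grid <- grid_spec(0, 4, res = 1, nrow = 4, ncol = 4)
  polys <- dplyr::bind_rows(rect_poly(0, 2, 0, 4, "west"),
                            rect_poly(2, 4, 0, 4, "east"))
  class(polys) <- c("poly_set", class(polys))
  units <- tibble::tibble(unit_id = c("west", "east"), decile = c(2L, 9L))
  dr <- rasterize_deciles(units, polys, grid)
  expect_true(all(dr$values[, 1:2] == 2))
  expect_true(all(dr$values[, 3:4] == 9))

  # overlapping polygons: the first listed wins deterministically
  over <- dplyr::bind_rows(rect_poly(0, 4, 0, 4, "first"),
                           rect_poly(0, 4, 0, 4, "second"))
  class(over) <- class(polys)
  ra <- rasterize_admin(over, grid)
  expect_true(all(ra$raster$values == 1))

  withr::local_seed(43)
  mosaic <- dplyr::bind_rows(lapply(1:4, function(i)
    rect_poly((i - 1), i, 0, 4, sprintf("u%d", i))))
  class(mosaic) <- class(polys)
  u4 <- tibble::tibble(unit_id = sprintf("u%d", 1:4), decile = sample(1:10, 4))
  dr4 <- rasterize_deciles(u4, mosaic, grid)
  cc <- cell_centres(grid)
  want <- u4$decile[ceiling(cc$x)]
  expect_equal(as.vector(t(dr4$values)), want)
})

test_that("travel-time thresholding is strict", {
  grid <- grid_spec(0, 2, res = 1, nrow = 2, ncol = 2)
  tt <- grid_raster(grid, matrix(c(180, 181, 60, NA), 2, 2))
  got <- classify_travel_time(tt, 180)
  expect_identical(got$values[1, 1], FALSE)  # exactly 3 h is not "more than"
  expect_identical(got$values[2, 1], TRUE)
  expect_identical(got$values[1, 2], FALSE)
  expect_true(is.na(got$values[2, 2]))

  withr::local_seed(47)
  vals <- matrix(runif(400, 0, 400), 20, 20)
  r <- grid_raster(grid_spec(0, 20, res = 1, nrow = 20, ncol = 20), vals)
  expect_equal(classify_travel_time(r, 60)$values, vals > 60)
})

test_that("delay-mortality scaling is linear in the delay", {
  expect_equal(as.numeric(delay_mortality_scaling(1)), 1.01)
  expect_equal(as.numeric(delay_mortality_scaling(0)), 0)
  d25 <- as.numeric(delay_mortality_scaling(25))
  expect_equal(d25, 25.25)
  expect_gt(d25, 25)
  a <- runif(1, 0, 10); b <- runif(1, 0, 10)
  expect_equal(as.numeric(delay_mortality_scaling(a + b)),
               as.numeric(delay_mortality_scaling(a)) +
                 as.numeric(delay_mortality_scaling(b)))
  expect_error(delay_mortality_scaling(-1), "nonnegative")
  expect_match(attr(delay_mortality_scaling(2), "assumption"), "linear")
})
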