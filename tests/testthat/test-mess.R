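test_that("univariate similarity reproduces the piecewise form", {
  train <- c(1, 2, 3, 4, 5)
  expect_equal(mess_similarity(3, train), 80)    # f = 40 -> 2f
  expect_equal(mess_similarity(1, train), 0)     # value at the minimum, f = 0
  expect_equal(mess_similarity(0, train), -25)   # 100*(0-1)/(5-1)
  expect_equal(mess_similarity(6, train), -25)   # symmetric above the maximum
  expect_equal(mess_similarity(5, train), 2 * (100 - 80))  # f = 80 -> 2(100-f)

  # degenerate training collapses to the documented convention
  expect_equal(mess_similarity(c(2, 3), c(2, 2, 2)), c(100, -100))
})

test_that("similarity agrees with a brute-force oracle on random cases", {
  withr::local_seed(11)
  for (k in 1:25) {
    train <- round(runif(sample(2:30, 1), -5, 5), 2)
    vals <- c(round(runif(10, -8, 8), 2), sample(train, 2))  # include ties
    got <- mess_similarity(vals, train)
    want <- vapply(vals, brute_similarity, numeric(1), train = train)
    expect_equal(got, want, tolerance = 1e-12)
    # sign law: negative iff outside the training envelope
    expect_equal(got < 0, vals < min(train) | vals > max(train))
  }
})

test_that("training extraction partitions records by the range polygon", {
  grid <- grid_spec(0, 10, res = 1, nrow = 10, ncol = 10)
  bands <- list(b1 = matrix(runif(100), 10, 10), b2 = matrix(runif(100), 10, 10))
  covs <- covariate_stack(grid, bands)
  eor <- rect_poly(2, 6, 2, 6, "sp")
  recs <- make_records("sp", lon = c(3.5, 4.5, 5.5, 8.5, 9.5),
                       lat = c(3.5, 4.5, 5.5, 8.5, 9.5))
  fit <- mess_fit(recs, eor, covs)
  expect_equal(nrow(fit$values), 3)
  expect_equal(fit$n_outside, 2)

  # a record exactly on the boundary counts as inside
  recs_b <- make_records("sp", lon = c(2, 3.5), lat = c(3, 3.5))
  expect_equal(nrow(mess_fit(recs_b, eor, covs)$values), 2)

  # fewer than two usable records refuses the fit with a typed condition
  expect_error(mess_fit(recs[4:5, ], eor, covs),
               class = "snakevuln_insufficient_training")

  # records on nodata cells are excluded and tallied; the record at
  # (4.5, 4.5) sits on cell (row 6, col 5) of this 10-degree grid
  bands$b1[6, 5] <- NA
  covs_na <- covariate_stack(grid, bands)
  fit_na <- mess_fit(recs, eor, covs_na)
  expect_equal(fit_na$n_nodata_excluded, 1)
  expect_equal(nrow(fit_na$values), 2)
})

test_that("tidy and glance expose the fitted envelope", {
  grid <- grid_spec(0, 4, res = 1, nrow = 4, ncol = 4)
  covs <- covariate_stack(grid, list(b1 = matrix(1:16, 4, 4)))
  recs <- make_records("sp", lon = c(0.5, 2.5), lat = c(0.5, 2.5))
  fit <- mess_fit(recs, rect_poly(0, 4, 0, 4), covs)
  td <- tidy(fit)
  expect_named(td, c("covariate", "min", "max", "n"))
  expect_true(all(td$min <= td$max))
  expect_equal(glance(fit)$n_training, 2)
})

test_that("the surface is the band-wise minimum and classifies a planted region", {
  withr::local_seed(21)
  grid <- grid_spec(0, 20, res = 1, nrow = 20, ncol = 20)
  b1 <- matrix(runif(400, 10, 20), 20, 20)
  b2 <- matrix(runif(400, 10, 20), 20, 20)
  b2[1:5, 1:5] <- 100  # pushed far outside any training envelope
  covs <- covariate_stack(grid, list(b1 = b1, b2 = b2))
  recs <- make_records("sp", lon = 10:15 + 0.5, lat = 10:15 + 0.5)
  fit <- mess_fit(recs, rect_poly(8, 18, 8, 18), covs)
  surf <- mess_surface(fit, covs)

  # exact agreement with the per-cell scalar oracle
  want <- matrix(NA_real_, 20, 20)
  for (r in 1:20) for (c in 1:20) {
    want[r, c] <- brute_mess_cell(c(b1[r, c], b2[r, c]), fit$values)
  }
  expect_equal(surf$similarity$values, want, tolerance = 1e-12)

  # the pushed block is negative (extrapolation) exactly where planted
  expect_true(all(surf$similarity$values[1:5, 1:5] < 0))
  # minimum aggregation: never above either band's own score
  s1 <- matrix(mess_similarity(as.vector(b1), fit$values[, "b1"]), 20, 20)
  expect_true(all(surf$similarity$values <= s1 + 1e-12))
  # a training record's own cell is never extrapolation
  rc <- cell_at(grid, recs$lon, recs$lat)
  expect_true(all(surf$similarity$values[cbind(rc$row, rc$col)] >= 0))
})

test_that("interpolation region grows monotonically with training records", {
  withr::local_seed(31)
  grid <- grid_spec(0, 10, res = 1, nrow = 10, ncol = 10)
  covs <- covariate_stack(grid, list(b = matrix(runif(100, 0, 10), 10, 10)))
  eor <- rect_poly(0, 10, 0, 10)
  recs <- make_records("sp", lon = runif(8, 0.2, 9.8), lat = runif(8, 0.2, 9.8))
  small <- mess_fit(recs[1:3, ], eor, covs)
  large <- mess_fit(recs, eor, covs)
  expect_true(all(large$min <= small$min), TRUE)
  expect_true(all(large$max >= small$max))
  m_small <- mess_surface(small, covs)$mask$values
  m_large <- mess_surface(large, covs)$mask$values
  expect_true(all(m_large[m_small]))  # no interpolation cell is lost
})

test_that("record classification reads the surface at the record's cell", {
  grid <- grid_spec(0, 10, res = 1, nrow = 10, ncol = 10)
  covs <- covariate_stack(grid, list(b = matrix(5, 10, 10)))
  sim <- matrix(10, 10, 10); sim[2, 2] <- -3; sim[3, 3] <- NA
  surf <- structure(list(similarity = grid_raster(grid, sim),
                         mask = grid_raster(grid, sim >= 0), threshold = 0),
                    class = "mess_surface")
  recs <- make_records("sp", lon = c(0.5, 1.5, 2.5), lat = c(9.5, 8.5, 7.5))
  out <- classify_records(recs, surf)
  expect_equal(out$mess_label, c("mess_positive", "mess_negative", "nodata"))
})
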