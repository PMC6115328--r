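test_that("deduplication removes exact duplicates and coordinate-less rows", {
  recs <- make_records("sp1", lon = c(-1.2, -1.2, 3.0), lat = c(6.5, 6.5, 2.0),
                       year = c(2009L, 2009L, 2009L))
  out <- dedup_occurrences(recs, quiet = TRUE)
  expect_equal(nrow(out), 2)
  expect_equal(out$lon, c(-1.2, 3.0))

  recs2 <- make_records("sp1", lon = c(NA, 5), lat = c(4, NA))
  expect_equal(nrow(dedup_occurrences(recs2, quiet = TRUE)), 0)

  recs3 <- make_records("sp1", lon = c(200, 10), lat = c(10, 95))
  out3 <- dedup_occurrences(recs3, quiet = TRUE)
  expect_equal(nrow(out3), 0)
  expect_equal(sum(attr(out3, "dropped")$n), 2)
})

test_that("deduplication matches a brute-force pairwise oracle and is idempotent", {
  withr::local_seed(42)
  base <- make_records(sample(c("spA", "spB"), 40, replace = TRUE),
                       lon = round(runif(40, -10, 10), 3),
                       lat = round(runif(40, -10, 10), 3),
                       year = sample(c(NA, 1990:2010), 40, replace = TRUE))
  dup_idx <- sample(nrow(base), 7)
  missing <- make_records("spA", lon = NA, lat = runif(3))
  recs <- dplyr::bind_rows(base, base[dup_idx, ], missing)[sample(50), ]

  out <- dedup_occurrences(recs, quiet = TRUE)
  expect_equal(nrow(out), 40)

  # oracle: O(n^2) pairwise duplicate scan over coordinate-complete rows
  complete <- recs[!is.na(recs$lat) & !is.na(recs$lon), ]
  keep <- rep(TRUE, nrow(complete))
  for (i in seq_len(nrow(complete))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      same_year <- identical(complete$year[i], complete$year[j])
      if (keep[j] && complete$species_id[i] == complete$species_id[j] &&
          same_year && complete$lat[i] == complete$lat[j] &&
          complete$lon[i] == complete$lon[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  expect_equal(nrow(out), sum(keep))
  expect_identical(dedup_occurrences(out, quiet = TRUE)$lon, out$lon)
})

test_that("group assignment respects the record-count boundary", {
  expect_equal(assign_group(FALSE, 0), "A")
  expect_equal(assign_group(TRUE, 4), "B")
  expect_equal(assign_group(TRUE, 5), "C")
  expect_equal(assign_group(TRUE, 0), "B")
  expect_warning(g <- assign_group(FALSE, 3), "no range map")
  expect_equal(g, "A")
  # total and exclusive over a random batch
  withr::local_seed(1)
  has <- runif(50) < 0.8
  n <- sample(0:10, 50, replace = TRUE)
  g <- suppressWarnings(assign_group(has, n))
  expect_true(all(g %in% c("A", "B", "C")))
  expect_true(all(g[has] %in% c("B", "C")))
  expect_equal(g[has], ifelse(n[has] < 5, "B", "C"))
})

test_that("registry summary counts are conserved and match a direct tally", {
  withr::local_seed(3)
  reg <- tibble::tibble(
    species_id = sprintf("s%02d", 1:30),
    name = sprintf("Genus sp%02d", 1:30),
    who_category = sample(c(1L, 2L), 30, replace = TRUE),
    has_eor = runif(30) < 0.9)
  reg$group <- suppressWarnings(assign_group(reg$has_eor, sample(0:8, 30, TRUE)))
  s <- summarize_registry(reg)
  expect_equal(s$n_group_a + s$n_group_b + s$n_group_c, 30)
  expect_equal(s$n_included, sum(reg$group %in% c("B", "C")))
  expect_equal(s$n_category1,
               sum(reg$who_category == 1 & reg$group %in% c("B", "C")))
  expect_identical(summarize_registry(reg[0, ])$n_total, 0L)
})

test_that("antivenom join complements availability over included species", {
  reg <- tibble::tibble(species_id = sprintf("s%d", 1:20),
                        who_category = rep(c(1L, 2L), 10),
                        group = rep(c("B", "C"), each = 10))
  av <- tibble::tibble(species_id = sprintf("s%d", 1:9),
                       antivenom_available = TRUE)
  out <- join_antivenom(reg, av)
  expect_equal(sum(out$antivenom_available), 9)
  expect_equal(sum(!out$antivenom_available), 11)

  empty <- join_antivenom(reg, av[0, ])
  expect_true(all(!empty$antivenom_available))

  withr::local_seed(9)
  flags <- runif(20) < 0.5
  av2 <- tibble::tibble(species_id = reg$species_id, antivenom_available = flags)
  out2 <- join_antivenom(reg, av2)
  expect_equal(sum(out2$antivenom_available), sum(flags))
})
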