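# Independent brute-force oracles used across the suite. These are kept
# deliberately naive and separate from the package implementation.

# Piecewise univariate similarity, one candidate at a time.
brute_similarity <- function(v, train) {
  lo <- min(train); hi <- max(train)
  if (hi == lo) return(if (v == lo) 100 else -100)
  f <- 100 * sum(train < v) / length(train)
  if (f == 0) {
    100 * (v - lo) / (hi - lo)
  } else if (f <= 50) {
    2 * f
  } else if (f < 100) {
    2 * (100 - f)
  } else {
    100 * (hi - v) / (hi - lo)
  }
}

# Minimum across bands at one cell; training is an n x bands matrix.
brute_mess_cell <- function(vals, training) {
  min(vapply(seq_along(vals), function(j) brute_similarity(vals[j], training[, j]),
             numeric(1)))
}

# Point-in-polygon via mgcv's independent implementation (single ring,
# boundary behaviour unspecified there, so callers avoid boundary points).
mgcv_inside <- function(poly_ring, x, y) {
  mgcv::in.out(cbind(c(poly_ring$x, poly_ring$x[1]),
                     c(poly_ring$y, poly_ring$y[1])),
               cbind(x, y))
}

# A deterministic random simple polygon (star-shaped around a centre).
random_star_polygon <- function(n = 9, cx = 0, cy = 0, rmin = 1, rmax = 3,
                                feature_id = "star") {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  poly_set(feature_id, 1L, x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Small deterministic occurrence table builder.
make_records <- function(species_id, lon, lat, year = 2000L) {
  tibble::tibble(species_id = species_id, year = year, lat = lat, lon = lon,
                 source = "test")
}
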