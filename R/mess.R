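#' Covariate stack
#'
#' An ordered set of named environmental raster bands sharing one grid
#' (by default the eight bioclimatic covariates used for range screening).
#'
#' @param grid A [grid_spec()].
#' @param bands Named list of value matrices (`NA` = nodata).
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(grid, bands) {
  stopifnot(inherits(grid, "grid_spec"), length(bands) >= 1,
            !is.null(names(bands)), !anyDuplicated(names(bands)))
  for (nm in names(bands)) {
    if (!is.matrix(bands[[nm]]) ||
        nrow(bands[[nm]]) != grid$nrow || ncol(bands[[nm]]) != grid$ncol) {
      abort(sprintf("band %s does not match the grid extent", nm))
    }
  }
  structure(list(grid = grid, bands = bands), class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d bands (%s) on %s\n",
              length(x$bands), paste(names(x$bands), collapse = ", "),
              format(x$grid)))
  invisible(x)
}

#' @describeIn covariate_stack Long tidy view: one row per cell per band.
#' @param x A `covariate_stack`.
#' @param ... Unused.
#' @export
as_tibble.covariate_stack <- function(x, ...) {
  cc <- cell_centres(x$grid)
  bind_rows(lapply(names(x$bands), function(nm) {
    out <- cc
    out$band <- nm
    out$value <- as.vector(t(x$bands[[nm]]))
    out
  }))
}

# Covariate values at given cells; matrix n x bands (NA where nodata).
covariates_at_cells <- function(covariates, row, col) {
  m <- matrix(NA_real_, nrow = length(row), ncol = length(covariates$bands),
              dimnames = list(NULL, names(covariates$bands)))
  ok <- !is.na(row) & !is.na(col)
  idx <- cbind(row[ok], col[ok])
  for (j in seq_along(covariates$bands)) {
    m[ok, j] <- covariates$bands[[j]][idx]
  }
  m
}

#' Fit a multivariate environmental similarity model
#'
#' The training sample consists of the covariate values at the cells of
#' occurrence records falling inside the expert-opinion range (boundary
#' points count as inside). Records on cells where any covariate is nodata
#' are excluded from the sample and tallied. At least two usable training
#' records are required; otherwise the fit is refused with an error of
#' class `"snakevuln_insufficient_training"`, which callers may catch to
#' retain the unamended expert range.
#'
#' @param records Tibble with `lon` and `lat` columns (deduplicated).
#' @param eor A [poly_set()] expert-opinion range.
#' @param covariates A [covariate_stack()].
#' @return An object of class `mess_fit`: per-covariate training vectors and
#'   extremes, plus bookkeeping on excluded records.
#' @export
mess_fit <- function(records, eor, covariates) {
  inside <- points_in_poly(eor, records$lon, records$lat)
  rc <- cell_at(covariates$grid, records$lon[inside], records$lat[inside])
  vals <- covariates_at_cells(covariates, rc$row, rc$col)
  usable <- stats::complete.cases(vals)
  n_nodata <- sum(!usable)
  vals <- vals[usable, , drop = FALSE]
  if (nrow(vals) < 2) {
    abort(sprintf("insufficient training records inside the range (%d usable; need >= 2)",
                  nrow(vals)),
          class = "snakevuln_insufficient_training")
  }
  structure(list(
    values = vals,
    min = apply(vals, 2, min),
    max = apply(vals, 2, max),
    n_inside = sum(inside),
    n_outside = sum(!inside),
    n_nodata_excluded = n_nodata),
    class = "mess_fit")
}

#' @export
print.mess_fit <- function(x, ...) {
  cat(sprintf("<mess_fit> %d training records, %d covariates (%d nodata-excluded)\n",
              nrow(x$values), ncol(x$values), x$n_nodata_excluded))
  invisible(x)
}

#' @export
tidy.mess_fit <- function(x, ...) {
  tibble(covariate = colnames(x$values),
         min = unname(x$min), max = unname(x$max),
         n = nrow(x$values))
}

#' @export
glance.mess_fit <- function(x, ...) {
  tibble(n_training = nrow(x$values), n_covariates = ncol(x$values),
         n_inside = x$n_inside, n_outside = x$n_outside,
         n_nodata_excluded = x$n_nodata_excluded)
}

#' Univariate environmental similarity score
#'
#' The piecewise similarity of a candidate value to a training sample.
#' With `f` the percentage of training values strictly below the candidate
#' (ties count as not below) and `min`/`max` the training extremes:
#' \itemize{
#'   \item `f = 0`: `100 * (value - min) / (max - min)`
#'   \item `0 < f <= 50`: `2 * f`
#'   \item `50 < f < 100`: `2 * (100 - f)`
#'   \item `f = 100`: `100 * (max - value) / (max - min)`
#' }
#' Scores are negative exactly when the value lies outside the training
#' interval. Degenerate training (all values equal) scores 100 at the
#' constant and -100 elsewhere (documented convention).
#'
#' @param value Numeric vector of candidate values.
#' @param training Numeric vector of training values (non-empty).
#' @return Numeric vector of similarity scores.
#' @export
mess_similarity <- function(value, training) {
  stopifnot(length(training) >= 1)
  tmin <- min(training); tmax <- max(training)
  if (tmax == tmin) {
    return(ifelse(value == tmin, 100, -100))
  }
  f <- 100 * vapply(value, function(v) mean(training < v), numeric(1))
  out <- numeric(length(value))
  b1 <- f == 0
  b2 <- f > 0 & f <= 50
  b3 <- f > 50 & f < 100
  b4 <- f == 100
  out[b1] <- 100 * (value[b1] - tmin) / (tmax - tmin)
  out[b2] <- 2 * f[b2]
  out[b3] <- 2 * (100 - f[b3])
  out[b4] <- 100 * (tmax - value[b4]) / (tmax - tmin)
  out[is.na(value)] <- NA_real_
  out
}

#' Multivariate environmental similarity surface
#'
#' Per-cell similarity is the minimum over covariates of
#' [mess_similarity()]; cells where any band is nodata carry no
#' classification. The interpolation mask is `similarity >= threshold`.
#'
#' @param fit A [mess_fit()].
#' @param covariates A [covariate_stack()] sharing the fit's band names.
#' @param extent Optional list with `rows` and `cols` integer ranges
#'   selecting a subwindow of the covariate grid; by default the surface is
#'   evaluated over the full grid.
#' @param threshold Interpolation threshold (default 0; the boundary counts
#'   as interpolation since the training extremes are attainable
#'   environments).
#' @return An object of class `mess_surface` with elements `similarity`
#'   (numeric [grid_raster()]), `mask` (logical [grid_raster()]) and
#'   `threshold`.
#' @export
mess_surface <- function(fit, covariates, extent = NULL, threshold = 0) {
  stopifnot(inherits(fit, "mess_fit"), inherits(covariates, "covariate_stack"))
  bands_needed <- colnames(fit$values)
  if (!all(bands_needed %in% names(covariates$bands))) {
    abort("covariate stack lacks bands present in the training sample")
  }
  grid <- covariates$grid
  rows <- seq_len(grid$nrow); cols <- seq_len(grid$ncol)
  if (!is.null(extent)) {
    rows <- extent$rows; cols <- extent$cols
    grid <- grid_spec(
      xmin = grid$xmin + (min(cols) - 1) * grid$res,
      ymax = grid$ymax - (min(rows) - 1) * grid$res,
      res = grid$res, nrow = length(rows), ncol = length(cols))
  }
  sim <- NULL
  for (nm in bands_needed) {
    band <- covariates$bands[[nm]][rows, cols, drop = FALSE]
    s <- matrix(mess_similarity(as.vector(band), fit$values[, nm]),
                nrow = length(rows), ncol = length(cols))
    sim <- if (is.null(sim)) s else pmin(sim, s)
  }
  structure(list(
    similarity = grid_raster(grid, sim, name = "similarity"),
    mask = grid_raster(grid, sim >= threshold, name = "interpolation"),
    threshold = threshold),
    class = "mess_surface")
}

#' @export
print.mess_surface <- function(x, ...) {
  v <- x$similarity$values
  cat(sprintf("<mess_surface> %s, threshold %g: %d interpolation, %d extrapolation, %d nodata cells\n",
              format(x$similarity$grid), x$threshold,
              sum(v >= x$threshold, na.rm = TRUE),
              sum(v < x$threshold, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' @export
autoplot.mess_surface <- function(object, ...) {
  autoplot(object$similarity) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = object$threshold) +
    ggplot2::labs(fill = "MESS similarity")
}

#' Classify occurrence records against a similarity surface
#'
#' @param records Tibble with `lon`/`lat`.
#' @param surface A [mess_surface()].
#' @return The records with a `mess_label` column: `"mess_positive"`
#'   (interpolation), `"mess_negative"` (extrapolation) or `"nodata"`
#'   (nodata cell or outside the surface extent).
#' @export
classify_records <- function(records, surface) {
  sim <- raster_value_at(surface$similarity, records$lon, records$lat)
  records$mess_label <- dplyr::case_when(
    is.na(sim) ~ "nodata",
    sim >= surface$threshold ~ "mess_positive",
    TRUE ~ "mess_negative")
  records
}
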