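#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text interchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by one
#' row of cell values per line, north to south. Logical rasters are
#' written as 0/1.
#'
#' @param raster A [grid_raster()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel written for `NA` cells (default -9999).
#' @param digits Significant digits for numeric values (default 10).
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999, digits = 10) {
  g <- raster$grid
  v <- raster$values
  if (is.logical(v)) v <- v + 0L
  header <- c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymax - g$nrow * g$res),
    sprintf("cellsize %.10g", g$res),
    sprintf("NODATA_value %g", nodata))
  fmt <- function(row) {
    s <- formatC(row, digits = digits, format = "g")
    s[is.na(row)] <- as.character(nodata)
    paste(s, collapse = " ")
  }
  lines <- vapply(seq_len(g$nrow), function(r) fmt(v[r, ]), character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param name Optional layer name.
#' @return A [grid_raster()] (`NA` where the nodata sentinel occurs).
#' @export
read_ascii_grid <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  ncol <- as.integer(hdr$ncols); nrow <- as.integer(hdr$nrows)
  vals <- matrix(NA_real_, nrow, ncol)
  for (r in seq_len(nrow)) {
    vals[r, ] <- as.numeric(strsplit(trimws(lines[6 + r]), "\\s+")[[1]])
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  grid <- grid_spec(xmin = hdr$xllcorner,
                    ymax = hdr$yllcorner + nrow * hdr$cellsize,
                    res = hdr$cellsize, nrow = nrow, ncol = ncol)
  grid_raster(grid, vals, name = name)
}

#' Write a polygon set as GeoJSON
#'
#' Features become GeoJSON `Polygon`s (one ring per `ring_id`, closed on
#' write) with their `feature_id` as a property; any extra per-feature
#' attribute columns in `attributes` are carried along.
#'
#' @param poly A [poly_set()].
#' @param path Output path.
#' @param attributes Optional tibble keyed by `feature_id` with extra
#'   properties.
#' @return Invisibly, `path`.
#' @export
write_geojson <- function(poly, path, attributes = NULL) {
  feats <- lapply(unique(poly$feature_id), function(fid) {
    feat <- poly[poly$feature_id == fid, ]
    rings <- lapply(unique(feat$ring_id), function(rid) {
      ring <- feat[feat$ring_id == rid, ]
      coords <- cbind(ring$x, ring$y)
      coords <- rbind(coords, coords[1, , drop = FALSE])  # close ring
      lapply(seq_len(nrow(coords)), function(i) c(coords[i, 1], coords[i, 2]))
    })
    props <- list(feature_id = fid)
    if (!is.null(attributes)) {
      extra <- attributes[attributes$feature_id == fid, , drop = FALSE]
      if (nrow(extra) == 1) {
        for (nm in setdiff(names(extra), "feature_id")) props[[nm]] <- extra[[nm]]
      }
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features. Feature ids come from a
#' `feature_id` property, falling back to an `id` member or a running
#' index.
#'
#' @param path GeoJSON file path.
#' @return A list: `poly` (a [poly_set()]) and `attributes` (tibble of
#'   feature properties).
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) abort("expected a FeatureCollection")
  rows <- list(); attrs <- list()
  for (i in seq_along(obj$features)) {
    f <- obj$features[[i]]
    fid <- f$properties$feature_id %||% f$id %||% sprintf("feature_%d", i)
    geom <- f$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    abort(sprintf("unsupported geometry type %s", geom$type)))
    rid <- 0L
    for (p in polys) for (ring in p) {
      rid <- rid + 1L
      xy <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      # drop the closing vertex if the ring is explicitly closed
      if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
      rows[[length(rows) + 1]] <- tibble(feature_id = as.character(fid), ring_id = rid,
                                         x = xy[, 1], y = xy[, 2])
    }
    pr <- f$properties
    pr$feature_id <- as.character(fid)
    attrs[[length(attrs) + 1]] <- as_tibble(pr[!vapply(pr, is.list, logical(1))])
  }
  poly <- bind_rows(rows)
  class(poly) <- c("poly_set", class(poly))
  list(poly = poly, attributes = bind_rows(attrs))
}

#' Write a covariate stack as ASCII grids plus a band manifest
#'
#' @param covariates A [covariate_stack()].
#' @param dir Output directory (created if needed); bands become
#'   `<band>.asc` plus `bands.csv` listing them in order.
#' @return Invisibly, `dir`.
#' @export
write_covariates <- function(covariates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(covariates$bands)) {
    write_ascii_grid(grid_raster(covariates$grid, covariates$bands[[nm]], name = nm),
                     file.path(dir, paste0(nm, ".asc")))
  }
  readr::write_csv(tibble(band = names(covariates$bands),
                          file = paste0(names(covariates$bands), ".asc")),
                   file.path(dir, "bands.csv"))
  invisible(dir)
}

#' Read a covariate stack written by [write_covariates()]
#'
#' @param dir Directory containing `bands.csv` and the `.asc` files.
#' @return A [covariate_stack()].
#' @export
read_covariates <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "bands.csv"), show_col_types = FALSE)
  bands <- list(); grid <- NULL
  for (i in seq_len(nrow(manifest))) {
    r <- read_ascii_grid(file.path(dir, manifest$file[i]), name = manifest$band[i])
    if (is.null(grid)) grid <- r$grid
    else check_same_grid(grid, r, "first band", manifest$file[i])
    bands[[manifest$band[i]]] <- r$values
  }
  covariate_stack(grid, bands)
}

#' Read an analysis configuration file
#'
#' YAML file holding the tunable constants of the analysis; missing keys
#' take the documented defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list (see [default_config()]).
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

#' Default analysis configuration
#'
#' @return Named list: `min_records_group_c` (5), `buffer_radius_deg`
#'   (0.898), `travel_thresholds_min` (60 and 180), `vulnerable_deciles`
#'   (1-3), `mortality_slope_pct_per_hour` (1.01),
#'   `mess_positive_threshold` (0).
#' @export
default_config <- function() {
  list(min_records_group_c = 5L,
       buffer_radius_deg = 0.898,
       travel_thresholds_min = c(60, 180),
       vulnerable_deciles = 1:3,
       mortality_slope_pct_per_hour = 1.01,
       mess_positive_threshold = 0)
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_records_group_c > 0,
            cfg$buffer_radius_deg > 0,
            all(cfg$travel_thresholds_min > 0),
            all(cfg$vulnerable_deciles %in% 1:10),
            cfg$mortality_slope_pct_per_hour > 0)
  invisible(cfg)
}
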