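#' Tidy polygon sets
#'
#' Vector geometries are represented as plain tibbles with one row per
#' vertex and columns `feature_id`, `ring_id`, `x`, `y` (WGS84 decimal
#' degrees, rings implicitly closed). A feature may have several rings;
#' membership within a feature follows the even-odd rule, so interior rings
#' act as holes. A geometry is the union of its features. Points lying
#' exactly on a ring boundary count as inside (deterministic, inclusive
#' convention used throughout the pipeline).
#'
#' @param feature_id Feature identifier (character or factor-able).
#' @param ring_id Ring index within the feature.
#' @param x,y Vertex coordinates.
#' @return A `poly_set` tibble.
#' @export
poly_set <- function(feature_id, ring_id, x, y) {
  out <- tibble(feature_id = as.character(feature_id),
                ring_id = as.integer(ring_id),
                x = as.numeric(x), y = as.numeric(y))
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    abort("polygon vertices must be finite")
  }
  class(out) <- c("poly_set", class(out))
  out
}

#' Axis-aligned rectangle as a polygon feature
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @param feature_id Feature identifier.
#' @return A `poly_set` with one rectangular feature.
#' @export
rect_poly <- function(xmin, xmax, ymin, ymax, feature_id = "rect") {
  poly_set(feature_id, 1L,
           x = c(xmin, xmax, xmax, xmin),
           y = c(ymin, ymin, ymax, ymax))
}

poly_features <- function(poly) unique(poly$feature_id)

poly_bbox <- function(poly) {
  c(xmin = min(poly$x), xmax = max(poly$x),
    ymin = min(poly$y), ymax = max(poly$y))
}

# Even-odd crossing test for one closed ring, vectorised over points.
# Returns list(inside = crossing parity, boundary = on-edge flag).
ring_test <- function(rx, ry, px, py, eps = 1e-9) {
  n <- length(rx)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- rx[j]; y1 <- ry[j]; x2 <- rx[i]; y2 <- ry[i]
    # on-segment: collinear within eps and inside the segment's bbox
    dx <- x2 - x1; dy <- y2 - y1
    cross <- dx * (py - y1) - dy * (px - x1)
    seg_len <- sqrt(dx * dx + dy * dy)
    tol <- eps * max(1, seg_len)
    on_seg <- abs(cross) <= tol &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | on_seg
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) / (y2 - y1) * dx
      hit <- px[crosses] < xi
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  list(inside = inside, boundary = boundary)
}

#' Point-in-polygon membership
#'
#' Even-odd (ray casting) test against every feature of a [poly_set()];
#' a point is a member if it is inside or on the boundary of any feature.
#'
#' @param poly A `poly_set`.
#' @param x,y Point coordinates (equal length).
#' @param boundary Either `"inside"` (default: boundary points count as
#'   members) or `"outside"`.
#' @return Logical vector, one element per point.
#' @export
points_in_poly <- function(poly, x, y, boundary = c("inside", "outside")) {
  boundary <- match.arg(boundary)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  member <- logical(length(x))
  if (nrow(poly) == 0 || length(x) == 0) return(member)
  for (fid in unique(poly$feature_id)) {
    feat <- poly[poly$feature_id == fid, ]
    bb <- poly_bbox(feat)
    cand <- which(!member &
                    x >= bb["xmin"] - 1e-9 & x <= bb["xmax"] + 1e-9 &
                    y >= bb["ymin"] - 1e-9 & y <= bb["ymax"] + 1e-9)
    if (length(cand) == 0) next
    parity <- logical(length(cand))
    on_bdy <- logical(length(cand))
    for (rid in unique(feat$ring_id)) {
      ring <- feat[feat$ring_id == rid, ]
      res <- ring_test(ring$x, ring$y, x[cand], y[cand])
      parity <- xor(parity, res$inside)
      on_bdy <- on_bdy | res$boundary
    }
    inside <- if (boundary == "inside") parity | on_bdy else parity & !on_bdy
    member[cand] <- member[cand] | inside
  }
  member
}

# Clip a single ring (matrix of x,y) to the half-plane a*x + b*y <= c
# (Sutherland-Hodgman step). Returns a matrix, possibly with 0 rows.
clip_ring_halfplane <- function(xy, a, b, cval) {
  n <- nrow(xy)
  if (n == 0) return(xy)
  out_x <- numeric(0); out_y <- numeric(0)
  s <- xy[n, ]
  s_in <- a * s[1] + b * s[2] <= cval
  for (i in seq_len(n)) {
    p <- xy[i, ]
    p_in <- a * p[1] + b * p[2] <= cval
    if (p_in) {
      if (!s_in) {
        t <- (cval - a * s[1] - b * s[2]) / (a * (p[1] - s[1]) + b * (p[2] - s[2]))
        out_x <- c(out_x, s[1] + t * (p[1] - s[1]))
        out_y <- c(out_y, s[2] + t * (p[2] - s[2]))
      }
      out_x <- c(out_x, p[1]); out_y <- c(out_y, p[2])
    } else if (s_in) {
      t <- (cval - a * s[1] - b * s[2]) / (a * (p[1] - s[1]) + b * (p[2] - s[2]))
      out_x <- c(out_x, s[1] + t * (p[1] - s[1]))
      out_y <- c(out_y, s[2] + t * (p[2] - s[2]))
    }
    s <- p; s_in <- p_in
  }
  cbind(out_x, out_y)
}

# Split one convex ring at the antimeridian: parts outside [-180, 180]
# are wrapped by +/-360. Returns a list of rings (matrices).
split_antimeridian <- function(xy) {
  parts <- list()
  main <- clip_ring_halfplane(clip_ring_halfplane(xy, 1, 0, 180), -1, 0, 180)
  if (nrow(main) >= 3) parts <- c(parts, list(main))
  east <- clip_ring_halfplane(xy, -1, 0, -180)      # x >= 180
  if (nrow(east) >= 3) {
    east[, 1] <- east[, 1] - 360
    parts <- c(parts, list(east))
  }
  west <- clip_ring_halfplane(xy, 1, 0, -180)       # x <= -180
  if (nrow(west) >= 3) {
    west[, 1] <- west[, 1] + 360
    parts <- c(parts, list(west))
  }
  parts
}

#' Disc buffers around points
#'
#' Builds one planar disc (in degree space) of radius `radius_deg` around
#' each point, approximated by a regular polygon. Discs crossing the
#' antimeridian are split at +/-180 degrees and the overhang wrapped.
#' Discs are kept as separate features; membership in the buffered geometry
#' is membership in any disc, so coincident or overlapping discs behave as
#' their union.
#'
#' @param points A data frame with columns `x` and `y` (or `lon`/`lat`).
#' @param radius_deg Buffer radius in decimal degrees (default 0.898,
#'   roughly 100 km at the equator).
#' @param n_segments Number of polygon segments per disc (default 64).
#' @return A `poly_set`, empty if `points` has no rows.
#' @export
buffer_records <- function(points, radius_deg = 0.898, n_segments = 64) {
  stopifnot(radius_deg > 0, n_segments >= 8)
  if (!all(c("x", "y") %in% names(points))) {
    if (all(c("lon", "lat") %in% names(points))) {
      points <- dplyr::rename(points, x = "lon", y = "lat")
    } else {
      abort("points must have columns x/y or lon/lat")
    }
  }
  if (nrow(points) == 0) {
    return(poly_set(character(0), integer(0), numeric(0), numeric(0)))
  }
  ang <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  ux <- cos(ang); uy <- sin(ang)
  pieces <- list()
  for (i in seq_len(nrow(points))) {
    ring <- cbind(points$x[i] + radius_deg * ux, points$y[i] + radius_deg * uy)
    parts <- if (min(ring[, 1]) < -180 || max(ring[, 1]) > 180) {
      split_antimeridian(ring)
    } else list(ring)
    for (k in seq_along(parts)) {
      pieces[[length(pieces) + 1]] <- tibble(
        feature_id = sprintf("disc_%d_%d", i, k), ring_id = 1L,
        x = parts[[k]][, 1], y = parts[[k]][, 2])
    }
  }
  out <- bind_rows(pieces)
  class(out) <- c("poly_set", class(out))
  out
}

# Signed shoelace area of one ring.
ring_area <- function(rx, ry) {
  n <- length(rx)
  j <- c(n, seq_len(n - 1))
  abs(sum(rx[j] * ry - rx * ry[j])) / 2
}

#' Area of a polygon set
#'
#' For a single simple feature the shoelace formula is exact. For possibly
#' overlapping features (e.g. a union of buffer discs) the area is measured
#' numerically by counting membership of a fine regular lattice of sample
#' points over the bounding box.
#'
#' @param poly A `poly_set`.
#' @param n Lattice points per axis for the numeric path (default 400).
#' @return Area in square degrees.
#' @export
poly_area <- function(poly, n = 400) {
  if (nrow(poly) == 0) return(0)
  feats <- unique(poly$feature_id)
  if (length(feats) == 1 && length(unique(poly$ring_id)) == 1) {
    return(ring_area(poly$x, poly$y))
  }
  bb <- poly_bbox(poly)
  xs <- seq(bb["xmin"], bb["xmax"], length.out = n)
  ys <- seq(bb["ymin"], bb["ymax"], length.out = n)
  gx <- rep(xs, times = n); gy <- rep(ys, each = n)
  frac <- mean(points_in_poly(poly, gx, gy))
  unname(frac * (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"]))
}

#' Rasterize a geometry onto an analysis grid
#'
#' A cell is marked present when its centre lies inside the geometry
#' (`touch = "centre"`, the default). The `"any"` alternative marks a cell
#' when any point of a 3 x 3 subsample of the cell is inside (an
#' approximation to all-touched rasterization).
#'
#' @param geometry A [poly_set()] or a [build_contemporary_range()] result.
#' @param grid A [grid_spec()].
#' @param touch `"centre"` or `"any"`.
#' @return A logical [grid_raster()].
#' @export
rasterize_range <- function(geometry, grid, touch = c("centre", "any")) {
  touch <- match.arg(touch)
  contains <- function(x, y) {
    if (inherits(geometry, "contemporary_range")) {
      range_contains(geometry, x, y)
    } else {
      points_in_poly(geometry, x, y)
    }
  }
  if (touch == "centre") {
    cc <- cell_centres(grid)
    inside <- contains(cc$x, cc$y)
  } else {
    offs <- c(-1, 0, 1) / 3 * grid$res
    cc <- cell_centres(grid)
    inside <- logical(nrow(cc))
    for (dx in offs) for (dy in offs) {
      inside <- inside | contains(cc$x + dx, cc$y + dy)
    }
  }
  grid_raster(grid, matrix(inside, nrow = grid$nrow, ncol = grid$ncol,
                           byrow = TRUE))
}
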