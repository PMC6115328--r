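#' Select occurrence records outside the expert-opinion range
#'
#' Returns exactly the records whose point is neither inside nor on the
#' boundary of the range geometry (the boundary counts as inside).
#'
#' @param records Tibble with `lon`/`lat` (deduplicated).
#' @param eor A [poly_set()].
#' @return The subset of `records` lying outside.
#' @export
select_outside_records <- function(records, eor) {
  inside <- points_in_poly(eor, records$lon, records$lat)
  records[!inside, , drop = FALSE]
}

#' Build a species' contemporary range
#'
#' The proposed contemporary range is the expert-opinion range merged with
#' the environmentally screened amendment: the union of the buffer discs
#' around valid (MESS-positive) outside records, intersected with the
#' similarity surface's interpolation cells (each treated as a square
#' polygon on the analysis grid). The result always contains the
#' expert-opinion range; with no MESS-positive outside records it equals
#' it exactly.
#'
#' Membership is evaluated lazily: a point is in the range iff it is in the
#' expert range, or in a buffer disc *and* in an interpolation cell of the
#' surface. Cells outside the surface extent, or nodata cells, never count
#' as interpolation, so buffers are implicitly clipped to covariate
#' coverage.
#'
#' @param eor A [poly_set()] expert-opinion range.
#' @param buffered A [poly_set()] of buffer discs (possibly empty), from
#'   [buffer_records()].
#' @param surface A [mess_surface()], or `NULL` when there is nothing to
#'   amend.
#' @return An object of class `contemporary_range`.
#' @export
build_contemporary_range <- function(eor, buffered, surface = NULL) {
  amended <- nrow(buffered) > 0 && !is.null(surface)
  structure(list(eor = eor,
                 buffered = buffered,
                 surface = if (amended) surface else NULL,
                 amended = amended),
            class = "contemporary_range")
}

#' @export
print.contemporary_range <- function(x, ...) {
  cat(sprintf("<contemporary_range> %s expert range%s\n",
              if (x$amended) "amended" else "unamended",
              if (x$amended)
                sprintf(" (+%d buffer disc features)",
                        length(unique(x$buffered$feature_id))) else ""))
  invisible(x)
}

#' Point membership in a contemporary range
#'
#' @param range A [build_contemporary_range()] result.
#' @param x,y Point coordinates.
#' @return Logical vector.
#' @export
range_contains <- function(range, x, y) {
  inside <- points_in_poly(range$eor, x, y)
  if (range$amended && any(!inside)) {
    cand <- which(!inside)
    in_buf <- points_in_poly(range$buffered, x[cand], y[cand])
    if (any(in_buf)) {
      idx <- cand[in_buf]
      interp <- raster_value_at(range$surface$mask, x[idx], y[idx])
      interp[is.na(interp)] <- FALSE
      inside[idx] <- interp
    }
  }
  inside
}

#' Refine one species' range end to end
#'
#' Runs the full per-species refinement: fit the similarity model on
#' within-range records, classify outside records, buffer the
#' MESS-positive ones, and merge. Species whose fit is refused (fewer than
#' two usable training records) or that have no MESS-positive outside
#' records keep their unamended expert range.
#'
#' @param records Deduplicated occurrence tibble for one species
#'   (`lon`/`lat`).
#' @param eor The species' [poly_set()] expert range.
#' @param covariates A [covariate_stack()].
#' @param buffer_radius_deg Buffer radius in decimal degrees.
#' @param threshold Interpolation threshold for the similarity surface.
#' @return A list: `range` (a `contemporary_range`), `surface` (the
#'   [mess_surface()] or `NULL`), `outside` (outside records with their
#'   `mess_label`), and `fit_refused` (logical).
#' @export
refine_species_range <- function(records, eor, covariates,
                                 buffer_radius_deg = 0.898, threshold = 0) {
  empty <- poly_set(character(0), integer(0), numeric(0), numeric(0))
  fit <- tryCatch(mess_fit(records, eor, covariates),
                  snakevuln_insufficient_training = function(e) NULL)
  if (is.null(fit)) {
    return(list(range = build_contemporary_range(eor, empty, NULL),
                surface = NULL, outside = NULL, fit_refused = TRUE))
  }
  surface <- mess_surface(fit, covariates, threshold = threshold)
  outside <- select_outside_records(records, eor)
  outside <- classify_records(outside, surface)
  pos <- outside[outside$mess_label == "mess_positive", , drop = FALSE]
  buffered <- if (nrow(pos) > 0) {
    buffer_records(tibble(x = pos$lon, y = pos$lat), buffer_radius_deg)
  } else empty
  list(range = build_contemporary_range(eor, buffered, surface),
       surface = surface, outside = outside, fit_refused = FALSE)
}
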