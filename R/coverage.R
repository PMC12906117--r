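# Coverage analysis: union of isochrones per facility category, population
# masking of the raster, and coverage tables (absolute and percentage) per
# threshold.
#
# Denominator conventions are explicit and carried in every output row:
#  * fixed_national  - a supplied national population figure;
#  * raster_total    - the sum of the population raster;
#  * category_sum    - sum of the benefit categories (benefit tables only).

denominator_conventions <- c("fixed_national", "raster_total", "category_sum")

#' Union of isochrones at one threshold
#'
#' Dissolves the isochrones of several facility sets (or of several
#' facilities) into one composite coverage area. Idempotent for a single
#' set. All sets must share the speed multiplier and grid geometry.
#'
#' @param sets a single `isochrone_set` or a list of them.
#' @param threshold threshold minutes, present in every set.
#' @return object of class `coverage_mask` (logical cell mask + geometry).
#' @export
union_isochrones <- function(sets, threshold) {
  if (inherits(sets, "isochrone_set")) sets <- list(sets)
  if (!length(sets)) stop_invalid("no isochrone sets supplied")
  mult <- unique(vapply(sets, function(s) s$multiplier, 0))
  if (length(mult) != 1)
    stop_invalid("mixed speed multipliers: %s", paste(mult, collapse = ", "))
  key <- as.character(threshold)
  masks <- lapply(sets, function(s) {
    if (!key %in% names(s$masks))
      stop_invalid("threshold %s not present in set '%s'", key, s$label)
    check_same_geometry(s, sets[[1]], "isochrone sets")
    s$masks[[key]]
  })
  structure(list(mask = Reduce(`|`, masks),
                 geometry = sets[[1]]$geometry,
                 threshold_min = as.numeric(threshold),
                 multiplier = mult),
            class = "coverage_mask")
}

#' Area of a coverage mask in km2
#' @param mask a `coverage_mask`.
#' @return scalar km2.
#' @export
mask_area_km2 <- function(mask) {
  sum(mask$mask) * (mask$geometry$cell_size_m / 1000)^2
}

#' Population inside a polygon or coverage mask
#'
#' Sums population over the cells whose centres fall inside the geometry
#' (cell-centre rule, so masking and grid classification agree exactly).
#'
#' @param polygon a `coverage_mask`, a logical matrix, a single polygon
#'   ring (closed two-column matrix), or a list of rings.
#' @param pop a population `grid_raster` in the same coordinate frame.
#' @return persons (scalar).
#' @export
population_within <- function(polygon, pop) {
  stopifnot(inherits(pop, "grid_raster"))
  if (inherits(polygon, "coverage_mask")) {
    check_same_geometry(polygon, pop, "mask and raster")
    return(sum(pop$values[polygon$mask]))
  }
  if (is.logical(polygon) && is.matrix(polygon)) {
    if (!identical(dim(polygon), dim(pop$values)))
      stop_invalid("mask and raster dimensions differ")
    return(sum(pop$values[polygon]))
  }
  rings <- if (is.matrix(polygon)) list(polygon) else polygon
  if (!length(rings)) return(0)
  mask <- rings_to_mask(rings, grid_geometry(pop))
  sum(pop$values[mask])
}

#' Isochrone sets for registry categories
#'
#' Computes one multi-source travel-time field and its isochrones per
#' facility category of a registry.
#'
#' @param registry a `facility_registry`.
#' @param network a `road_network`.
#' @param grid analysis grid (`grid_raster`).
#' @param categories registry set names (default all seven).
#' @param multiplier speed multiplier.
#' @param thresholds isochrone thresholds in minutes.
#' @param ... passed to [compute_travel_time_field()].
#' @return named list of `isochrone_set`s.
#' @export
category_isochrones <- function(registry, network, grid,
                                categories = names(registry$sets),
                                multiplier = 1,
                                thresholds = iso_thresholds_default, ...) {
  stopifnot(inherits(registry, "facility_registry"))
  out <- list()
  for (cat in categories) {
    fac <- registry_set_facilities(registry, cat)
    if (nrow(fac) == 0) {
      warning(sprintf("category '%s' is empty; skipped", cat), call. = FALSE)
      next
    }
    fld <- compute_travel_time_field(network, fac, grid,
                                     multiplier = multiplier,
                                     label = cat, ...)
    out[[cat]] <- isochrone_polygons(fld, thresholds)
  }
  out
}

#' Coverage table
#'
#' One row per (facility category, threshold): covered population, the
#' denominator under the stated convention, and the display percentage
#' (rounded half-up to one decimal).
#'
#' @param registry a `facility_registry` (used to order/limit categories).
#' @param isochrones named list of `isochrone_set`s, as from
#'   [category_isochrones()].
#' @param pop population `grid_raster`.
#' @param thresholds thresholds to report (default 15/30/45/60 min).
#' @param denominator `"raster_total"` (default) or `"fixed_national"`.
#' @param fixed_value national population used when
#'   `denominator = "fixed_national"`.
#' @return data.frame of class `coverage_table` with columns `category,
#'   threshold_min, speed_multiplier, covered_pop, denominator,
#'   denominator_convention, pct`.
#' @export
coverage_table <- function(registry, isochrones, pop,
                           thresholds = c(15, 30, 45, 60),
                           denominator = c("raster_total", "fixed_national"),
                           fixed_value = 83420000) {
  denominator <- match.arg(denominator)
  denom <- switch(denominator,
                  raster_total = raster_total(pop),
                  fixed_national = fixed_value)
  cats <- intersect(names(registry$sets), names(isochrones))
  rows <- list()
  for (cat in cats) {
    iso <- isochrones[[cat]]
    for (t in thresholds) {
      covered <- population_within(union_isochrones(iso, t), pop)
      rows[[length(rows) + 1]] <- data.frame(
        category = cat, threshold_min = t,
        speed_multiplier = iso$multiplier,
        covered_pop = covered, denominator = denom,
        denominator_convention = denominator,
        pct = pct_round(covered, denom))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("coverage_table", class(out))
  out
}
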