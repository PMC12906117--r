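# Urbanisation and regional breakdowns: settlement-class composition of
# coverage/benefit areas, area accounting in km2, and per-state/county
# re-aggregation of the national tables. Region membership is by cell
# centre, so counties partition their state and population is conserved
# exactly across aggregation levels.

#' Classify settlement-model codes
#'
#' Urban: codes 30, 23, 22, 21 (urban centres, towns, suburbs);
#' rural: 13, 12, 11; everything else (water code 10 and unknown codes) is
#' "other". Total: every code maps to exactly one class.
#'
#' @param code integer vector or matrix of settlement codes.
#' @return character vector/matrix with values `"urban"`, `"rural"`,
#'   `"other"`.
#' @export
classify_settlement <- function(code) {
  out <- ifelse(code %in% c(30L, 23L, 22L, 21L), "urban",
                ifelse(code %in% c(13L, 12L, 11L), "rural", "other"))
  if (is.matrix(code)) out <- matrix(out, nrow(code), ncol(code))
  out
}

settlement_class_levels <- c("urban", "rural", "other")

#' Urban/rural area shares of a mask
#'
#' Per settlement class: area inside the mask (cell count times cell area)
#' and two share conventions, both reported because coverage results are
#' quoted in both styles: `composition_pct` (share of the mask itself,
#' sums to 100) and `coverage_of_class_pct` (share of that class's total
#' area in the whole extent).
#'
#' @param mask a `coverage_mask` or logical matrix.
#' @param settlement settlement-code `grid_raster`.
#' @return data.frame with rows urban/rural/other and columns
#'   `settlement_class, area_km2, composition_pct, coverage_of_class_pct`.
#' @export
area_shares <- function(mask, settlement) {
  stopifnot(inherits(settlement, "grid_raster"))
  m <- if (inherits(mask, "coverage_mask")) {
    check_same_geometry(mask, settlement, "mask and settlement raster")
    mask$mask
  } else mask
  if (!identical(dim(m), dim(settlement$values)))
    stop_invalid("mask and settlement raster dimensions differ")
  cls <- classify_settlement(settlement$values)
  cell_km2 <- (settlement$cell_size_m / 1000)^2
  in_mask <- vapply(settlement_class_levels,
                    function(k) sum(m & cls == k) * cell_km2, 0)
  in_extent <- vapply(settlement_class_levels,
                      function(k) sum(cls == k) * cell_km2, 0)
  data.frame(settlement_class = settlement_class_levels,
             area_km2 = unname(in_mask),
             composition_pct = pct_round(in_mask, sum(in_mask)),
             coverage_of_class_pct = pct_round(in_mask, in_extent),
             row.names = NULL)
}

# Logical mask of the cells belonging to one admin region.
region_mask <- function(regions, region_id) {
  r <- regions$regions[regions$regions$id == region_id, ]
  if (nrow(r) != 1) stop_invalid("unknown region id %s", region_id)
  if (r$level == "state") regions$state_raster$values == region_id
  else regions$county_raster$values == region_id
}

#' Regional coverage and benefit tables
#'
#' Repeats coverage and/or benefit aggregation within every state and
#' county. Cells belong to exactly one region (cell-centre rule), each
#' region's denominator is its own raster total, and county rows sum to
#' their state row exactly.
#'
#' @param outputs named list with optional elements `coverage` (named list
#'   of `isochrone_set`s, as for [coverage_table()]) and `benefit` (a
#'   `benefit_grid` or named list of them).
#' @param regions an `admin_regions` object.
#' @param pop population `grid_raster`.
#' @param settlement optional settlement `grid_raster`; adds per-region
#'   urban area columns.
#' @param thresholds coverage thresholds to report.
#' @return data.frame of class `regional_table` with columns `region_id,
#'   region_name, level, parent, kind, category, threshold_min,
#'   scenario_id, population, region_population, pct, area_km2` (plus
#'   `urban_area_km2` when `settlement` is given).
#' @export
regional_tables <- function(outputs, regions, pop, settlement = NULL,
                            thresholds = c(15, 30, 45, 60)) {
  stopifnot(inherits(regions, "admin_regions"), inherits(pop, "grid_raster"))
  check_same_geometry(regions$state_raster, pop, "regions and raster")
  cell_km2 <- (pop$cell_size_m / 1000)^2
  cls <- if (!is.null(settlement)) classify_settlement(settlement$values)
  rows <- list()
  add <- function(reg, kind, category, threshold_min, scenario_id, sel,
                  rmask, rpop) {
    n <- sum(pop$values[sel & rmask])
    row <- data.frame(region_id = reg$id, region_name = reg$name,
                      level = reg$level, parent = reg$parent, kind = kind,
                      category = category, threshold_min = threshold_min,
                      scenario_id = scenario_id, population = n,
                      region_population = rpop,
                      pct = pct_round(n, rpop),
                      area_km2 = sum(sel & rmask) * cell_km2)
    if (!is.null(cls))
      row$urban_area_km2 <- sum(sel & rmask & cls == "urban") * cell_km2
    rows[[length(rows) + 1]] <<- row
  }
  benefit <- outputs$benefit
  if (inherits(benefit, "benefit_grid")) benefit <- list(benefit)
  for (k in seq_len(nrow(regions$regions))) {
    reg <- regions$regions[k, ]
    rmask <- region_mask(regions, reg$id)
    rpop <- sum(pop$values[rmask])
    if (!is.null(outputs$coverage)) {
      for (cat in names(outputs$coverage)) {
        iso <- outputs$coverage[[cat]]
        for (t in intersect(thresholds, iso$thresholds)) {
          add(reg, "coverage", cat, t, NA_character_,
              iso$masks[[as.character(t)]], rmask, rpop)
        }
      }
    }
    if (!is.null(benefit)) {
      for (g in benefit) {
        for (code in seq_along(benefit_categories) - 1L) {
          add(reg, "benefit", benefit_categories[code + 1L], NA_real_,
              g$scenario$id, g$categories == code, rmask, rpop)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("regional_table", class(out))
  out
}
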