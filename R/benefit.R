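# Benefit analysis - the core comparison: per-cell travel time to the
# nearest CT-equipped hospital versus the nearest specialised facility
# (certified stroke unit or stroke-ready hospital), classified into
# hub-and-spoke benefit categories under driving-speed and in-hospital
# delay scenarios, then aggregated over the population raster.
#
# Classification rule (horizon 60 min, benefit threshold 10 min):
#   target unreachable & CT unreachable -> neither_reachable
#   target unreachable & CT reachable   -> only_ct_reachable
#   otherwise, saving = t_target - (t_ct + penalty):
#     saving <  10        -> irrelevant
#     10 <= saving < 20   -> low
#     20 <= saving < 30   -> medium
#     saving >= 30        -> high
# "Reachable" means time <= 60 (a facility at exactly 60.0 min counts).
# The delay penalty is added to the CT time after routing and, by default,
# does NOT enter the 60-min reachability test (so the only-CT and neither
# rows are invariant across penalty scenarios); set
# `penalty_affects_reachability = TRUE` for the stricter reading.

#' Benefit category labels
#'
#' Integer codes 0..5 in grid rasters map, in order, to these labels.
#' @export
benefit_categories <- c("neither_reachable", "only_ct_reachable",
                        "irrelevant", "low", "medium", "high")

#' Scenario specification
#'
#' The six canonical scenarios are multipliers 1.0/1.2/0.8 at penalty 0,
#' and penalties 10/20/30 min at multiplier 1.0. Other combinations are
#' permitted but flagged non-canonical.
#'
#' @param multiplier driving-speed multiplier (> 0).
#' @param penalty_min minutes added to CT-hospital access.
#' @param target comparison facility set: `"certified"` or
#'   `"stroke_ready"`.
#' @return object of class `scenario_spec` with an `id` such as
#'   `"penalty_10"`.
#' @export
scenario_spec <- function(multiplier = 1, penalty_min = 0,
                          target = c("certified", "stroke_ready")) {
  target <- match.arg(target)
  if (multiplier <= 0) stop_invalid("multiplier must be > 0")
  if (penalty_min < 0) stop_invalid("penalty must be >= 0")
  canonical <- (penalty_min == 0 && multiplier %in% c(0.8, 1, 1.2)) ||
    (multiplier == 1 && penalty_min %in% c(10, 20, 30))
  id <- if (penalty_min > 0) sprintf("penalty_%g", penalty_min)
        else if (multiplier == 1) "normal"
        else if (multiplier > 1) sprintf("speed_up%g", 100 * (multiplier - 1))
        else sprintf("speed_down%g", 100 * (1 - multiplier))
  structure(list(id = id, multiplier = multiplier,
                 penalty_min = penalty_min, target = target,
                 canonical = canonical),
            class = "scenario_spec")
}

canonical_scenarios <- function(target = "certified") {
  list(scenario_spec(1.0, 0, target),
       scenario_spec(1.2, 0, target),
       scenario_spec(0.8, 0, target),
       scenario_spec(1.0, 10, target),
       scenario_spec(1.0, 20, target),
       scenario_spec(1.0, 30, target))
}

#' Classify travel-time pairs into benefit categories
#'
#' Vectorised over cells; see the classification rule in the package
#' documentation above. Times may be `Inf` (unreachable).
#'
#' @param t_ct minutes to the nearest CT-equipped hospital.
#' @param t_target minutes to the nearest specialised facility.
#' @param penalty_min in-hospital delay added to the CT time.
#' @param horizon_min reachability horizon (default 60).
#' @param benefit_min clinically significant saving threshold (default 10).
#' @param penalty_affects_reachability if `TRUE`, the penalty also enters
#'   the 60-min reachability test for the CT hospital.
#' @return integer codes 0..5 (same shape as the inputs); see
#'   [benefit_categories].
#' @export
classify_benefit <- function(t_ct, t_target, penalty_min = 0,
                             horizon_min = 60, benefit_min = 10,
                             penalty_affects_reachability = FALSE) {
  if (any(t_ct < 0, na.rm = TRUE) || any(t_target < 0, na.rm = TRUE))
    stop_invalid("travel times must be non-negative")
  eff_ct <- t_ct + penalty_min
  reach_ct <- if (penalty_affects_reachability) eff_ct <= horizon_min
              else t_ct <= horizon_min
  reach_t <- t_target <= horizon_min
  saving <- t_target - eff_ct
  code <- ifelse(!reach_t,
                 ifelse(reach_ct, 1L, 0L),
                 ifelse(saving < benefit_min, 2L,
                        ifelse(saving < benefit_min + 10, 3L,
                               ifelse(saving < benefit_min + 20, 4L, 5L))))
  if (is.matrix(t_ct)) code <- matrix(as.integer(code), nrow(t_ct), ncol(t_ct))
  code
}

#' Build a benefit grid
#'
#' Applies [classify_benefit()] to every cell of two travel-time fields
#' sharing geometry and speed multiplier.
#'
#' @param field_ct `travel_time_field` for the CT-equipped set.
#' @param field_target `travel_time_field` for the comparison set.
#' @param scenario a `scenario_spec`; its multiplier must match the fields.
#' @param ... passed to [classify_benefit()] (boundary-rule toggles).
#' @return object of class `benefit_grid`: `$categories` (integer matrix,
#'   codes 0..5), raw `$t_ct` / `$t_target`, `$scenario`, `$geometry`.
#' @export
build_benefit_grid <- function(field_ct, field_target, scenario, ...) {
  stopifnot(inherits(field_ct, "travel_time_field"),
            inherits(field_target, "travel_time_field"),
            inherits(scenario, "scenario_spec"))
  check_same_geometry(field_ct, field_target, "travel-time fields")
  if (abs(field_ct$multiplier - field_target$multiplier) > 1e-9 ||
      abs(field_ct$multiplier - scenario$multiplier) > 1e-9)
    stop_invalid("field multipliers (%g, %g) inconsistent with scenario (%g)",
                 field_ct$multiplier, field_target$multiplier,
                 scenario$multiplier)
  cats <- classify_benefit(field_ct$values, field_target$values,
                           penalty_min = scenario$penalty_min, ...)
  structure(list(categories = cats, t_ct = field_ct$values,
                 t_target = field_target$values, scenario = scenario,
                 geometry = grid_geometry(field_ct)),
            class = "benefit_grid")
}

#' @export
print.benefit_grid <- function(x, ...) {
  cat(sprintf("<benefit_grid> scenario '%s' (x%g, +%g min), target '%s'\n",
              x$scenario$id, x$scenario$multiplier, x$scenario$penalty_min,
              x$scenario$target))
  print(table(factor(benefit_categories[x$categories + 1L],
                     levels = benefit_categories)))
  invisible(x)
}

#' Benefit population table
#'
#' Population per benefit category (the six categories partition the grid,
#' so they sum to the raster total exactly), plus a derived
#' `beneficiaries_10plus` row (low + medium + high). Percentages follow the
#' stated denominator convention, rounded half-up to one decimal.
#'
#' @param grid a `benefit_grid`.
#' @param pop population `grid_raster` on the same geometry.
#' @param denominator `"category_sum"` (default), `"raster_total"` or
#'   `"fixed_national"`.
#' @param fixed_value national population for `"fixed_national"`.
#' @return data.frame of class `benefit_table` with columns `scenario_id,
#'   speed_multiplier, penalty_min, target, category, population, pct,
#'   denominator, denominator_convention, derived`.
#' @export
benefit_population_table <- function(grid, pop,
                                     denominator = c("category_sum",
                                                     "raster_total",
                                                     "fixed_national"),
                                     fixed_value = 83420000) {
  stopifnot(inherits(grid, "benefit_grid"), inherits(pop, "grid_raster"))
  denominator <- match.arg(denominator)
  check_same_geometry(grid, pop, "benefit grid and raster")
  popc <- vapply(seq_along(benefit_categories) - 1L, function(code)
    sum(pop$values[grid$categories == code]), 0)
  names(popc) <- benefit_categories
  denom <- switch(denominator,
                  category_sum = sum(popc),
                  raster_total = raster_total(pop),
                  fixed_national = fixed_value)
  sc <- grid$scenario
  ben <- sum(popc[c("low", "medium", "high")])
  out <- data.frame(
    scenario_id = sc$id, speed_multiplier = sc$multiplier,
    penalty_min = sc$penalty_min, target = sc$target,
    category = c(benefit_categories, "beneficiaries_10plus"),
    population = c(popc, ben),
    pct = pct_round(c(popc, ben), denom),
    denominator = denom, denominator_convention = denominator,
    derived = c(rep(FALSE, length(popc)), TRUE))
  rownames(out) <- NULL
  class(out) <- c("benefit_table", class(out))
  out
}

#' Run the canonical six-scenario suite
#'
#' Computes baseline (multiplier 1.0) travel-time fields for the
#' CT-equipped set and the comparison target, derives the speed scenarios
#' by exact rescaling, applies penalties at classification time (penalty
#' scenarios reuse the baseline fields), and aggregates each scenario over
#' the population raster.
#'
#' @param registry a `facility_registry`.
#' @param network a `road_network`.
#' @param pop population `grid_raster` (also the analysis grid).
#' @param target `"certified"` (default) or `"stroke_ready"`.
#' @param denominator,fixed_value passed to [benefit_population_table()].
#' @param ... passed to [compute_travel_time_field()] (e.g. access speed).
#' @return object of class `benefit_suite`: `$tables` and `$grids` named by
#'   scenario id, `$fields` the baseline fields, `$table` all six tables
#'   bound together.
#' @export
scenario_suite <- function(registry, network, pop,
                           target = c("certified", "stroke_ready"),
                           denominator = "category_sum",
                           fixed_value = 83420000, ...) {
  target <- match.arg(target)
  stopifnot(inherits(registry, "facility_registry"))
  tgt_fac <- registry_set_facilities(registry, target)
  ct_fac <- registry_set_facilities(registry, "ct_equipped")
  if (nrow(tgt_fac) == 0) stop_invalid("empty target set '%s'", target)
  if (nrow(ct_fac) == 0) stop_invalid("empty CT-equipped set")
  f_ct <- compute_travel_time_field(network, ct_fac, pop,
                                    label = "ct_equipped", ...)
  f_tg <- compute_travel_time_field(network, tgt_fac, pop,
                                    label = target, ...)
  grids <- list()
  tables <- list()
  for (sc in canonical_scenarios(target)) {
    if (sc$multiplier == 1) {
      g <- build_benefit_grid(f_ct, f_tg, sc)
    } else {
      g <- build_benefit_grid(apply_speed_multiplier(f_ct, sc$multiplier),
                              apply_speed_multiplier(f_tg, sc$multiplier),
                              sc)
    }
    grids[[sc$id]] <- g
    tables[[sc$id]] <- benefit_population_table(g, pop, denominator,
                                                fixed_value)
  }
  structure(list(tables = tables, grids = grids,
                 fields = list(ct = f_ct, target = f_tg),
                 table = do.call(rbind, tables)),
            class = "benefit_suite")
}

#' @export
print.benefit_suite <- function(x, ...) {
  cat(sprintf("<benefit_suite> target '%s', %d scenarios\n",
              x$grids[[1]]$scenario$target, length(x$grids)))
  ben <- x$table[x$table$category == "beneficiaries_10plus", ]
  print(ben[, c("scenario_id", "population", "pct")], row.names = FALSE)
  invisible(x)
}

#' Write a benefit grid as an ASCII category raster
#'
#' Cells hold the integer codes 0..5 of [benefit_categories].
#'
#' @param grid a `benefit_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benefit_grid <- function(grid, path) {
  g <- grid$geometry
  write_ascii_grid(grid_raster(grid$categories, g$cell_size_m, g$origin),
                   path)
}
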