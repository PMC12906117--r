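# Pipeline orchestration: configuration, staged execution, file emission
# and simple category maps. Every run is deterministic given its config
# (including the seed inside the region spec) and echoes the config plus a
# checksum manifest into its output directory.

#' Pipeline configuration
#'
#' @param spec a `region_spec` describing the synthetic region (or the
#'   grid/seed for generated inputs).
#' @param out_dir output directory (created if missing).
#' @param facilities optional pre-built facility table; defaults to the
#'   generated one.
#' @param coverage_categories registry sets to report coverage for.
#' @param thresholds coverage thresholds in minutes.
#' @param targets benefit comparison targets to run
#'   (`"certified"`, `"stroke_ready"`).
#' @param denominator denominator convention for coverage tables.
#' @param benefit_denominator denominator convention for benefit tables.
#' @param fixed_value national population for the `fixed_national`
#'   convention.
#' @param access_speed_kmh off-network access-leg speed.
#' @param n_states,counties_per_state administrative partition.
#' @param decoy_fraction decoy rows in the generated facility table.
#' @param include_settlement run the urbanisation stage.
#' @param include_regional run the state/county stage.
#' @param draw_maps render category maps as PNG files.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = region_spec(),
                            out_dir = tempfile("strokeaccess-run-"),
                            facilities = NULL,
                            coverage_categories = c("ct_equipped",
                                                    "stroke_ready",
                                                    "certified",
                                                    "supraregional",
                                                    "regional_or_tele",
                                                    "thrombectomy",
                                                    "tele_only"),
                            thresholds = c(15, 30, 45, 60),
                            targets = "certified",
                            denominator = "raster_total",
                            benefit_denominator = "category_sum",
                            fixed_value = 83420000,
                            access_speed_kmh = 30,
                            n_states = 4, counties_per_state = 3,
                            decoy_fraction = 0.15,
                            include_settlement = TRUE,
                            include_regional = TRUE,
                            draw_maps = TRUE) {
  stopifnot(inherits(spec, "region_spec"))
  targets <- match.arg(targets, c("certified", "stroke_ready"),
                       several.ok = TRUE)
  structure(list(spec = spec, out_dir = out_dir, facilities = facilities,
                 coverage_categories = coverage_categories,
                 thresholds = thresholds, targets = targets,
                 denominator = denominator,
                 benefit_denominator = benefit_denominator,
                 fixed_value = fixed_value,
                 access_speed_kmh = access_speed_kmh,
                 n_states = n_states,
                 counties_per_state = counties_per_state,
                 decoy_fraction = decoy_fraction,
                 include_settlement = include_settlement,
                 include_regional = include_regional,
                 draw_maps = draw_maps),
            class = "pipeline_config")
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$spec <- unclass(out$spec)
  out$facilities <- NULL
  out
}

#' Run the full accessibility pipeline
#'
#' Generates (or accepts) the region inputs, builds the facility registry,
#' computes travel-time fields and isochrones, and emits coverage tables,
#' benefit tables and grids, urbanisation shares, regional tables, maps,
#' the echoed config and a checksum manifest into `config$out_dir`.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with the in-memory results: `region`,
#'   `registry`, `isochrones`, `coverage`, `benefit` (per target),
#'   `urbanisation`, `regional`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  status <- "incomplete"
  on.exit({
    manifest <- list(status = status,
                     files = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  emit <- function(path) files <<- c(files, path)
  stage <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  jsonlite::write_json(config_as_list(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  emit(file.path(config$out_dir, "config.json"))

  region <- stage("simulate", {
    pop <- generate_population_raster(config$spec)
    net <- generate_road_network(config$spec)
    fac <- config$facilities %||%
      generate_facilities(config$spec, pop, net,
                          decoy_fraction = config$decoy_fraction)
    list(population = pop,
         settlement = if (config$include_settlement)
           derive_settlement_raster(pop),
         network = net, facilities = fac,
         regions = if (config$include_regional)
           generate_admin_regions(config$spec, config$n_states,
                                  config$counties_per_state))
  })
  emit(write_ascii_grid(region$population,
                        file.path(config$out_dir, "population.asc")))
  if (!is.null(region$settlement))
    emit(write_ascii_grid(region$settlement,
                          file.path(config$out_dir, "settlement.asc")))
  emit(write_network_geojson(region$network,
                             file.path(config$out_dir, "network.geojson")))
  emit(write_facilities_csv(region$facilities,
                            file.path(config$out_dir, "facilities.csv")))

  registry <- stage("registry", build_registry(region$facilities))
  emit(write_registry_csv(registry,
                          file.path(config$out_dir, "registry.csv")))

  isochrones <- stage("traveltime",
    category_isochrones(registry, region$network, region$population,
                        categories = config$coverage_categories,
                        access_speed_kmh = config$access_speed_kmh))
  if ("certified" %in% names(isochrones))
    emit(write_isochrones_geojson(isochrones$certified,
                                  file.path(config$out_dir,
                                            "isochrones_certified.geojson")))

  coverage <- stage("coverage",
    coverage_table(registry, isochrones, region$population,
                   thresholds = config$thresholds,
                   denominator = config$denominator,
                   fixed_value = config$fixed_value))
  utils::write.csv(coverage, file.path(config$out_dir, "coverage.csv"),
                   row.names = FALSE)
  emit(file.path(config$out_dir, "coverage.csv"))

  benefit <- stage("benefit", {
    out <- list()
    for (tgt in config$targets) {
      suite <- scenario_suite(registry, region$network, region$population,
                              target = tgt,
                              denominator = config$benefit_denominator,
                              fixed_value = config$fixed_value,
                              access_speed_kmh = config$access_speed_kmh)
      path <- file.path(config$out_dir, sprintf("benefit_%s.csv", tgt))
      utils::write.csv(suite$table, path, row.names = FALSE)
      emit(path)
      for (id in names(suite$grids))
        emit(write_benefit_grid(suite$grids[[id]],
                                file.path(config$out_dir,
                                          sprintf("benefit_grid_%s_%s.asc",
                                                  tgt, id))))
      out[[tgt]] <- suite
    }
    out
  })

  urbanisation <- NULL
  if (!is.null(region$settlement)) {
    urbanisation <- stage("urbanisation", {
      rows <- lapply(names(isochrones), function(cat) {
        res <- lapply(config$thresholds, function(t) {
          sh <- area_shares(union_isochrones(isochrones[[cat]], t),
                            region$settlement)
          cbind(category = cat, threshold_min = t, sh)
        })
        do.call(rbind, res)
      })
      do.call(rbind, rows)
    })
    utils::write.csv(urbanisation,
                     file.path(config$out_dir, "urbanisation.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "urbanisation.csv"))
  } else {
    warning("settlement raster not available; urbanisation stage skipped",
            call. = FALSE)
  }

  regional <- NULL
  if (!is.null(region$regions)) {
    regional <- stage("regional",
      regional_tables(list(coverage = isochrones,
                           benefit = benefit[[config$targets[1]]]$grids),
                      region$regions, region$population,
                      settlement = region$settlement,
                      thresholds = config$thresholds))
    utils::write.csv(regional, file.path(config$out_dir, "regional.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "regional.csv"))
  }

  if (config$draw_maps) {
    stage("report", {
      dir.create(file.path(config$out_dir, "maps"), showWarnings = FALSE)
      for (tgt in names(benefit))
        render_maps(benefit[[tgt]]$grids,
                    facilities = registry$facilities,
                    dir = file.path(config$out_dir, "maps"),
                    prefix = sprintf("benefit_%s", tgt))
    })
  }

  status <- "complete"
  invisible(list(region = region, registry = registry,
                 isochrones = isochrones, coverage = coverage,
                 benefit = benefit, urbanisation = urbanisation,
                 regional = regional, files = files))
}

# Stable, injective category -> colour mapping (documented in the legend).
benefit_palette <- c(neither_reachable = "grey55",
                     only_ct_reachable = "lightblue2",
                     irrelevant = "grey92",
                     low = "gold",
                     medium = "darkorange2",
                     high = "red3")

#' Render benefit-category maps
#'
#' One PNG per scenario grid: category-coloured raster with facility points
#' overlaid and a legend. The colour mapping is fixed and injective.
#'
#' @param grids named list of `benefit_grid`s (names become file names).
#' @param facilities optional facility table plotted as points.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param width,height device size in pixels.
#' @return character vector of file paths, invisibly.
#' @export
render_maps <- function(grids, facilities = NULL, dir = ".",
                        prefix = "benefit", width = 800, height = 800) {
  if (inherits(grids, "benefit_grid")) grids <- list(map = grids)
  paths <- character(0)
  for (id in names(grids)) {
    g <- grids[[id]]
    path <- file.path(dir, sprintf("%s_%s.png", prefix,
                                   id %||% g$scenario$id))
    grDevices::png(path, width = width, height = height)
    graphics::par(mar = c(2, 2, 3, 1))
    d <- g$geometry$dim
    if (prod(d) == 0) {
      graphics::plot.new()
      graphics::title(main = sprintf("scenario %s (empty grid)",
                                     g$scenario$id))
    } else {
      s <- g$geometry$cell_size_m
      xs <- g$geometry$origin[1] + (seq_len(d[2]) - 0.5) * s
      ys <- g$geometry$origin[2] + (seq_len(d[1]) - 0.5) * s
      graphics::image(xs / 1000, ys / 1000, t(g$categories),
                      zlim = c(0, 5), col = unname(benefit_palette),
                      asp = 1, xlab = "km", ylab = "km",
                      main = sprintf("Hub-and-spoke benefit: %s (x%g, +%g min)",
                                     g$scenario$id, g$scenario$multiplier,
                                     g$scenario$penalty_min))
      if (!is.null(facilities))
        graphics::points(facilities$x / 1000, facilities$y / 1000,
                         pch = 16, cex = 0.4)
    }
    graphics::legend("topright", legend = names(benefit_palette),
                     fill = unname(benefit_palette), cex = 0.8, bg = "white")
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}
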