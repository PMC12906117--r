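# Travel-time engine: multi-source shortest-path fields over the road
# network, drive-time isochrones at 5-minute steps, and speed-multiplier
# scenarios. This is the internal replacement for an external routing
# service: per-edge time = length / (speed * multiplier), and every grid
# cell receives the time of a straight-line access leg from its centre to
# the nearest network node (default 30 km/h) plus that node's shortest-path
# time to the nearest source. Times are stored exactly; the 60-minute
# horizon is applied only at classification time.

#' Compute a travel-time field
#'
#' Minutes from every grid cell to the nearest facility of a set, via
#' multi-source Dijkstra over the road network. Unreachable cells (network
#' component without a source) hold `Inf`.
#'
#' @param network a `road_network`.
#' @param sources facility rows (data.frame with `x`, `y` and optionally
#'   `node_id`) or a vector of node ids.
#' @param grid a `grid_raster` (or its geometry) defining the analysis
#'   cells.
#' @param multiplier driving-speed multiplier (> 0); scales every speed,
#'   including the access leg.
#' @param access_speed_kmh straight-line speed for the cell-centre to
#'   nearest-node access leg.
#' @param snap_tolerance_m facilities farther than this from any node are
#'   snapped with a warning.
#' @param label facility-set label carried into downstream tables.
#' @return object of class `travel_time_field` (a `grid_raster` of minutes
#'   with fields `label`, `multiplier`, `access_speed_kmh`).
#' @export
compute_travel_time_field <- function(network, sources, grid,
                                      multiplier = 1,
                                      access_speed_kmh = 30,
                                      snap_tolerance_m = 2000,
                                      label = "facilities") {
  stopifnot(inherits(network, "road_network"))
  if (multiplier <= 0) stop_invalid("multiplier must be > 0")
  if (is.data.frame(sources)) {
    if (nrow(sources) == 0) stop_invalid("empty source set")
    if ("node_id" %in% names(sources) &&
        all(sources$node_id %in% network$nodes$id)) {
      src_ids <- unique(sources$node_id)
    } else {
      snap <- nearest_nodes(network, sources$x, sources$y)
      if (any(snap$dist_m > snap_tolerance_m))
        warning(sprintf("%d facilit%s snapped to a node beyond %g m",
                        sum(snap$dist_m > snap_tolerance_m),
                        if (sum(snap$dist_m > snap_tolerance_m) == 1) "y" else "ies",
                        snap_tolerance_m), call. = FALSE)
      src_ids <- unique(snap$node_id)
    }
  } else {
    if (length(sources) == 0) stop_invalid("empty source set")
    if (!all(sources %in% network$nodes$id))
      stop_invalid("source node id(s) not in network")
    src_ids <- unique(sources)
  }
  g <- network_graph_minutes(network, multiplier)
  vidx <- match(src_ids, network$nodes$id)
  D <- igraph::distances(g, v = igraph::V(g)[vidx], to = igraph::V(g),
                         algorithm = "dijkstra")
  node_time <- if (nrow(D) == 1) as.numeric(D) else apply(D, 2, min)
  d <- grid_geometry(grid)$dim
  geom <- grid_geometry(grid)
  template <- grid_raster(matrix(0, d[1], d[2]), geom$cell_size_m, geom$origin)
  cc <- cell_centres(template)
  nn <- nearest_nodes(network, as.vector(cc$x), as.vector(cc$y))
  access_min <- (nn$dist_m / 1000) / (access_speed_kmh * multiplier) * 60
  vals <- matrix(access_min + node_time[nn$node_index], d[1], d[2])
  structure(list(values = vals, cell_size_m = geom$cell_size_m,
                 origin = geom$origin, label = label,
                 multiplier = multiplier,
                 access_speed_kmh = access_speed_kmh,
                 node_times = stats::setNames(node_time,
                                              network$nodes$id)),
            class = c("travel_time_field", "grid_raster"))
}

#' @export
print.travel_time_field <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<travel_time_field> '%s', multiplier %g: %d/%d cells reachable, median %.1f min\n",
    x$label, x$multiplier, length(fin), length(x$values),
    if (length(fin)) stats::median(fin) else NA_real_))
  invisible(x)
}

#' Rescale a travel-time field to another driving speed
#'
#' Uniform scaling of all speeds (edges and access leg) by `m` divides
#' every finite time by `m`; the result equals recomputation from scratch
#' at the scaled speed.
#'
#' @param field a `travel_time_field`.
#' @param m speed multiplier relative to the field's current speeds (> 0).
#' @return a `travel_time_field` at multiplier `field$multiplier * m`.
#' @export
apply_speed_multiplier <- function(field, m) {
  stopifnot(inherits(field, "travel_time_field"))
  if (m <= 0) stop_invalid("multiplier must be > 0")
  field$values <- field$values / m
  field$node_times <- field$node_times / m
  field$multiplier <- field$multiplier * m
  field
}

iso_thresholds_default <- seq(5, 60, by = 5)

#' Isochrones of a travel-time field
#'
#' For each threshold t the isochrone is the union of the closed cells
#' `{cell : time <= t}`, dissolved into a (multi)polygon of cell squares.
#' Nesting in t holds by construction, and polygon masking agrees exactly
#' with grid classification.
#'
#' @param field a `travel_time_field`.
#' @param thresholds minutes; default the twelve 5-minute steps 5..60.
#' @return object of class `isochrone_set`: `$masks` is a named list of
#'   logical matrices, one per threshold.
#' @export
isochrone_polygons <- function(field, thresholds = iso_thresholds_default) {
  stopifnot(inherits(field, "travel_time_field"))
  if (!any(is.finite(field$values)))
    warning("field has no reachable cell; isochrones are empty",
            call. = FALSE)
  masks <- lapply(thresholds, function(t) field$values <= t)
  names(masks) <- as.character(thresholds)
  structure(list(label = field$label, multiplier = field$multiplier,
                 thresholds = thresholds, masks = masks,
                 geometry = grid_geometry(field)),
            class = "isochrone_set")
}

#' @export
print.isochrone_set <- function(x, ...) {
  cat(sprintf("<isochrone_set> '%s', multiplier %g, thresholds %s min\n",
              x$label, x$multiplier,
              paste(range(x$thresholds), collapse = "-")))
  invisible(x)
}

# ---- cell-union polygon geometry ------------------------------------------

# Dissolve a logical cell mask into rectangle rings (one per run of TRUE
# cells in a row); rings are closed 5-point counter-clockwise matrices.
mask_to_rings <- function(mask, cell_size_m, origin) {
  rings <- list()
  s <- cell_size_m
  for (i in seq_len(nrow(mask))) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      x0 <- origin[1] + (starts[k] - 1) * s
      x1 <- origin[1] + ends[k] * s
      y0 <- origin[2] + (i - 1) * s
      y1 <- origin[2] + i * s
      rings[[length(rings) + 1]] <-
        rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    }
  }
  rings
}

# Rasterise polygon rings onto a grid geometry by the cell-centre rule.
rings_to_mask <- function(rings, geometry) {
  d <- geometry$dim
  template <- grid_raster(matrix(0, d[1], d[2]), geometry$cell_size_m,
                          geometry$origin)
  cc <- cell_centres(template)
  if (length(rings) == 0) return(matrix(FALSE, d[1], d[2]))
  bnd <- do.call(rbind, lapply(rings, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  inside <- mgcv::in.out(bnd, cbind(as.vector(cc$x), as.vector(cc$y)))
  matrix(inside, d[1], d[2])
}

#' Write an isochrone set as GeoJSON
#'
#' One feature per threshold: a MultiPolygon of dissolved cell rectangles
#' with properties `set_label`, `threshold_min`, `speed_multiplier`.
#'
#' @param iso an `isochrone_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isochrones_geojson <- function(iso, path) {
  feats <- lapply(seq_along(iso$thresholds), function(k) {
    rings <- mask_to_rings(iso$masks[[k]], iso$geometry$cell_size_m,
                           iso$geometry$origin)
    coords <- lapply(rings, function(r) list(apply(r, 1, c, simplify = FALSE)))
    list(type = "Feature",
         properties = list(set_label = iso$label,
                           threshold_min = iso$thresholds[k],
                           speed_multiplier = iso$multiplier),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

# Extract polygon rings from a parsed GeoJSON geometry object.
geojson_rings <- function(geom) {
  ring_mat <- function(rg) do.call(rbind, lapply(rg, function(p)
    c(p[[1]], p[[2]])))
  if (geom$type == "Polygon") {
    lapply(geom$coordinates, ring_mat)
  } else if (geom$type == "MultiPolygon") {
    unlist(lapply(geom$coordinates, function(poly) lapply(poly, ring_mat)),
           recursive = FALSE)
  } else {
    stop_invalid("unsupported geometry type '%s'", geom$type)
  }
}

#' Ingest externally computed isochrones
#'
#' Reads a GeoJSON FeatureCollection of isochrone polygons (e.g. from an
#' external routing service), rasterises each threshold onto the analysis
#' grid by the cell-centre rule, and validates completeness and nesting.
#' Nesting violations are repaired by cumulative union with a warning.
#'
#' @param path GeoJSON file; features must carry `threshold_min` and may
#'   carry `set_label` / `speed_multiplier` properties.
#' @param grid a `grid_raster` (or geometry) to rasterise onto.
#' @param thresholds thresholds that must all be present.
#' @return an `isochrone_set`.
#' @export
ingest_external_isochrones <- function(path, grid,
                                       thresholds = iso_thresholds_default) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- fc$features
  th <- vapply(feats, function(f) as.numeric(f$properties$threshold_min), 0)
  missing <- setdiff(thresholds, th)
  if (length(missing))
    stop_invalid("missing isochrone threshold(s): %s",
                 paste(missing, collapse = ", "))
  geometry <- grid_geometry(grid)
  label <- feats[[1]]$properties$set_label %||% "external"
  mult <- as.numeric(feats[[1]]$properties$speed_multiplier %||% 1)
  masks <- vector("list", length(thresholds))
  names(masks) <- as.character(thresholds)
  for (k in seq_along(thresholds)) {
    idx <- which(th == thresholds[k])
    rings <- unlist(lapply(feats[idx], function(f) geojson_rings(f$geometry)),
                    recursive = FALSE)
    masks[[k]] <- rings_to_mask(rings, geometry)
  }
  repaired <- FALSE
  for (k in seq_along(masks)[-1]) {
    if (any(masks[[k - 1]] & !masks[[k]])) {
      masks[[k]] <- masks[[k]] | masks[[k - 1]]
      repaired <- TRUE
    }
  }
  if (repaired)
    warning("isochrone nesting violated; repaired by cumulative union",
            call. = FALSE)
  structure(list(label = label, multiplier = mult, thresholds = thresholds,
                 masks = masks, geometry = geometry),
            class = "isochrone_set")
}
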