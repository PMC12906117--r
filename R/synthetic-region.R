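# Synthetic-region generator: clustered population raster, settlement codes,
# road network, tiered facility registry and nested administrative regions
# with the statistical structure the accessibility analysis assumes, so the
# whole pipeline is testable without national datasets.
#
# All coordinates live on a flat projected plane in metres (equal-area by
# construction). One integer seed drives every sub-generator through
# deterministic child seeds, so a RegionSpec reproduces bit-identically.

#' Specification of a synthetic region
#'
#' @param extent_m width/height of the region in metres (length-2); must be
#'   divisible by `cell_size_m`.
#' @param cell_size_m raster cell edge in metres (default 1000, the analysis
#'   resolution).
#' @param n_urban_centres number of clustered population centres.
#' @param total_population persons in the region.
#' @param n_facilities_by_tier named counts `c(ct_equipped=, stroke_ready=,
#'   certified=)`; must be nested (certified <= stroke_ready <= ct_equipped).
#' @param road_grid_spacing_m spacing of the local-road lattice.
#' @param seed integer seed driving all sub-generators.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(extent_m = c(250000, 250000),
                        cell_size_m = 1000,
                        n_urban_centres = 8,
                        total_population = 15e6,
                        n_facilities_by_tier = c(ct_equipped = 260,
                                                 stroke_ready = 85,
                                                 certified = 62),
                        road_grid_spacing_m = 5000,
                        seed = 1L) {
  extent_m <- as.numeric(rep(extent_m, length.out = 2))
  if (any(extent_m <= 0)) stop_invalid("extent must be positive")
  if (cell_size_m <= 0) stop_invalid("cell_size_m must be positive")
  if (any(abs(extent_m / cell_size_m - round(extent_m / cell_size_m)) > 1e-9))
    stop_invalid("extent must be divisible by cell_size_m")
  if (n_urban_centres < 0 || total_population < 0)
    stop_invalid("counts must be non-negative")
  t <- n_facilities_by_tier
  need <- c("ct_equipped", "stroke_ready", "certified")
  if (!all(need %in% names(t)))
    stop_invalid("n_facilities_by_tier needs %s", paste(need, collapse = ", "))
  if (any(t < 0)) stop_invalid("tier counts must be non-negative")
  if (!(t["certified"] <= t["stroke_ready"] &&
        t["stroke_ready"] <= t["ct_equipped"]))
    stop_invalid("tier counts must be nested: certified <= stroke_ready <= ct_equipped")
  if (road_grid_spacing_m <= 0) stop_invalid("road_grid_spacing_m must be positive")
  structure(list(extent_m = extent_m, cell_size_m = cell_size_m,
                 n_urban_centres = as.integer(n_urban_centres),
                 total_population = as.numeric(total_population),
                 n_facilities_by_tier = t[need],
                 road_grid_spacing_m = road_grid_spacing_m,
                 seed = as.integer(seed)),
            class = "region_spec")
}

# Urban centre locations/scales/weights shared between the population and
# road generators; deterministic in spec$seed alone.
urban_centres <- function(spec) {
  n <- spec$n_urban_centres
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      sigma_m = numeric(0), weight = numeric(0)))
  with_seed(child_seed(spec$seed, 1), {
    d <- data.frame(
      x = stats::runif(n, 0, spec$extent_m[1]),
      y = stats::runif(n, 0, spec$extent_m[2]),
      sigma_m = stats::runif(n, 0.02, 0.08) * min(spec$extent_m))
    # Zipf-like city-size weights: a few dominant centres, a rural tail
    d$weight <- (seq_len(n))^-1
    d
  })
}

#' Generate a clustered population raster
#'
#' Population density is a mixture of `n_urban_centres` isotropic Gaussian
#' kernels with distinct scales over a low uniform rural floor (15% of the
#' mass), rescaled so the cell sum equals `total_population` exactly.
#'
#' @param spec a `region_spec`.
#' @return a `grid_raster` of persons per cell.
#' @export
generate_population_raster <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  nr <- as.integer(round(spec$extent_m[2] / spec$cell_size_m))
  nc <- as.integer(round(spec$extent_m[1] / spec$cell_size_m))
  zero <- grid_raster(matrix(0, nr, nc), spec$cell_size_m)
  if (spec$total_population == 0) return(zero)
  cc <- cell_centres(zero)
  ctr <- urban_centres(spec)
  if (nrow(ctr) == 0) {
    v <- matrix(spec$total_population / (nr * nc), nr, nc)
    return(grid_raster(v, spec$cell_size_m))
  }
  dens <- matrix(0, nr, nc)
  for (k in seq_len(nrow(ctr))) {
    d2 <- (cc$x - ctr$x[k])^2 + (cc$y - ctr$y[k])^2
    dens <- dens + ctr$weight[k] * exp(-d2 / (2 * ctr$sigma_m[k]^2))
  }
  urban_share <- 0.85
  dens <- urban_share * dens / sum(dens) +
    (1 - urban_share) / (nr * nc)
  v <- dens * (spec$total_population / sum(dens))
  grid_raster(v, spec$cell_size_m)
}

# Settlement-model codes the urbanisation classifier consumes, ordered from
# least to most dense band (code 10 is reserved for water).
settlement_codes <- c(11L, 12L, 13L, 21L, 22L, 23L, 30L)

#' Default settlement density band boundaries (persons per km2)
#'
#' Six strictly increasing thresholds separating the seven settlement codes
#' 11, 12, 13 (rural bands) and 21, 22, 23, 30 (suburban to urban-centre
#' bands); loosely modelled on degree-of-urbanisation density cut-offs.
#' @export
default_settlement_thresholds <- c(5, 50, 150, 300, 600, 1500)

#' Derive a settlement-code raster from population density
#'
#' Assigns each cell one of the codes `{30, 23, 22, 21, 13, 12, 11}` by
#' density band (highest band -> 30, descending to 11) and code 10 to cells
#' under the optional water mask, mirroring the structure of a settlement
#' model grid.
#'
#' @param pop a population `grid_raster`.
#' @param density_thresholds six strictly increasing densities (persons/km2),
#'   one per band boundary.
#' @param water_mask optional logical matrix; `TRUE` cells get code 10.
#' @return a `grid_raster` of integer settlement codes.
#' @export
derive_settlement_raster <- function(pop,
                                     density_thresholds = default_settlement_thresholds,
                                     water_mask = NULL) {
  stopifnot(inherits(pop, "grid_raster"))
  th <- as.numeric(density_thresholds)
  if (length(th) != length(settlement_codes) - 1)
    stop_invalid("need %d density thresholds, got %d",
                 length(settlement_codes) - 1, length(th))
  if (any(diff(th) <= 0)) stop_invalid("thresholds must be strictly increasing")
  dens <- pop$values / (pop$cell_size_m / 1000)^2
  band <- findInterval(dens, th) + 1L          # 1..7
  codes <- matrix(settlement_codes[band], nrow(dens), ncol(dens))
  if (!is.null(water_mask)) {
    if (!identical(dim(water_mask), dim(dens)))
      stop_invalid("water_mask dimensions must match the raster")
    codes[water_mask] <- 10L
  }
  grid_raster(codes, pop$cell_size_m, pop$origin)
}

#' Generate a synthetic road network
#'
#' A lattice of local roads (50 km/h) at `road_grid_spacing_m` with jittered
#' interior node positions, plus high-speed corridors (100 km/h) connecting
#' the urban centres along a minimum spanning tree. The lattice keeps the
#' network connected.
#'
#' @param spec a `region_spec`.
#' @param jitter_frac node position jitter as a fraction of the spacing
#'   (0 disables; corner nodes of the extent are never jittered outside it).
#' @param local_speed_kmh,corridor_speed_kmh speed classes.
#' @return a `road_network`.
#' @export
generate_road_network <- function(spec, jitter_frac = 0.2,
                                  local_speed_kmh = 50,
                                  corridor_speed_kmh = 100) {
  stopifnot(inherits(spec, "region_spec"))
  sp <- spec$road_grid_spacing_m
  if (sp > min(spec$extent_m))
    stop_invalid("road_grid_spacing_m exceeds the extent")
  nx <- as.integer(floor(spec$extent_m[1] / sp)) + 1L
  ny <- as.integer(floor(spec$extent_m[2] / sp)) + 1L
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  with_seed(child_seed(spec$seed, 2), {
    x <- (ij$i - 1) * sp
    y <- (ij$j - 1) * sp
    if (jitter_frac > 0) {
      x <- x + stats::runif(length(x), -jitter_frac, jitter_frac) * sp
      y <- y + stats::runif(length(y), -jitter_frac, jitter_frac) * sp
      x <- pmin(pmax(x, 0), spec$extent_m[1])
      y <- pmin(pmax(y, 0), spec$extent_m[2])
    }
    nodes <- data.frame(id = seq_len(nx * ny), x = x, y = y)
    node_at <- function(i, j) (j - 1L) * nx + i
    horiz <- ij[ij$i < nx, ]
    vert <- ij[ij$j < ny, ]
    e <- rbind(data.frame(from = node_at(horiz$i, horiz$j),
                          to = node_at(horiz$i + 1L, horiz$j)),
               data.frame(from = node_at(vert$i, vert$j),
                          to = node_at(vert$i, vert$j + 1L)))
    len <- sqrt((nodes$x[e$from] - nodes$x[e$to])^2 +
                  (nodes$y[e$from] - nodes$y[e$to])^2)
    edges <- data.frame(from = e$from, to = e$to, length_m = len,
                        speed_kmh = local_speed_kmh)
    ctr <- urban_centres(spec)
    if (nrow(ctr) >= 2) {
      cn <- nearest_nodes(list(nodes = nodes), ctr$x, ctr$y)$node_id
      dmat <- as.matrix(stats::dist(cbind(ctr$x, ctr$y)))
      g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                               weighted = TRUE)
      mst <- igraph::as_edgelist(igraph::mst(g))
      a <- cn[as.integer(mst[, 1])]
      b <- cn[as.integer(mst[, 2])]
      keep <- a != b
      if (any(keep)) {
        len2 <- sqrt((nodes$x[a[keep]] - nodes$x[b[keep]])^2 +
                       (nodes$y[a[keep]] - nodes$y[b[keep]])^2)
        edges <- rbind(edges,
                       data.frame(from = a[keep], to = b[keep],
                                  length_m = len2,
                                  speed_kmh = corridor_speed_kmh))
      }
    }
    road_network(nodes, edges)
  })
}

#' Generate a tiered facility table
#'
#' Facility sites are sampled with probability proportional to cell
#' population (with replacement) and snapped to the nearest network node.
#' Tiers are nested: the `certified` most populous sites are certified
#' stroke units (the top ~35% of them supra-regional, the least populous
#' ~40% of the regional ones telemedicine-supported, thrombectomy centres =
#' the supra-regional units); the next sites up to `stroke_ready` are
#' uncertified high-volume stroke hospitals; the rest are CT-only.
#' Procedure counts are drawn from tier-conditioned ranges so every
#' non-decoy row passes the registry filters (>= 3 CT procedures; certified
#' or stroke-ready rows >= 100 stroke procedures). A configurable fraction
#' of extra sub-threshold decoy rows exercises the filters.
#'
#' @param spec a `region_spec`.
#' @param pop population `grid_raster`.
#' @param network a `road_network`.
#' @param decoy_fraction extra decoy rows as a fraction of the CT-equipped
#'   count; decoys have `ct_procedures` in 0..2 and `stroke_ops` in 0..99.
#' @return data.frame with columns `id, name, x, y, node_id, ct_procedures,
#'   stroke_ops, certified_su, su_class, thrombectomy`.
#' @export
generate_facilities <- function(spec, pop, network, decoy_fraction = 0.15) {
  stopifnot(inherits(spec, "region_spec"), inherits(pop, "grid_raster"),
            inherits(network, "road_network"))
  n_ct <- as.integer(spec$n_facilities_by_tier["ct_equipped"])
  n_ready <- as.integer(spec$n_facilities_by_tier["stroke_ready"])
  n_cert <- as.integer(spec$n_facilities_by_tier["certified"])
  if (n_ct > nrow(network$nodes))
    stop_invalid("more facilities requested (%d) than network nodes (%d)",
                 n_ct, nrow(network$nodes))
  n_decoy <- as.integer(round(decoy_fraction * n_ct))
  with_seed(child_seed(spec$seed, 3), {
    cc <- cell_centres(pop)
    w <- as.vector(pop$values)
    prob <- if (sum(w) > 0) w else NULL
    pick <- sample.int(length(w), n_ct + n_decoy, replace = TRUE, prob = prob)
    # most populous sampled sites get the specialised tiers
    ord <- order(w[pick[seq_len(n_ct)]], decreasing = TRUE)
    pick[seq_len(n_ct)] <- pick[seq_len(n_ct)][ord]
    snap <- nearest_nodes(network, as.vector(cc$x)[pick], as.vector(cc$y)[pick])
    n_tot <- n_ct + n_decoy
    certified <- c(rep(TRUE, n_cert), rep(FALSE, n_tot - n_cert))
    su_class <- rep("none", n_tot)
    if (n_cert > 0) {
      n_supra <- ceiling(0.35 * n_cert)
      su_class[seq_len(n_supra)] <- "supraregional"
      if (n_cert > n_supra) {
        reg <- (n_supra + 1):n_cert
        su_class[reg] <- "regional"
        n_tele <- floor(0.4 * length(reg))
        if (n_tele > 0)  # least populous regional units run on telemedicine
          su_class[rev(reg)[seq_len(n_tele)]] <- "telemedicine_regional"
      }
    }
    thrombectomy <- su_class == "supraregional"
    ct_proc <- integer(n_tot)
    stroke_ops <- integer(n_tot)
    i_cert <- which(certified)
    i_ready <- setdiff(seq_len(n_ready), i_cert)
    i_ctonly <- setdiff(seq_len(n_ct), c(i_cert, i_ready))
    i_decoy <- if (n_decoy > 0) (n_ct + 1):n_tot else integer(0)
    ct_proc[i_cert] <- 3L + stats::rpois(length(i_cert), 2000)
    ct_proc[i_ready] <- 3L + stats::rpois(length(i_ready), 1200)
    ct_proc[i_ctonly] <- 3L + stats::rpois(length(i_ctonly), 400)
    ct_proc[i_decoy] <- sample(0:2, length(i_decoy), replace = TRUE)
    stroke_ops[i_cert] <- 100L + stats::rpois(length(i_cert), 400)
    stroke_ops[i_ready] <- 100L + stats::rpois(length(i_ready), 150)
    stroke_ops[i_ctonly] <- sample(0:99, length(i_ctonly), replace = TRUE)
    stroke_ops[i_decoy] <- sample(0:99, length(i_decoy), replace = TRUE)
    data.frame(id = seq_len(n_tot),
               name = sprintf("Hospital %03d", seq_len(n_tot)),
               x = network$nodes$x[snap$node_index],
               y = network$nodes$y[snap$node_index],
               node_id = snap$node_id,
               ct_procedures = ct_proc,
               stroke_ops = stroke_ops,
               certified_su = certified,
               su_class = su_class,
               thrombectomy = thrombectomy)
  })
}

#' Generate nested administrative regions
#'
#' States are a Voronoi partition of seeded points clipped to the extent;
#' counties a nested Voronoi partition within each state. Membership is by
#' cell centre, so counties partition their state and states partition the
#' extent exactly.
#'
#' @param spec a `region_spec`.
#' @param n_states number of states (>= 1).
#' @param counties_per_state counties within each state (>= 1).
#' @return object of class `admin_regions`: `$regions` (id, name, level,
#'   parent), `$state_raster` and `$county_raster` (`grid_raster`s of region
#'   ids per cell), `$seeds`.
#' @export
generate_admin_regions <- function(spec, n_states = 4, counties_per_state = 3) {
  stopifnot(inherits(spec, "region_spec"))
  if (n_states < 1 || counties_per_state < 1)
    stop_invalid("n_states and counties_per_state must be >= 1")
  nr <- as.integer(round(spec$extent_m[2] / spec$cell_size_m))
  nc <- as.integer(round(spec$extent_m[1] / spec$cell_size_m))
  base <- grid_raster(matrix(0, nr, nc), spec$cell_size_m)
  cc <- cell_centres(base)
  with_seed(child_seed(spec$seed, 4), {
    sx <- stats::runif(n_states, 0, spec$extent_m[1])
    sy <- stats::runif(n_states, 0, spec$extent_m[2])
    d2 <- outer(as.vector(cc$x), sx, "-")^2 + outer(as.vector(cc$y), sy, "-")^2
    state_of <- max.col(-d2, ties.method = "first")
    regions <- data.frame(id = seq_len(n_states),
                          name = sprintf("State %02d", seq_len(n_states)),
                          level = "state", parent = NA_integer_)
    county_of <- integer(length(state_of))
    next_id <- n_states
    seeds <- data.frame(id = regions$id, x = sx, y = sy)
    for (s in seq_len(n_states)) {
      cells <- which(state_of == s)
      k <- min(counties_per_state, length(cells))
      if (k == 0) next
      cs <- cells[sample.int(length(cells), k)]
      ids <- next_id + seq_len(k)
      next_id <- next_id + k
      regions <- rbind(regions,
                       data.frame(id = ids,
                                  name = sprintf("State %02d County %02d", s,
                                                 seq_len(k)),
                                  level = "county", parent = s))
      seeds <- rbind(seeds, data.frame(id = ids,
                                       x = as.vector(cc$x)[cs],
                                       y = as.vector(cc$y)[cs]))
      dd <- outer(as.vector(cc$x)[cells], as.vector(cc$x)[cs], "-")^2 +
        outer(as.vector(cc$y)[cells], as.vector(cc$y)[cs], "-")^2
      county_of[cells] <- ids[max.col(-dd, ties.method = "first")]
    }
    structure(list(regions = regions,
                   state_raster = grid_raster(matrix(state_of, nr, nc),
                                              spec$cell_size_m),
                   county_raster = grid_raster(matrix(county_of, nr, nc),
                                               spec$cell_size_m),
                   seeds = seeds),
              class = "admin_regions")
  })
}

#' Generate a complete synthetic region
#'
#' Convenience wrapper running every sub-generator off one `region_spec`.
#'
#' @param spec a `region_spec`.
#' @param n_states,counties_per_state administrative partition sizes.
#' @param decoy_fraction passed to [generate_facilities()].
#' @param ... passed to [generate_road_network()].
#' @return object of class `synthetic_region` with elements `spec`,
#'   `population`, `settlement`, `network`, `facilities`, `regions`.
#' @export
generate_region <- function(spec, n_states = 4, counties_per_state = 3,
                            decoy_fraction = 0.15, ...) {
  pop <- generate_population_raster(spec)
  net <- generate_road_network(spec, ...)
  structure(list(spec = spec,
                 population = pop,
                 settlement = derive_settlement_raster(pop),
                 network = net,
                 facilities = generate_facilities(spec, pop, net,
                                                  decoy_fraction = decoy_fraction),
                 regions = generate_admin_regions(spec, n_states,
                                                  counties_per_state)),
            class = "synthetic_region")
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf("<synthetic_region> %g x %g km, %d facilities, pop %.4g\n",
              x$spec$extent_m[1] / 1000, x$spec$extent_m[2] / 1000,
              nrow(x$facilities), raster_total(x$population)))
  invisible(x)
}

#' Read/write the facility CSV dialect
#'
#' @param facilities facility data.frame.
#' @param path file path.
#' @return the data.frame (read) or `path` invisibly (write).
#' @export
write_facilities_csv <- function(facilities, path) {
  utils::write.csv(facilities, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_facilities_csv
#' @export
read_facilities_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
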