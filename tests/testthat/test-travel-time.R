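# A 10-km west-east line road at 60 km/h with nodes every km, and a 1 x 11
# grid whose cell centres coincide with the nodes (zero access legs).
line_fixture <- function(speed = 60) {
  net <- line_network(10000, 1000, speed_kmh = speed)
  grid <- grid_raster(matrix(0, 1, 11), 1000, origin = c(-500, -500))
  list(net = net, grid = grid)
}

test_that("travel times are length/speed arithmetic plus the access leg", {
  fx <- line_fixture(speed = 50)
  f <- compute_travel_time_field(fx$net, sources = 1, grid = fx$grid)
  # node 11 sits 10 km down a 50 km/h road: 12 min
  expect_equal(unname(f$node_times["11"]), 60 * 10 / 50)
  expect_equal(unname(f$node_times["1"]), 0)       # a source's own node
  expect_equal(f$values[1, 1], 0)                  # zero access distance
  expect_equal(f$values[1, 11], 12)

  # off-grid cell centres add a straight-line access leg at 30 km/h
  shifted <- grid_raster(matrix(0, 1, 11), 1000, origin = c(0, -500))
  g <- compute_travel_time_field(fx$net, 1, shifted)
  expect_equal(g$values[1, 1], (0.5 / 30) * 60)    # 500 m leg = 1 min

  expect_error(compute_travel_time_field(fx$net, integer(0), fx$grid),
               "empty source")
  far <- data.frame(x = 5000, y = 9000)            # 9 km off the road
  expect_warning(compute_travel_time_field(fx$net, far, fx$grid),
                 "snapped")
})

test_that("multi-source field is the cell-wise minimum of single sources", {
  net <- random_network(120, 20000, seed = 5)
  grid <- grid_raster(matrix(0, 20, 20), 1000)
  f12 <- compute_travel_time_field(net, c(7, 80), grid)
  f1 <- compute_travel_time_field(net, 7, grid)
  f2 <- compute_travel_time_field(net, 80, grid)
  expect_equal(f12$values, pmin(f1$values, f2$values), tolerance = 1e-12)
})

test_that("speed multipliers are exact algebra on the baseline field", {
  net <- random_network(100, 15000, seed = 8)
  grid <- grid_raster(matrix(0, 15, 15), 1000)
  base <- compute_travel_time_field(net, c(3, 50), grid)
  expect_equal(apply_speed_multiplier(base, 1), base)
  fast <- apply_speed_multiplier(base, 1.2)
  expect_equal(fast$values, base$values / 1.2)
  expect_equal(fast$multiplier, 1.2)
  # rescaling equals recomputation from scratch at the scaled speed
  recomputed <- compute_travel_time_field(net, c(3, 50), grid,
                                          multiplier = 1.2)
  expect_equal(fast$values, recomputed$values, tolerance = 1e-9)
  expect_error(apply_speed_multiplier(base, 0), "> 0")

  # isochrone scaling law: slower driving at threshold t = baseline at 0.8 t
  slow <- apply_speed_multiplier(base, 0.8)
  iso_slow <- isochrone_polygons(slow, thresholds = c(10, 20, 30))
  iso_base <- isochrone_polygons(base, thresholds = 0.8 * c(10, 20, 30))
  for (k in 1:3)
    expect_identical(iso_slow$masks[[k]], iso_base$masks[[k]])
})

test_that("isochrones are nested unions of closed cells", {
  vals <- matrix(Inf, 3, 3)
  vals[2, 2] <- 4.9
  f <- structure(list(values = vals, cell_size_m = 1000, origin = c(0, 0),
                      label = "single", multiplier = 1),
                 class = c("travel_time_field", "grid_raster"))
  iso <- isochrone_polygons(f)
  expect_equal(iso$thresholds, seq(5, 60, 5))
  expect_equal(sum(iso$masks[["5"]]), 1)
  expect_true(iso$masks[["5"]][2, 2])
  expect_identical(iso$masks[["10"]], iso$masks[["5"]])
  for (k in seq_along(iso$masks)[-1])
    expect_true(all(iso$masks[[k - 1]] <= iso$masks[[k]]))  # nesting

  f$values[] <- Inf
  expect_warning(empty <- isochrone_polygons(f), "no reachable")
  expect_true(all(!unlist(empty$masks)))
})

test_that("field reflection symmetry holds through the extent centre", {
  ext <- 12000
  net <- random_network(60, ext, seed = 21)
  refl <- road_network(data.frame(id = net$nodes$id,
                                  x = ext - net$nodes$x,
                                  y = ext - net$nodes$y),
                       net$edges)
  grid <- grid_raster(matrix(0, 12, 12), 1000)
  f <- compute_travel_time_field(net, c(4, 33), grid)
  g <- compute_travel_time_field(refl, c(4, 33), grid)
  expect_equal(g$values, f$values[12:1, 12:1], tolerance = 1e-9)
})

test_that("isochrone GeoJSON round-trips to identical cell coverage", {
  d <- demo_region()
  fac <- d$registry$facilities[d$registry$facilities$id %in%
                                 d$registry$sets$certified, ]
  f <- compute_travel_time_field(d$region$network, fac, d$region$population,
                                 label = "certified")
  iso <- isochrone_polygons(f)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_isochrones_geojson(iso, p)
  back <- ingest_external_isochrones(p, d$region$population)
  expect_equal(back$label, "certified")
  expect_equal(back$multiplier, 1)
  for (t in names(iso$masks))
    expect_identical(back$masks[[t]], iso$masks[[t]])
})

test_that("external isochrones are validated and nesting is repaired", {
  geom <- grid_raster(matrix(0, 4, 4), 1000)
  rect <- function(x0, y0, x1, y1)
    list(list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))))
  feat <- function(t, coords)
    list(type = "Feature",
         properties = list(set_label = "ext", threshold_min = t,
                           speed_multiplier = 1),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  p <- withr::local_tempfile(fileext = ".geojson")

  # only 11 thresholds -> error naming the gap
  feats <- lapply(seq(5, 55, 5), function(t) feat(t, rect(0, 0, 2000, 2000)))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       p, auto_unbox = TRUE, digits = 10)
  expect_error(ingest_external_isochrones(p, geom), "60")

  # polygon(10) not inside polygon(15) -> cumulative-union repair + warning
  feats <- lapply(seq(5, 60, 5), function(t) {
    if (t == 10) feat(t, rect(0, 0, 4000, 4000))
    else feat(t, rect(0, 0, 2000, 2000))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       p, auto_unbox = TRUE, digits = 10)
  expect_warning(fixed <- ingest_external_isochrones(p, geom), "repaired")
  expect_true(all(fixed$masks[["10"]] <= fixed$masks[["15"]]))
  expect_equal(sum(fixed$masks[["15"]]), 16)
})
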