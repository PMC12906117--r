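small_spec <- function(...) {
  base <- list(extent_m = c(20000, 20000), cell_size_m = 1000,
               n_urban_centres = 2, total_population = 1e5,
               n_facilities_by_tier = c(ct_equipped = 5, stroke_ready = 3,
                                        certified = 2),
               road_grid_spacing_m = 5000, seed = 11)
  do.call(region_spec, utils::modifyList(base, list(...)))
}

test_that("region specs validate their invariants", {
  expect_s3_class(small_spec(), "region_spec")
  expect_error(region_spec(extent_m = c(0, 1000)), "positive")
  expect_error(small_spec(cell_size_m = 300), "divisible")
  expect_error(small_spec(n_facilities_by_tier = c(ct_equipped = 2,
                                                   stroke_ready = 3,
                                                   certified = 1)),
               "nested")
  expect_error(small_spec(road_grid_spacing_m = 50000) |>
                 generate_road_network(), "exceeds")
})

test_that("population raster conserves totals and handles edge cases", {
  pop <- generate_population_raster(small_spec())
  expect_equal(raster_total(pop), 1e5, tolerance = 1e-6)
  expect_true(all(pop$values >= 0))

  zero <- generate_population_raster(small_spec(total_population = 0))
  expect_true(all(zero$values == 0))

  flat <- generate_population_raster(small_spec(n_urban_centres = 0))
  expect_equal(unique(as.vector(flat$values)), 1e5 / 400)

  # clustered generator concentrates mass: top decile of cells holds more
  # than a uniform share
  top <- sort(as.vector(pop$values), decreasing = TRUE)[1:40]
  expect_gt(sum(top), 0.2 * 1e5)
})

test_that("generators are bit-reproducible for a fixed seed", {
  s <- small_spec()
  expect_identical(generate_population_raster(s),
                   generate_population_raster(s))
  expect_identical(generate_road_network(s), generate_road_network(s))
  pop <- generate_population_raster(s)
  net <- generate_road_network(s)
  expect_identical(generate_facilities(s, pop, net),
                   generate_facilities(s, pop, net))
  expect_identical(generate_admin_regions(s, 3, 2),
                   generate_admin_regions(s, 3, 2))
})

test_that("settlement codes follow the density bands", {
  s <- small_spec(n_urban_centres = 0)             # uniform 250 persons/km2
  pop <- generate_population_raster(s)
  st <- derive_settlement_raster(pop)              # 250 sits in band 21
  expect_true(all(st$values == 21))
  st2 <- derive_settlement_raster(pop, density_thresholds = c(300, 400, 500,
                                                              600, 700, 800))
  expect_true(all(st2$values == 11))               # below every threshold

  pop$values[3, 4] <- 2000 * (pop$cell_size_m / 1000)^2  # above top band
  st3 <- derive_settlement_raster(pop)
  expect_equal(st3$values[3, 4], 30)

  # urban fraction equals a direct count of cells above the urban boundary
  dens <- pop$values / (pop$cell_size_m / 1000)^2
  th <- default_settlement_thresholds
  expect_equal(mean(st3$values %in% c(30, 23, 22, 21)),
               mean(dens >= th[3]))

  expect_error(derive_settlement_raster(pop, density_thresholds = c(1, 2)),
               "thresholds")
  wm <- matrix(FALSE, nrow(pop$values), ncol(pop$values)); wm[1, 1] <- TRUE
  expect_equal(derive_settlement_raster(pop, water_mask = wm)$values[1, 1], 10)
})

test_that("road lattice has the expected combinatorics and speed classes", {
  s <- small_spec(road_grid_spacing_m = 10000, n_urban_centres = 0)
  net <- generate_road_network(s, jitter_frac = 0)
  expect_equal(nrow(net$nodes), 9)                 # 3 x 3 lattice
  expect_equal(nrow(net$edges), 12)
  expect_true(all(net$edges$length_m == 10000))
  expect_equal(max(net$nodes$component), 1)

  with_corridors <- generate_road_network(small_spec())
  expect_setequal(unique(with_corridors$edges$speed_kmh), c(50, 100))
  expect_equal(max(with_corridors$nodes$component), 1)
})

test_that("facility generator respects tier nesting and decoy contract", {
  s <- small_spec()
  pop <- generate_population_raster(s)
  net <- generate_road_network(s)
  fac <- generate_facilities(s, pop, net, decoy_fraction = 0)
  expect_equal(nrow(fac), 5)
  expect_equal(sum(fac$certified_su), 2)
  expect_equal(sum(fac$stroke_ops >= 100 | fac$certified_su), 3)
  expect_true(all(fac$ct_procedures >= 3))          # decoy 0: all pass filter
  expect_true(all(fac$su_class[fac$certified_su] != "none"))
  expect_true(all(!fac$certified_su | fac$stroke_ops >= 100))

  with_decoys <- generate_facilities(s, pop, net, decoy_fraction = 0.4)
  expect_equal(nrow(with_decoys), 7)
  expect_true(all(with_decoys$ct_procedures[6:7] < 3))

  expect_error(generate_facilities(small_spec(road_grid_spacing_m = 10000,
                                              n_facilities_by_tier =
                                                c(ct_equipped = 50,
                                                  stroke_ready = 3,
                                                  certified = 2)),
                                   pop,
                                   generate_road_network(
                                     small_spec(road_grid_spacing_m = 10000),
                                     jitter_frac = 0)),
               "more facilities")
})

test_that("facilities snap to the node nearest the populated cell", {
  s <- small_spec()
  net <- generate_road_network(s, jitter_frac = 0)
  pop <- generate_population_raster(s)
  pop$values[] <- 0
  pop$values[7, 13] <- 1e5                          # all mass in one cell
  fac <- generate_facilities(s, pop, net, decoy_fraction = 0)
  cx <- pop$origin[1] + 12.5 * pop$cell_size_m
  cy <- pop$origin[2] + 6.5 * pop$cell_size_m
  d <- sqrt((net$nodes$x - cx)^2 + (net$nodes$y - cy)^2)
  best <- net$nodes$id[which.min(d)]                # exhaustive comparison
  expect_true(all(fac$node_id == best))
})

test_that("admin regions partition the extent exactly", {
  s <- small_spec()
  one <- generate_admin_regions(s, 1, 1)
  expect_true(all(one$state_raster$values == 1))
  expect_true(all(one$county_raster$values == 2))

  reg <- generate_admin_regions(s, 3, 2)
  counties <- reg$regions[reg$regions$level == "county", ]
  # every cell centre in exactly one state and one county
  expect_true(all(reg$state_raster$values %in%
                    reg$regions$id[reg$regions$level == "state"]))
  expect_true(all(reg$county_raster$values %in% counties$id))
  # county cells agree with their parent state, so county areas sum to the
  # state area exactly
  for (s_id in unique(reg$state_raster$values)) {
    kids <- counties$id[counties$parent == s_id]
    expect_equal(sum(reg$county_raster$values %in% kids),
                 sum(reg$state_raster$values == s_id))
  }
  expect_error(generate_admin_regions(s, 0, 1), ">= 1")
})
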