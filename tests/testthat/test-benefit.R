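test_that("benefit classification matches its clinical definition", {
  lab <- function(code) benefit_categories[code + 1L]
  expect_equal(lab(classify_benefit(15, 40, penalty_min = 10)), "low")
  expect_equal(lab(classify_benefit(20, 25)), "irrelevant")
  expect_equal(lab(classify_benefit(30, 70)), "only_ct_reachable")
  expect_equal(lab(classify_benefit(65, 70)), "neither_reachable")
  expect_equal(lab(classify_benefit(10, 40)), "high")       # saving == 30
  expect_equal(lab(classify_benefit(10, 30)), "medium")     # saving == 20
  expect_equal(lab(classify_benefit(10, 20)), "low")        # saving == 10
  expect_equal(lab(classify_benefit(10, 19.9)), "irrelevant")
  # "within 60 min" is inclusive: a facility at exactly 60.0 is reachable
  expect_equal(lab(classify_benefit(10, 60)), "high")
  expect_equal(lab(classify_benefit(60, 60.0001)), "only_ct_reachable")
  expect_equal(lab(classify_benefit(Inf, Inf)), "neither_reachable")
  expect_error(classify_benefit(-1, 10), "non-negative")
})

test_that("delay penalties shift savings but not reachability by default", {
  lab <- function(code) benefit_categories[code + 1L]
  # CT at 55 min, stroke unit out of reach: stays only-CT under a +10
  # penalty (the table convention) ...
  expect_equal(lab(classify_benefit(55, 70, penalty_min = 10)),
               "only_ct_reachable")
  # ... but becomes unreachable under the strict toggle
  expect_equal(lab(classify_benefit(55, 70, penalty_min = 10,
                                    penalty_affects_reachability = TRUE)),
               "neither_reachable")
  # penalised classification equals the zero-penalty rule on shifted CT
  # times when the penalty enters reachability too
  set.seed(4)
  t_ct <- runif(200, 0, 90)
  t_tg <- t_ct + runif(200, 0, 50)
  for (p in c(10, 20, 30))
    expect_identical(
      classify_benefit(t_ct, t_tg, penalty_min = p,
                       penalty_affects_reachability = TRUE),
      classify_benefit(t_ct + p, t_tg))
})

test_that("benefit grids partition cells and match a per-cell oracle", {
  net <- random_network(90, 40000, seed = 13)
  grid <- grid_raster(matrix(0, 40, 40), 1000)
  f_ct <- compute_travel_time_field(net, c(2, 9, 40, 71), grid,
                                    label = "ct_equipped")
  f_tg <- compute_travel_time_field(net, 2, grid, label = "certified")
  sc <- scenario_spec(1, 10)
  g <- build_benefit_grid(f_ct, f_tg, sc)
  expect_true(all(g$categories %in% 0:5))
  oracle <- matrix(NA_character_, 40, 40)
  for (i in 1:40) for (j in 1:40)
    oracle[i, j] <- oracle_classify(f_ct$values[i, j], f_tg$values[i, j],
                                    penalty = 10)
  expect_identical(matrix(benefit_categories[g$categories + 1L], 40, 40),
                   oracle)

  # identical fields at zero penalty: every reachable cell is irrelevant
  same <- build_benefit_grid(f_ct, f_ct, scenario_spec(1, 0))
  reachable <- f_ct$values <= 60
  expect_true(all(same$categories[reachable] == 2))

  expect_error(build_benefit_grid(f_ct, f_tg, scenario_spec(1.2, 0)),
               "inconsistent")
  small <- compute_travel_time_field(net, 2, grid_raster(matrix(0, 5, 5),
                                                         1000))
  expect_error(build_benefit_grid(f_ct, small, sc), "frames")
})

test_that("benefit tables conserve population and report shares", {
  d <- demo_region()
  fx <- compute_travel_time_field(d$region$network,
                                  registry_set_facilities(d$registry,
                                                      "ct_equipped"),
                                  d$region$population, label = "ct_equipped")
  ft <- compute_travel_time_field(d$region$network,
                                  registry_set_facilities(d$registry,
                                                      "certified"),
                                  d$region$population, label = "certified")
  g <- build_benefit_grid(fx, ft, scenario_spec(1, 0))
  tab <- benefit_population_table(g, d$region$population)
  main <- tab[!tab$derived, ]
  expect_equal(sum(main$population), raster_total(d$region$population))
  expect_equal(tab$population[tab$category == "beneficiaries_10plus"],
               sum(main$population[main$category %in%
                                     c("low", "medium", "high")]))
  expect_equal(tab$pct, pct_round(tab$population, tab$denominator))

  # uniform population: category share equals its cell share
  uni <- grid_raster(matrix(10, nrow(g$categories), ncol(g$categories)),
                     g$geometry$cell_size_m)
  tu <- benefit_population_table(g, uni)
  irr <- mean(g$categories == 2)
  expect_equal(tu$pct[tu$category == "irrelevant"],
               round_half_up(100 * irr, 1))
})

test_that("the six-scenario suite obeys penalty and target monotonicity", {
  d <- demo_region()
  suite <- scenario_suite(d$registry, d$region$network, d$region$population)
  expect_named(suite$tables, c("normal", "speed_up20", "speed_down20",
                               "penalty_10", "penalty_20", "penalty_30"))
  ben <- function(s, id)
    s$tables[[id]]$population[s$tables[[id]]$category ==
                                "beneficiaries_10plus"]
  # beneficiaries shrink as the in-hospital penalty grows
  bp <- vapply(c("normal", "penalty_10", "penalty_20", "penalty_30"),
               function(id) ben(suite, id), 0)
  expect_true(all(diff(bp) <= 0))
  # only-CT and neither rows are penalty-invariant (table convention)
  for (cat in c("only_ct_reachable", "neither_reachable")) {
    v <- vapply(c("normal", "penalty_10", "penalty_30"), function(id)
      suite$tables[[id]]$population[suite$tables[[id]]$category == cat], 0)
    expect_true(all(v == v[1]))
  }
  # a larger comparison set can only shrink the saving
  suite_sr <- scenario_suite(d$registry, d$region$network,
                             d$region$population, target = "stroke_ready")
  expect_lte(ben(suite_sr, "normal"), ben(suite, "normal"))
  g_c <- suite$grids$normal
  g_s <- suite_sr$grids$normal
  expect_true(all(g_s$t_target <= g_c$t_target + 1e-9))
})
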