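test_that("scenario constructor enforces disjoint food sets and rates", {
  expect_error(snap_scenario("x", incentivized = "fruits",
                             restricted = "fruits"), "at most one")
  expect_error(snap_scenario("x", incentivized = "pizza"), "unknown food")
  expect_error(snap_scenario("x", incentive_rate = 1.2), "rates")
  sc <- default_scenarios()
  expect_named(sc, c("fv_incentive", "fv_ssb_restriction", "snap_plus"))
  expect_equal(sc$snap_plus$incentive_rate, 0.30)
  expect_equal(sc$snap_plus$disincentive_rate, 0.30)
})

test_that("price-instrument composition follows the multiplicative form", {
  # direct product oracle
  comp <- list(price_response = 0.26, snap_venue_share = 0.9,
               snap_dollar_share = 0.9, spend_shift = 0.1)
  expect_equal(overall_change_incentive(comp), 0.26 * 0.9 * 0.9 * 0.9)
  expect_equal(overall_change_incentive(comp), 0.18954)

  comp$price_response <- 0
  expect_equal(overall_change_incentive(comp), 0)

  comp$snap_dollar_share <- 1.4
  expect_error(overall_change_incentive(comp), "\\[0, 1\\]")

  # monotone in the price response, bounded by it
  effects <- load_effect_components()
  base <- effects[effects$scenario == "fv_incentive" &
                    effects$food == "vegetables", ]
  prs <- seq(0.05, 0.6, by = 0.05)
  vals <- vapply(prs, function(pr) {
    r <- base; r$price_response <- pr; overall_change_incentive(r)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(abs(vals) <= prs))
})

test_that("restriction effect is the unshifted SNAP retail share", {
  expect_equal(overall_change_restriction(0.664, 0.5), -0.332)
  expect_equal(overall_change_restriction(0.7, 1), 0)
  expect_equal(overall_change_restriction(0.8, 0.25), -0.6)
  expect_error(overall_change_restriction(1.2, 0.5), "\\[0, 1\\]")
  expect_error(overall_change_restriction(0.5, -0.1), "\\[0, 1\\]")
})

test_that("shipped components reproduce the published intake changes", {
  effects <- load_effect_components()
  scn <- default_scenarios()
  base <- default_diet_means()

  fv <- intake_changes(scn$fv_incentive, effects)
  expect_equal(fv$pct_change[fv$food == "vegetables"], 0.19)
  expect_equal(round(fv$abs_change[fv$food == "vegetables"], 1), 25.6)
  # fruits: the published overall effect is 23.4%, printed change 19.1 g/d;
  # 0.234 * 81.3 = 19.02, a printed-rounding discrepancy kept as-is
  expect_equal(fv$pct_change[fv$food == "fruits"], 0.234)
  expect_equal(fv$abs_change[fv$food == "fruits"], 19.0242,
               tolerance = 1e-6)
  expect_lt(abs(fv$abs_change[fv$food == "fruits"] - 19.1), 0.1)

  # SSB restriction: -33.2% overall; published g/d change is -139 while
  # -0.332 * 414 = -137.4 (second recorded discrepancy)
  rs <- intake_changes(scn$fv_ssb_restriction, effects)
  expect_equal(rs$pct_change[rs$food == "ssb"], -0.332)
  expect_equal(rs$abs_change[rs$food == "ssb"], -137.448)

  # every other published change reproduced within 0.1 g/d
  published <- c(fruits = 19.1, vegetables = 28.8, nuts = 1.7,
                 whole_grains = 3.4, fish = 3.9, plant_oils = 3.8,
                 ssb = -52, processed_meat = -5.1, junk_food = -11.5)
  sp <- intake_changes(scn$snap_plus, effects)
  for (f in setdiff(names(published), "fruits"))
    expect_lt(abs(sp$abs_change[sp$food == f] - published[[f]]), 0.1,
              label = f)
  # incentive effect range: nuts (31.5%) is the published outlier above
  # the stated 19.0-24.2% incentive band; the others fall inside it up to
  # the 0.1 g/d rounding of the printed changes the composites are
  # back-solved from (whole grains: 3.4/13.9 = 24.5%)
  inc <- sp[sp$instrument == "incentive" & sp$food != "nuts", ]
  expect_true(all(inc$pct_change >= 0.185 & inc$pct_change <= 0.246))
  expect_equal(round(sp$pct_change[sp$food == "nuts"], 3), 0.315)
  # disincentive band -13.3% to -17.4%
  dis <- sp[sp$instrument == "disincentive", ]
  expect_true(all(dis$pct_change <= -0.125 & dis$pct_change >= -0.174))
})

test_that("applying a scenario shifts diets multiplicatively and safely", {
  pop <- tiny_pop(50, seed = 9)
  effects <- load_effect_components()
  scn <- default_scenarios()

  empty <- snap_scenario("null")
  out <- apply_scenario(pop, empty, effects)
  expect_equal(out$population, pop)
  expect_equal(nrow(out$changes), 0)

  out <- apply_scenario(pop, scn$snap_plus, effects)
  expect_equal(out$population$vegetables,
               pop$vegetables * (1 + 28.8 / 134.8))
  expect_equal(out$population$ssb, pop$ssb * (1 - 52 / 414))
  expect_equal(out$population$fish, pop$fish * (1 + 3.9 / 20.6))
  untouched <- setdiff(names(pop), food_categories())
  expect_equal(out$population[untouched], pop[untouched])
  expect_true(all(as.matrix(out$population[, food_categories()]) >= 0))

  # missing component row names the food
  bad <- snap_scenario("fv_incentive", incentivized = "fish")
  expect_error(apply_scenario(pop, bad, effects), "fish")
})

test_that("changes as fractions of dietary recommendations", {
  # whole grains: 3.4 g/d against 3 oz/d = 85.05 g/d
  expect_equal(round(100 * dga_fraction(3.4, 3, "oz_day"), 1), 4.0)
  # vegetables: 28.8 g/d against 2.5 cups/d = 250 g/d
  expect_equal(round(100 * dga_fraction(28.8, 2.5, "cup_day"), 1), 11.5)
  # fruits: 19.1 g/d against 2 cups/d
  expect_equal(round(100 * dga_fraction(19.1, 2, "cup_day"), 1), 9.6)
  # fish: 3.9 g/d against 8 oz/wk
  expect_equal(round(100 * dga_fraction(3.9, 8, "oz_week"), 1), 12.0)
  expect_equal(dga_fraction(0, 5, "oz_week"), 0)
  expect_error(dga_fraction(1, 2, "pints"), "unknown unit")
  expect_error(dga_fraction(1, 0, "cup_day"), "> 0")
})
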