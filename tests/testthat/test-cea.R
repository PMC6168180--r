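test_that("discounting follows the 3% annual convention", {
  expect_equal(discounted(100, 0), 100)
  expect_equal(round(discounted(100, 2), 2), 94.26)
  expect_equal(discounted(250, 7, rate = 0), 250)
  expect_error(discounted(100, -1), ">= 0")
})

test_that("food program costs compose rates, spends, scopes, discounting", {
  inputs <- manual_cost_inputs(
    spend = data.frame(food = "fruits", spend_adult = 100,
                       spend_child = 0),
    adults = 1, all_participants = 1)
  sc <- snap_scenario("fv_incentive", incentivized = "fruits")
  # one food, $100/person-yr, 30% incentive, 1 adult, 1 year, no discount
  expect_equal(food_program_cost(sc, inputs, "adults_35plus", years = 1),
               30)
  # restriction produces no program savings
  rs <- snap_scenario("r", incentivized = "fruits", restricted = "ssb")
  inputs2 <- manual_cost_inputs(adults = 1, all_participants = 1)
  expect_equal(food_program_cost(rs, inputs2, "adults_35plus", 1),
               food_program_cost(snap_scenario("i", incentivized = "fruits"),
                                 inputs2, "adults_35plus", 1))
  # disincentives are revenue
  ds <- snap_scenario("d", disincentivized = "ssb")
  expect_lt(food_program_cost(ds, inputs2, "all_participants", 5), 0)
  expect_error(food_program_cost(sc, inputs, "teens", 1), "unknown scope")

  # shipped defaults: the 5-year F&V subsidy for all participants sits on
  # the published $11.54B scale, and SNAP-plus is net revenue
  real <- cost_inputs()
  scn <- default_scenarios()
  fv5 <- food_program_cost(scn$fv_incentive, real, "all_participants", 5)
  expect_equal(fv5 / 1e9, 11.54, tolerance = 1e-3)
  expect_equal(food_program_cost(scn$fv_incentive, real, "adults_35plus",
                                 5) / 1e9, 5.04, tolerance = 1e-3)
  sp5 <- food_program_cost(scn$snap_plus, real, "all_participants", 5)
  expect_equal(sp5 / 1e9, -4.93, tolerance = 1e-3)
  # the restriction scenario's subsidy equals the F&V-only subsidy
  expect_equal(food_program_cost(scn$fv_ssb_restriction, real,
                                 "all_participants", 5), fv5)
})

test_that("net cost honors the accounting perspective", {
  comp <- list(admin = 2, hc_savings = 5, food_adults = 10, food_all = 20)
  expect_equal(net_cost("societal", comp), -3)
  expect_equal(net_cost("govt_adults", comp), 7)
  expect_equal(net_cost("govt_all", comp), 17)
  expect_equal(net_cost("snap_budget", comp), 22)
  expect_equal(net_cost("societal",
                        list(admin = 0, hc_savings = 0, food_all = 0)), 0)
  expect_error(net_cost("societal", list(admin = 1)), "missing component")
  expect_error(net_cost("galactic", comp), "unknown perspective")

  # ordering under positive subsidies
  expect_true(net_cost("societal", comp) <= net_cost("govt_adults", comp))
  expect_true(net_cost("govt_adults", comp) <= net_cost("govt_all", comp))
})

test_that("ICERs classify exactly at the willingness-to-pay thresholds", {
  expect_equal(icer(10e9, 1e5)$icer, 100000)
  expect_equal(icer(10e9, 1e5)$status, "cost_effective")
  expect_equal(icer(-1, 1)$status, "cost_saving")
  expect_true(is.na(icer(-1, 1)$icer))
  expect_equal(icer(1, -1)$status, "dominated")
  expect_equal(icer(50000, 1)$status, "very_cost_effective")
  expect_equal(icer(50001, 1)$status, "cost_effective")
  expect_equal(icer(150000, 1)$status, "cost_effective")
  expect_equal(icer(150001, 1)$status, "not_cost_effective")
  expect_error(icer(1, 0), "non-zero")
})

test_that("published component identities are reproduced from benchmarks", {
  bm <- load_benchmarks()
  row <- function(sc, h) bm[bm$scenario == sc & bm$horizon == h, ]

  # F&V lifetime societal: admin minus healthcare savings
  fvl <- row("fv_incentive", "lifetime")
  soc <- net_cost("societal", list(admin = fvl$admin_m * 1e6,
                                   hc_savings = fvl$hc_savings_b * 1e9))
  expect_equal(soc / 1e9, 0.212 - 6.77)
  # printed as Saving ($6.69B); component rounding leaves ~2% slack
  expect_lt(abs(-soc / 1e9 - 6.69) / 6.69, 0.02)

  # government-affordability ICER for F&V over a lifetime
  nc <- net_cost("govt_all", list(admin = fvl$admin_m * 1e6,
                                  hc_savings = fvl$hc_savings_b * 1e9,
                                  food_all = fvl$subsidy_all_b * 1e9))
  ic <- icer(nc, fvl$qalys)
  expect_lt(abs(ic$icer - 66525) / 66525, 0.01)
  expect_equal(ic$status, "cost_effective")
})

test_that("cea_from_components assembles one row per perspective", {
  comp <- list(admin = 1e8, hc_savings = 2e9, food_adults = 5e9,
               food_all = 1e10, qalys_gained = 5e4)
  tab <- cea_from_components(comp)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$status[tab$perspective == "societal"], "cost_saving")
  expect_equal(tab$net_cost[tab$perspective == "govt_all"],
               1e8 - 2e9 + 1e10)
  expect_equal(tab$icer[tab$perspective == "govt_adults"],
               (1e8 - 2e9 + 5e9) / 5e4)
})
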