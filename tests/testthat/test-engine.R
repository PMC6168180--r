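test_that("ten-year probabilities annualize under a constant hazard", {
  expect_equal(ten_year_to_annual(0), 0)
  expect_equal(round(ten_year_to_annual(0.1), 6), 0.010481)
  expect_equal(round(ten_year_to_annual(0.5), 6), 0.066967)
  p <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(ten_year_to_annual(p)) > 0))
  expect_true(all(ten_year_to_annual(p) <= p))
  expect_error(ten_year_to_annual(1), "\\[0, 1\\)")
})

test_that("the risk score reproduces the published function and is monotone", {
  # frozen value computed directly from the published coefficients
  expect_equal(framingham_cvd_risk(55, "male", 130, 200, 45, TRUE, FALSE),
               0.2205991467, tolerance = 1e-9)
  expect_equal(framingham_cvd_risk(55, "female", 130, 200, 45, TRUE,
                                   FALSE),
               0.1096564434, tolerance = 1e-9)

  base <- list(age = 55, sex = "male", sbp = 120, total_chol = 200,
               hdl = 45, smoker = FALSE, diabetic = FALSE)
  risk <- function(mods) {
    a <- utils::modifyList(base, mods)
    framingham_cvd_risk(a$age, a$sex, a$sbp, a$total_chol, a$hdl,
                        a$smoker, a$diabetic)
  }
  expect_gt(risk(list(sbp = 160)), risk(list()))
  expect_gt(risk(list(age = 65)), risk(list()))
  expect_gt(risk(list(total_chol = 260)), risk(list()))
  expect_gt(risk(list(smoker = TRUE)), risk(list()))
  expect_gt(risk(list(diabetic = TRUE)), risk(list()))
  expect_lt(risk(list(hdl = 70)), risk(list()))
  expect_error(framingham_cvd_risk(NA, "male", 120, 200, 45, FALSE,
                                   FALSE), "missing risk factor")
})

test_that("annual risk scales linearly in the modifier and calibration", {
  pop <- homog_pop(1)
  p0 <- annual_cvd_risk(pop, engine_params(calibration_multiplier = 1))
  expect_equal(p0, ten_year_to_annual(
    framingham_cvd_risk(50, "male", 130, 200, 45, FALSE, FALSE)))
  expect_equal(annual_cvd_risk(pop, engine_params(calibration_multiplier = 1),
                               rr_modifier = 0.9), 0.9 * p0)
  expect_equal(annual_cvd_risk(pop, engine_params(calibration_multiplier = 1.3)),
               1.3 * p0)
})

test_that("a single cycle handles degenerate hazards exactly", {
  n <- 4
  pop <- homog_pop(n)
  params <- const_hazard_params(p_event = 0, q_other = 0)
  ps <- list(state = rep(1L, n), age = pop$age, sex = pop$sex,
             sbp = pop$sbp, total_chol = pop$total_chol, hdl = pop$hdl,
             bmi = pop$bmi, smoker = pop$smoker, diabetic = pop$diabetic)
  u <- matrix(0.5, n, 5)
  step <- advance_year(ps, identity_modifiers(n), params, u, t = 1)
  expect_equal(step$ps$state, rep(1L, n))
  expect_equal(step$inc$qaly, rep(params$utilities[["WELL"]], n))
  expect_equal(step$inc$py, rep(1, n))

  # forced fatal MI: event certain, all events MI, case fatality 1
  params2 <- engine_params(fixed_annual_cvd_prob = 1,
                           event_split = c(mi = 1, angina = 0, rca = 0,
                                           stroke = 0),
                           case_fatality = c(mi = 1, angina = 0, rca = 0,
                                             stroke = 0),
                           cf_age_slope = 0, diabetes_base = 0,
                           mort_a = c(male = 0, female = 0), mort_b = 0)
  step2 <- advance_year(ps, identity_modifiers(n), params2, u, t = 1)
  expect_equal(step2$ps$state, rep(health_states()[["DEAD_CVD"]], n))
  expect_true(all(step2$inc$fatal_cvd))
  expect_equal(step2$inc$qaly, rep(0, n))

  ps$state[1] <- 99L
  expect_error(advance_year(ps, identity_modifiers(n), params, u, 1),
               "invalid health state")
})

test_that("trajectories are deterministic and conserve the cohort", {
  pop <- tiny_pop(300, seed = 6)
  s1 <- simulate_cohort(pop, NULL, 10, seed = 4, trace = TRUE)
  s2 <- simulate_cohort(pop, NULL, 10, seed = 4, trace = TRUE)
  expect_identical(s1$totals, s2$totals)
  expect_identical(s1$per_person, s2$per_person)
  # every cycle, persons across the nine states sum to the cohort size
  expect_equal(unname(rowSums(s1$state_trace)), rep(300, 10))
  # dead states are absorbing
  dead <- s1$state_trace[, "DEAD_CVD"] + s1$state_trace[, "DEAD_OTHER"]
  expect_true(all(diff(dead) >= 0))
})

test_that("discounting makes QALYs strictly less than life-years", {
  pop <- tiny_pop(200, seed = 8)
  s <- simulate_cohort(pop, NULL, 20, seed = 2, expansion = 1)
  expect_lt(s$totals$qalys, s$totals$person_years)
  expect_true(all(s$per_person$qaly <= s$per_person$py + 1e-12))
})

test_that("microsimulation matches the Markov chain for constant hazards", {
  n <- 20000
  years <- 20
  params <- const_hazard_params(p_event = 0.02, q_other = 0.01,
                                recurrent = 1.5)
  pop <- homog_pop(n, age = 50)
  sim <- simulate_cohort(pop, NULL, 20, params, seed = 12, expansion = 1)
  oracle <- markov_expectation(params, years)

  ev_pp <- sim$per_person$events
  se_ev <- stats::sd(ev_pp) / sqrt(n)
  expect_lt(abs(mean(ev_pp) - oracle$events), 3 * se_ev)

  q_pp <- sim$per_person$qaly
  se_q <- stats::sd(q_pp) / sqrt(n)
  expect_lt(abs(mean(q_pp) - oracle$qalys), 3 * se_q)
})

test_that("a protective modifier averts events at every horizon", {
  pop <- tiny_pop(5000, seed = 13)
  mods <- identity_modifiers(nrow(pop))
  mods$rr_chd <- rep(0.9, nrow(pop))
  mods$rr_stroke <- rep(0.9, nrow(pop))
  base <- simulate_cohort(pop, NULL, "lifetime", seed = 5,
                          snapshot_years = c(5, 10, 20))
  scn <- simulate_cohort(pop, mods, "lifetime", seed = 5,
                         snapshot_years = c(5, 10, 20))
  for (h in list(5, 10, 20, "lifetime")) {
    inc <- incremental_outcomes(base, scn, h)
    expect_gte(inc$cvd_events_averted, 0)
    expect_gte(inc$qalys_gained, 0)
  }
})

test_that("stratified outcomes partition the aggregate exactly", {
  pop <- tiny_pop(2000, seed = 14)
  mods <- identity_modifiers(nrow(pop))
  mods$rr_chd <- rep(0.85, nrow(pop))
  base <- simulate_cohort(pop, NULL, 10, seed = 3)
  scn <- simulate_cohort(pop, mods, 10, seed = 3)
  inc <- incremental_outcomes(base, scn)
  for (by in c("sex", "age_band", "race_ethnicity")) {
    st <- stratified_outcomes(base, scn, pop, by)
    expect_equal(sum(st$cvd_events_averted), inc$cvd_events_averted)
    expect_equal(sum(st$qalys_gained), inc$qalys_gained)
  }
})

test_that("invalid engine inputs are rejected", {
  expect_error(engine_params(event_split = c(mi = 0.5, angina = 0.2,
                                             rca = 0.1, stroke = 0.1)),
               "sum to 1")
  expect_error(engine_params(utilities = c(WELL = 1.2)), "\\[0,1\\]")
  pop <- tiny_pop(10, seed = 1)
  expect_error(simulate_cohort(pop, NULL, 7), "horizon")
  expect_error(simulate_cohort(pop[0, ], NULL, 5), "empty")
})
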