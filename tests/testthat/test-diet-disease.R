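test_that("log-linear dose-response with age attenuation", {
  entry <- data.frame(food = "vegetables", outcome = "chd",
                      rr_per_unit = 0.95, unit_size = 100, ref_age = 50,
                      age_attenuation = 0, pathway = "direct")
  # closed-form oracle at the reference age
  expect_equal(rr_for_change(entry, 25.6, 50), exp(log(0.95) * 0.256))
  expect_equal(round(rr_for_change(entry, 25.6, 50), 5), 0.98695)
  expect_equal(rr_for_change(entry, 0, 63), 1)

  # attenuation that halves the log-RR by 75 gives the square root
  entry$age_attenuation <- 0.2      # 1 - 0.2 * 25/10 = 0.5 at age 75
  rr_ref <- rr_for_change(entry, 100, 50)
  expect_equal(rr_for_change(entry, 100, 75), sqrt(rr_ref))
  # and floors at no effect: by age 100 the factor is 0
  expect_equal(rr_for_change(entry, 100, 100), 1)

  # |log RR| non-increasing in age for a fixed change
  ages <- seq(35, 90, by = 5)
  lnrr <- abs(log(rr_for_change(entry, 50, ages, clamp = c(0, Inf))))
  expect_true(all(diff(lnrr) <= 1e-12))

  # clamp guards against extreme deltas
  expect_equal(rr_for_change(entry, -1e5, 50), 2)
  entry$rr_per_unit <- -1
  expect_error(rr_for_change(entry, 1, 50), "> 0")
})

test_that("junk-food composite multiplies the retained joint associations", {
  rr_table <- data.frame(
    food = c("a", "b"), outcome = "chd",
    rr_per_unit = c(0.98, 1.01), unit_size = c(1, 1),
    ref_age = 50, age_attenuation = 0, pathway = "direct",
    stringsAsFactors = FALSE)
  profile <- data.frame(component = c("a", "b"),
                        delta_per_100g = c(1, 1),
                        stringsAsFactors = FALSE)
  # induced component changes of exactly one unit each: product oracle
  expect_equal(junk_food_rr(profile, 100, rr_table, 50), 0.98 * 1.01)
  expect_equal(junk_food_rr(profile, 100, rr_table, 50), 0.9898)
  # zero change in every component
  expect_equal(junk_food_rr(profile, 0, rr_table, 50), 1)
  # unknown component is an error
  profile2 <- rbind(profile, data.frame(component = "c",
                                        delta_per_100g = 1))
  expect_error(junk_food_rr(profile2, 1, rr_table, 50),
               "no relative-risk entries")

  # shipped defaults: reducing junk food is net protective for CHD but
  # contains both protective and harmful factors
  shipped <- load_junk_profile()
  rr <- load_rr_table()
  expect_lt(junk_food_rr(shipped, -11.5, rr, 50, "chd"), 1)
  signs <- vapply(seq_len(nrow(shipped)), function(i) {
    one <- shipped[i, , drop = FALSE]
    if (one$component == "sodium") return(NA_real_)
    junk_food_rr(one, -11.5, rr, 50, "chd")
  }, numeric(1))
  signs <- signs[!is.na(signs) & signs != 1]
  expect_true(any(signs < 1) && any(signs > 1))
})

test_that("person modifiers compose direct, mediated, and junk pathways", {
  pop <- tiny_pop(200, seed = 21)
  effects <- load_effect_components()
  scn <- default_scenarios()

  # no diet change: exact identity
  none <- person_modifiers(pop, NULL)
  expect_equal(none$rr_chd, rep(1, 200))
  expect_equal(none$rr_diabetes, rep(1, 200))
  expect_equal(none$d_sbp, rep(0, 200))

  # F&V-only scenario has no F&V-diabetes etiologic entry: diabetes
  # untouched, no mediated shifts
  fv <- person_modifiers(pop, intake_changes(scn$fv_incentive, effects))
  expect_equal(fv$rr_diabetes, rep(1, 200))
  expect_equal(fv$d_bmi, rep(0, 200))
  expect_equal(fv$d_sbp, rep(0, 200))
  expect_true(all(fv$rr_chd < 1) && all(fv$rr_stroke < 1))

  # log-additivity: modifiers of two separate changes multiply
  ch <- intake_changes(scn$fv_incentive, effects)
  m_both <- person_modifiers(pop, ch)
  m_f <- person_modifiers(pop, ch[ch$food == "fruits", ])
  m_v <- person_modifiers(pop, ch[ch$food == "vegetables", ])
  expect_equal(m_both$rr_chd, m_f$rr_chd * m_v$rr_chd, tolerance = 1e-12)
  expect_equal(m_both$rr_stroke, m_f$rr_stroke * m_v$rr_stroke,
               tolerance = 1e-12)
})

test_that("SSB changes shift BMI by the person's stratum slope", {
  med <- load_mediated_spec()
  pop <- homog_pop(1, age = 50)
  pop$bmi <- 32                       # obese, under 65
  change <- data.frame(food = "ssb", instrument = "restriction",
                       pct_change = -139 / pop$ssb,
                       abs_change = -139, stringsAsFactors = FALSE)
  mod <- person_modifiers(pop, change, mediated = med)
  slope <- med$ssb_bmi$slope[med$ssb_bmi$age_group == "35-64" &
                               med$ssb_bmi$bmi_group == "ge30"]
  expect_equal(mod$d_bmi, slope * (-139) / med$ssb_serving_g)
  # direct + BMI-mediated SSB terms are both protective here
  expect_lt(mod$rr_diabetes, 1)
  expect_lt(mod$rr_chd, 1)
})

test_that("junk-food sodium acts on blood pressure by stratum", {
  pop <- homog_pop(2, age = 55)
  pop$race_ethnicity <- c("nh_black", "nh_white")
  pop$sbp <- c(150, 120)              # hypertensive vs not
  pop$junk_food <- 66.5
  change <- data.frame(food = "junk_food", instrument = "disincentive",
                       pct_change = -11.5 / 66.5, abs_change = -11.5,
                       stringsAsFactors = FALSE)
  med <- load_mediated_spec()
  mod <- person_modifiers(pop, change, mediated = med)
  prof <- load_junk_profile()
  d_sodium <- prof$delta_per_100g[prof$component == "sodium"] *
    (-11.5) / 100
  slopes <- c(3.0 + 0.1 * 0.5, 1.0 + 0.1 * 0.5)  # age 55 gradient
  expect_equal(mod$d_sbp, slopes * d_sodium)
  expect_lt(mod$d_sbp[1], mod$d_sbp[2])  # larger drop where salt-sensitive
})
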