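# Shared fixtures: all built in code at test time.

tiny_pop <- function(n, seed = 1L) {
  generate_population(population_config(n, seed = seed))
}

# Homogeneous CVD-free cohort for constant-hazard validation runs.
homog_pop <- function(n, age = 50, sex = "male") {
  pop <- data.frame(
    id = seq_len(n), weight = 1, age = age, sex = sex,
    race_ethnicity = "nh_white", education = "high_school",
    income_poverty_ratio = "lt_1.30", insurance = "other",
    sbp = 130, total_chol = 200, hdl = 45, bmi = 28,
    smoker = FALSE, diabetic = FALSE, stringsAsFactors = FALSE)
  for (f in food_categories()) pop[[f]] <- default_diet_means()[[f]]
  class(pop) <- c("snap_population", "data.frame")
  pop
}

# Engine parameters that make a homogeneous cohort an exact constant-hazard
# Markov chain: fixed event probability, flat non-CVD mortality, no secular
# trends, no age gradients, no diabetes.
const_hazard_params <- function(p_event = 0.02, q_other = 0.01,
                                recurrent = 1.5) {
  engine_params(fixed_annual_cvd_prob = p_event,
                recurrent_multiplier = recurrent,
                cf_age_slope = 0,
                diabetes_base = 0,
                mort_a = c(male = q_other, female = q_other), mort_b = 0,
                trends = c(sbp = 0, total_chol = 0, bmi = 0),
                utility_age_decrement = 0)
}

# Minimal cost inputs built directly (unit tests of the cost arithmetic).
manual_cost_inputs <- function(spend = NULL, admin = NULL,
                               adults = 10, all_participants = 20,
                               discount_rate = 0.03) {
  if (is.null(spend))
    spend <- data.frame(food = food_categories(),
                        spend_adult = 100, spend_child = 100,
                        stringsAsFactors = FALSE)
  if (is.null(admin))
    admin <- data.frame(scenario = c("fv_incentive", "fv_ssb_restriction",
                                     "snap_plus"),
                        startup_millions = 1, annual_millions = 1,
                        stringsAsFactors = FALSE)
  structure(list(admin = admin, food_spend = spend, adults = adults,
                 all_participants = all_participants,
                 discount_rate = discount_rate, cpi_base = 2017),
            class = "snap_cost_inputs")
}

# Independent Markov-chain expectation for a homogeneous constant-hazard
# cohort: transition-matrix loop over the 9 states, computing expected
# cumulative events per person and expected discounted QALYs per person.
markov_expectation <- function(params, years) {
  p_well <- params$fixed_annual_cvd_prob
  p_cvd <- min(1, p_well * params$recurrent_multiplier)
  q <- params$mort_a[["male"]]
  es <- params$event_split[c("mi", "angina", "rca", "stroke")]
  cf <- pmin(params$cf_cap, params$case_fatality[c("mi", "angina", "rca",
                                                   "stroke")])
  acute_of_type <- c(2L, 4L, 5L, 6L)
  m <- matrix(0, 9, 9)
  resolve <- c(1L, 3L, 3L, 4L, 5L, 7L, 7L, 8L, 9L)
  for (s in 1:7) {
    pe <- if (s == 1) p_well else p_cvd
    m[s, 9] <- q
    for (k in 1:4) {
      m[s, acute_of_type[k]] <- m[s, acute_of_type[k]] +
        (1 - q) * pe * es[[k]] * (1 - cf[[k]])
      m[s, 8] <- m[s, 8] + (1 - q) * pe * es[[k]] * cf[[k]]
    }
    m[s, resolve[s]] <- m[s, resolve[s]] + (1 - q) * (1 - pe)
  }
  m[8, 8] <- 1; m[9, 9] <- 1
  u <- params$utilities[names(health_states())]
  pi_t <- c(1, rep(0, 8))
  ev <- 0; qaly <- 0
  for (t in seq_len(years)) {
    pe_vec <- c(p_well, rep(p_cvd, 6), 0, 0)
    ev <- ev + sum(pi_t[1:7] * (1 - q) * pe_vec[1:7])
    pi_t <- as.numeric(pi_t %*% m)
    qaly <- qaly + sum(pi_t * u) / (1 + params$discount_rate)^(t - 1)
  }
  list(events = ev, qalys = qaly)
}
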