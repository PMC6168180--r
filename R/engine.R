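#' Health-state codes used by the simulation engine
#'
#' Integer codes for the mutually exclusive health states. Acute states
#' (acute MI, acute stroke) last exactly one annual cycle before resolving
#' to their chronic counterparts; the two death states are absorbing.
#' Diabetes is an orthogonal absorbing flag, not a state.
#'
#' @return Named integer vector.
#' @export
health_states <- function() {
  c(WELL = 1L, ACUTE_MI = 2L, POST_MI = 3L, ANGINA = 4L,
    RCA_SURVIVOR = 5L, ACUTE_STROKE = 6L, POST_STROKE = 7L,
    DEAD_CVD = 8L, DEAD_OTHER = 9L)
}

#' Convert a 10-year event probability to an annual probability
#'
#' Assumes a constant hazard over the decade:
#' \code{p1 = 1 - (1 - p10)^(1/10)}. Monotone, and always \code{<= p10}.
#'
#' @param p10 10-year probability in [0, 1).
#' @return Annual probability.
#' @export
ten_year_to_annual <- function(p10) {
  if (any(p10 < 0 | p10 >= 1)) stop("p10 must lie in [0, 1)")
  1 - (1 - p10)^(1 / 10)
}

# Published general-CVD risk function coefficients (sex-specific Cox model
# on log-transformed risk factors; untreated blood pressure).
framingham_coefs <- list(
  male = list(age = 3.06117, tc = 1.12370, hdl = -0.93263, sbp = 1.93303,
              smoker = 0.65451, diabetic = 0.57367,
              s0 = 0.88936, mean_lp = 23.9802),
  female = list(age = 2.32888, tc = 1.20904, hdl = -0.70833, sbp = 2.76157,
                smoker = 0.52873, diabetic = 0.69154,
                s0 = 0.95012, mean_lp = 26.1931)
)

#' 10-year general cardiovascular disease risk
#'
#' The published sex-specific general-CVD risk score on log age, log total
#' cholesterol, log HDL cholesterol, log (untreated) systolic blood
#' pressure, current smoking, and diabetes status.
#'
#' @param age Years.
#' @param sex \code{"male"}/\code{"female"} character vector.
#' @param sbp Systolic blood pressure, mmHg.
#' @param total_chol Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param smoker,diabetic Logical.
#' @return 10-year event probability in [0, 1).
#' @export
framingham_cvd_risk <- function(age, sex, sbp, total_chol, hdl,
                                smoker, diabetic) {
  args <- list(age, sbp, total_chol, hdl, smoker, diabetic)
  if (any(vapply(args, anyNA, logical(1))) || anyNA(sex))
    stop("missing risk factor")
  male <- sex == "male"
  lp <- numeric(length(age))
  s0 <- numeric(length(age))
  for (s in c("male", "female")) {
    i <- if (s == "male") male else !male
    if (!any(i)) next
    cf <- framingham_coefs[[s]]
    lp[i] <- cf$age * log(age[i]) + cf$tc * log(total_chol[i]) +
      cf$hdl * log(hdl[i]) + cf$sbp * log(sbp[i]) +
      cf$smoker * smoker[i] + cf$diabetic * diabetic[i] - cf$mean_lp
    s0[i] <- cf$s0
  }
  p <- 1 - s0^exp(lp)
  pmin(pmax(p, 0), 1 - 1e-12)
}

#' Engine parameters
#'
#' All transition, trend, utility, and healthcare-cost parameters of the
#' annual-cycle state-transition engine. Every default not printed in the
#' source evaluation (event-type split, case fatality, diabetes incidence,
#' non-CVD mortality, utilities, state costs) is a calibration input and
#' can be overridden. \code{fixed_annual_cvd_prob} replaces the risk score
#' with a constant annual event probability; together with zeroed age/BMI
#' coefficients it makes a homogeneous cohort an exact constant-hazard
#' Markov chain, which is used for engine validation.
#'
#' @param calibration_multiplier Scalar on the annualized risk-score
#'   probability, calibrating event counts to empirical trends.
#' @param event_split Proportions of CVD events that are MI, angina,
#'   resuscitated cardiac arrest (RCA), and stroke; must sum to 1.
#' @param case_fatality Baseline case fatality by event type.
#' @param cf_age_slope Relative increase in case fatality per decade of age
#'   above 60.
#' @param cf_cap Upper bound on case fatality.
#' @param recurrent_multiplier Annual event-risk multiplier for persons
#'   with established CVD.
#' @param diabetes_base Annual diabetes incidence at age 50 and BMI 30.
#' @param diabetes_age_coef,diabetes_bmi_coef Log-linear incidence
#'   gradients per year of age and per BMI unit.
#' @param diabetes_cap Upper bound on annual diabetes incidence.
#' @param mort_a,mort_b Gompertz non-CVD mortality \code{q = a exp(b age)}
#'   (named \code{a} by sex); probability forced to 1 at age >= 100.
#' @param trends Annual secular drift added to SBP, total cholesterol, and
#'   BMI.
#' @param utilities QALY weight by health state (dead states 0).
#' @param utility_age_decrement Utility loss per year of age above 35.
#' @param utility_diabetes_mult Multiplier on utility while diabetic.
#' @param event_costs First-year healthcare cost by event type (2017 USD).
#' @param chronic_costs Annual healthcare cost by chronic state.
#' @param diabetes_annual_cost Annual add-on cost while diabetic.
#' @param cvd_death_cost Cost booked in the year of a fatal CVD event.
#' @param discount_rate Annual discount rate for QALYs and costs.
#' @param fixed_annual_cvd_prob Optional constant annual CVD probability
#'   (diagnostic override; \code{NULL} uses the risk score).
#' @return List of class \code{snap_engine_params}.
#' @export
engine_params <- function(calibration_multiplier = 1.3,
                          event_split = c(mi = 0.35, angina = 0.25,
                                          rca = 0.05, stroke = 0.35),
                          case_fatality = c(mi = 0.25, angina = 0.0,
                                            rca = 0.60, stroke = 0.18),
                          cf_age_slope = 0.5,
                          cf_cap = 0.9,
                          recurrent_multiplier = 2.0,
                          diabetes_base = 0.008,
                          diabetes_age_coef = 0.02,
                          diabetes_bmi_coef = 0.08,
                          diabetes_cap = 0.05,
                          mort_a = c(male = 4.5e-5, female = 2.7e-5),
                          mort_b = 0.09,
                          trends = c(sbp = 0.10, total_chol = 0.0,
                                     bmi = 0.05),
                          utilities = c(WELL = 1.0, ACUTE_MI = 0.76,
                                        POST_MI = 0.88, ANGINA = 0.85,
                                        RCA_SURVIVOR = 0.85,
                                        ACUTE_STROKE = 0.70,
                                        POST_STROKE = 0.78,
                                        DEAD_CVD = 0, DEAD_OTHER = 0),
                          utility_age_decrement = 0.0015,
                          utility_diabetes_mult = 0.97,
                          event_costs = c(mi = 52000, angina = 21000,
                                          rca = 62000, stroke = 38000),
                          chronic_costs = c(WELL = 0, ACUTE_MI = 0,
                                            POST_MI = 3100, ANGINA = 3600,
                                            RCA_SURVIVOR = 3200,
                                            ACUTE_STROKE = 0,
                                            POST_STROKE = 10500,
                                            DEAD_CVD = 0, DEAD_OTHER = 0),
                          diabetes_annual_cost = 9600,
                          cvd_death_cost = 14000,
                          discount_rate = 0.03,
                          fixed_annual_cvd_prob = NULL) {
  if (abs(sum(event_split) - 1) > 1e-9) stop("event_split must sum to 1")
  if (any(event_split < 0)) stop("event_split must be non-negative")
  if (any(utilities < 0 | utilities > 1)) stop("utilities must lie in [0,1]")
  if (any(case_fatality < 0 | case_fatality > 1))
    stop("case_fatality must lie in [0,1]")
  if (!is.null(fixed_annual_cvd_prob) &&
      (fixed_annual_cvd_prob < 0 || fixed_annual_cvd_prob > 1))
    stop("fixed_annual_cvd_prob must lie in [0,1]")
  p <- list(calibration_multiplier = calibration_multiplier,
            event_split = event_split, case_fatality = case_fatality,
            cf_age_slope = cf_age_slope, cf_cap = cf_cap,
            recurrent_multiplier = recurrent_multiplier,
            diabetes_base = diabetes_base,
            diabetes_age_coef = diabetes_age_coef,
            diabetes_bmi_coef = diabetes_bmi_coef,
            diabetes_cap = diabetes_cap,
            mort_a = mort_a, mort_b = mort_b, trends = trends,
            utilities = utilities,
            utility_age_decrement = utility_age_decrement,
            utility_diabetes_mult = utility_diabetes_mult,
            event_costs = event_costs, chronic_costs = chronic_costs,
            diabetes_annual_cost = diabetes_annual_cost,
            cvd_death_cost = cvd_death_cost,
            discount_rate = discount_rate,
            fixed_annual_cvd_prob = fixed_annual_cvd_prob)
  class(p) <- "snap_engine_params"
  p
}

#' Annual CVD event probability for each person
#'
#' Annualizes the 10-year risk-score probability, applies the trend
#' calibration multiplier and an optional scenario relative-risk modifier,
#' and clamps to [0, 1]. Strictly increasing in age, SBP, total
#' cholesterol, smoking, and diabetes, and decreasing in HDL.
#'
#' @param population Data frame with risk-factor columns.
#' @param params \code{\link{engine_params}}.
#' @param rr_modifier Scalar or per-person multiplier (default 1).
#' @return Annual event probability per person.
#' @export
annual_cvd_risk <- function(population, params = engine_params(),
                            rr_modifier = 1) {
  p10 <- framingham_cvd_risk(population$age, population$sex,
                             population$sbp, population$total_chol,
                             population$hdl, population$smoker,
                             population$diabetic)
  p <- ten_year_to_annual(p10) * params$calibration_multiplier * rr_modifier
  pmin(pmax(p, 0), 1)
}

other_cause_mortality <- function(age, sex, params) {
  a <- ifelse(sex == "male", params$mort_a[["male"]],
              params$mort_a[["female"]])
  q <- pmin(0.99, a * exp(params$mort_b * age))
  q[age >= 100] <- 1
  q
}

diabetes_incidence <- function(age, bmi, params) {
  pmin(params$diabetes_cap,
       params$diabetes_base *
         exp(params$diabetes_age_coef * (age - 50)) *
         exp(params$diabetes_bmi_coef * (bmi - 30)))
}

#' Advance the cohort by one annual cycle
#'
#' One cycle of the state-transition model, with competing risks resolved
#' by sequential conditional draws: (1) non-CVD death, (2) a CVD event
#' (typed by the event split, fatal per the case-fatality parameters),
#' (3) diabetes onset for event-free survivors; at most one event per
#' cycle. Acute states resolve to their chronic counterparts, risk factors
#' receive their secular drift and age advances one year, and discounted
#' QALY and healthcare-cost increments are accrued on the end-of-cycle
#' state.
#'
#' @param ps Cohort state list: \code{state} (integer codes from
#'   \code{\link{health_states}}), \code{age}, \code{sex}, \code{sbp},
#'   \code{total_chol}, \code{hdl}, \code{bmi}, \code{smoker},
#'   \code{diabetic}.
#' @param modifiers A \code{snap_modifiers} object (or
#'   \code{\link{identity_modifiers}}).
#' @param params \code{\link{engine_params}}.
#' @param u n x 5 matrix of uniforms (death, event, type, fatality,
#'   diabetes draws).
#' @param t Cycle index (1-based), used for discounting.
#' @return List with the updated \code{ps} and an \code{inc} list of
#'   per-person increments (\code{qaly}, \code{cost}, \code{event},
#'   \code{event_type}, \code{fatal_cvd}, \code{died_other},
#'   \code{diab_onset}, \code{py}).
#' @export
advance_year <- function(ps, modifiers, params, u, t) {
  if (any(ps$state < 1L | ps$state > 9L)) stop("invalid health state")
  n <- length(ps$state)
  states <- health_states()
  alive0 <- ps$state < states[["DEAD_CVD"]]

  q_other <- other_cause_mortality(ps$age, ps$sex, params)
  die_other <- alive0 & (u[, 1] < q_other)
  at_risk <- alive0 & !die_other

  if (!is.null(params$fixed_annual_cvd_prob)) {
    p_base <- rep(params$fixed_annual_cvd_prob, n)
  } else {
    pop_now <- list(age = ps$age, sex = ps$sex,
                    sbp = ps$sbp + modifiers$d_sbp,
                    total_chol = ps$total_chol, hdl = ps$hdl,
                    smoker = ps$smoker, diabetic = ps$diabetic)
    p_base <- annual_cvd_risk(pop_now, params)
  }
  has_cvd <- ps$state >= states[["ACUTE_MI"]] &
    ps$state <= states[["POST_STROKE"]]
  p_base[has_cvd] <- p_base[has_cvd] * params$recurrent_multiplier

  es <- params$event_split
  chd_w <- es[["mi"]] + es[["angina"]] + es[["rca"]]
  st_w <- es[["stroke"]]
  p_event <- pmin(1, p_base * (chd_w * modifiers$rr_chd +
                                 st_w * modifiers$rr_stroke))
  event <- at_risk & (u[, 2] < p_event)

  # conditional event type: CHD types weighted by the CHD modifier,
  # stroke by the stroke modifier
  d <- chd_w * modifiers$rr_chd + st_w * modifiers$rr_stroke
  c1 <- es[["mi"]] * modifiers$rr_chd / d
  c2 <- c1 + es[["angina"]] * modifiers$rr_chd / d
  c3 <- c2 + es[["rca"]] * modifiers$rr_chd / d
  type <- 1L + (u[, 3] > c1) + (u[, 3] > c2) + (u[, 3] > c3)
  type[!event] <- 0L

  cf_base <- params$case_fatality[c("mi", "angina", "rca", "stroke")]
  cf <- pmin(params$cf_cap,
             cf_base[pmax(type, 1L)] *
               (1 + params$cf_age_slope * pmax(0, ps$age - 60) / 10))
  fatal <- event & (u[, 4] < cf)

  p_diab <- diabetes_incidence(ps$age, ps$bmi, params) *
    modifiers$rr_diabetes
  diab_onset <- at_risk & !event & !ps$diabetic & (u[, 5] < pmin(1, p_diab))

  new_state <- ps$state
  new_state[ps$state == states[["ACUTE_MI"]]] <- states[["POST_MI"]]
  new_state[ps$state == states[["ACUTE_STROKE"]]] <- states[["POST_STROKE"]]
  acute_of_type <- c(states[["ACUTE_MI"]], states[["ANGINA"]],
                     states[["RCA_SURVIVOR"]], states[["ACUTE_STROKE"]])
  new_state[event] <- acute_of_type[type[event]]
  new_state[fatal] <- states[["DEAD_CVD"]]
  new_state[die_other] <- states[["DEAD_OTHER"]]

  diabetic <- ps$diabetic | diab_onset
  age_new <- ps$age + 1
  alive_end <- new_state < states[["DEAD_CVD"]]

  df <- (1 + params$discount_rate)^(-(t - 1))
  util <- params$utilities[names(states)][new_state] *
    pmax(0, 1 - params$utility_age_decrement * (age_new - 35))
  util[diabetic & alive_end] <- util[diabetic & alive_end] *
    params$utility_diabetes_mult
  util[!alive_end] <- 0
  qaly <- unname(util * df)

  cost <- numeric(n)
  nonfatal <- event & !fatal
  cost[nonfatal] <- params$event_costs[c("mi", "angina", "rca",
                                         "stroke")][type[nonfatal]]
  cost[fatal] <- params$cvd_death_cost
  chronic <- alive_end & !event
  cost[chronic] <- params$chronic_costs[names(states)][new_state[chronic]]
  cost[diabetic & alive_end] <- cost[diabetic & alive_end] +
    params$diabetes_annual_cost
  cost <- unname(cost * df)

  ps$state <- new_state
  ps$diabetic <- diabetic
  ps$age <- age_new
  ps$sbp <- ps$sbp + params$trends[["sbp"]]
  ps$total_chol <- ps$total_chol + params$trends[["total_chol"]]
  ps$bmi <- ps$bmi + params$trends[["bmi"]]

  list(ps = ps,
       inc = list(qaly = qaly, cost = cost, event = as.integer(event),
                  event_type = type, fatal_cvd = fatal,
                  died_other = die_other, diab_onset = diab_onset,
                  py = as.numeric(alive0)))
}

sim_totals <- function(acc, w) {
  list(n = length(w),
       represented = sum(w),
       person_years = sum(w * acc$py),
       cvd_events = sum(w * acc$events),
       events_mi = sum(w * acc$mi), events_angina = sum(w * acc$angina),
       events_rca = sum(w * acc$rca), events_stroke = sum(w * acc$stroke),
       cvd_deaths = sum(w * acc$cvd_death),
       total_deaths = sum(w * acc$dead),
       diabetes_cases = sum(w * acc$diab),
       qalys = sum(w * acc$qaly),
       hc_costs = sum(w * acc$cost))
}

#' Simulate a cohort under one set of risk modifiers
#'
#' Runs the annual-cycle state-transition simulation for every person until
#' the horizon (or death / age 100 under \code{"lifetime"}). Random numbers
#' are drawn from one seeded stream per cycle for the whole cohort, so two
#' runs with the same seed see identical draws person-for-person and
#' cycle-for-cycle (common random numbers): where hazards coincide, event
#' histories coincide exactly, which makes incremental comparisons against
#' a base case noise-free for unaffected persons.
#'
#' @param population A \code{snap_population} (all persons start
#'   CVD-free; the diabetes flag comes from the population).
#' @param modifiers \code{snap_modifiers} from
#'   \code{\link{person_modifiers}}, or \code{NULL} for the base case.
#' @param horizon One of 5, 10, 20, or \code{"lifetime"}.
#' @param params \code{\link{engine_params}}.
#' @param seed Integer seed for the event draws.
#' @param expansion Per-person expansion factors (default
#'   \code{\link{scale_to_national}} adult scaling).
#' @param snapshot_years Additional years at which cumulative totals are
#'   recorded (e.g. \code{c(5, 10, 20)} during a lifetime run).
#' @param trace If \code{TRUE}, also record the count of persons in each
#'   state at the end of every cycle.
#' @return Object of class \code{snap_sim}: \code{totals} (cumulative,
#'   expansion-weighted), \code{snapshots} (named list of totals per
#'   snapshot year), \code{per_person} accumulators, \code{alive_frac}
#'   (expansion-weighted alive fraction at the start of each cycle),
#'   and metadata.
#' @export
simulate_cohort <- function(population, modifiers = NULL,
                            horizon = "lifetime",
                            params = engine_params(), seed = 1L,
                            expansion = scale_to_national(population),
                            snapshot_years = NULL, trace = FALSE) {
  if (NROW(population) == 0) stop("population is empty")
  years <- if (identical(horizon, "lifetime")) {
    max(1L, as.integer(ceiling(100 - min(population$age))))
  } else if (is.numeric(horizon) && horizon %in% c(5, 10, 20)) {
    as.integer(horizon)
  } else stop("horizon must be 5, 10, 20, or \"lifetime\"")
  n <- nrow(population)
  if (is.null(modifiers)) modifiers <- identity_modifiers(n)
  if (length(expansion) == 1L) expansion <- rep(expansion, n)

  ps <- list(state = rep(health_states()[["WELL"]], n),
             age = population$age, sex = population$sex,
             sbp = population$sbp, total_chol = population$total_chol,
             hdl = population$hdl, bmi = population$bmi,
             smoker = population$smoker, diabetic = population$diabetic)
  acc <- list(qaly = numeric(n), cost = numeric(n), events = numeric(n),
              mi = numeric(n), angina = numeric(n), rca = numeric(n),
              stroke = numeric(n), diab = numeric(n),
              cvd_death = numeric(n), dead = numeric(n), py = numeric(n))
  snapshots <- list()
  alive_frac <- numeric(years)
  state_trace <- if (trace) matrix(0L, years, 9,
                                   dimnames = list(NULL,
                                                   names(health_states())))

  for (t in seq_len(years)) {
    alive_frac[t] <- sum(expansion[ps$state < 8L]) / sum(expansion)
    set.seed(seed + t)
    u <- matrix(stats::runif(5L * n), n, 5L)
    step <- advance_year(ps, modifiers, params, u, t)
    ps <- step$ps
    inc <- step$inc
    acc$qaly <- acc$qaly + inc$qaly
    acc$cost <- acc$cost + inc$cost
    acc$events <- acc$events + inc$event
    for (k in 1:4) {
      nm <- c("mi", "angina", "rca", "stroke")[k]
      acc[[nm]] <- acc[[nm]] + (inc$event_type == k)
    }
    acc$diab <- acc$diab + inc$diab_onset
    acc$cvd_death <- acc$cvd_death + inc$fatal_cvd
    acc$dead <- acc$dead + (inc$fatal_cvd | inc$died_other)
    acc$py <- acc$py + inc$py
    if (trace) state_trace[t, ] <- tabulate(ps$state, 9L)
    if (t %in% snapshot_years)
      snapshots[[as.character(t)]] <- sim_totals(acc, expansion)
  }
  out <- list(totals = sim_totals(acc, expansion), snapshots = snapshots,
              per_person = acc, alive_frac = alive_frac,
              expansion = expansion, horizon = horizon, years = years,
              seed = seed, n = n)
  if (trace) out$state_trace <- state_trace
  class(out) <- "snap_sim"
  out
}

#' @export
print.snap_sim <- function(x, ...) {
  tt <- x$totals
  cat("<snap_sim> ", x$n, " persons, ", x$years, " years (horizon ",
      as.character(x$horizon), "), representing ",
      format(round(tt$represented), big.mark = ","), "\n", sep = "")
  cat(sprintf("  CVD events %s | CVD deaths %s | diabetes cases %s\n",
              format(round(tt$cvd_events), big.mark = ","),
              format(round(tt$cvd_deaths), big.mark = ","),
              format(round(tt$diabetes_cases), big.mark = ",")))
  cat(sprintf("  discounted QALYs %s | discounted healthcare $%.2fB\n",
              format(round(tt$qalys), big.mark = ","),
              tt$hc_costs / 1e9))
  invisible(x)
}

totals_at <- function(sim, horizon) {
  if (identical(horizon, sim$horizon) ||
      (is.numeric(horizon) && horizon == sim$years)) return(sim$totals)
  key <- as.character(horizon)
  if (!key %in% names(sim$snapshots))
    stop("no snapshot recorded at horizon ", key)
  sim$snapshots[[key]]
}

#' Incremental outcomes of a scenario against the base case
#'
#' Averted counts are base minus scenario (positive = prevented); QALYs
#' gained and healthcare savings are scenario minus base and base minus
#' scenario respectively.
#'
#' @param base,scenario \code{snap_sim} objects run with the same
#'   population, seed, and horizon.
#' @param horizon Horizon (final totals or a recorded snapshot year).
#' @return One-row \code{data.frame}.
#' @export
incremental_outcomes <- function(base, scenario, horizon = base$horizon) {
  b <- totals_at(base, horizon)
  s <- totals_at(scenario, horizon)
  data.frame(horizon = as.character(horizon),
             cvd_events_averted = b$cvd_events - s$cvd_events,
             cvd_deaths_averted = b$cvd_deaths - s$cvd_deaths,
             diabetes_averted = b$diabetes_cases - s$diabetes_cases,
             qalys_gained = s$qalys - b$qalys,
             hc_savings = b$hc_costs - s$hc_costs,
             stringsAsFactors = FALSE)
}

#' Incremental outcomes by population stratum
#'
#' Aggregates per-person incremental outcomes (base minus scenario) over a
#' categorical population field. Only valid at the runs' final horizon.
#'
#' @param base,scenario \code{snap_sim} objects (same population and seed).
#' @param population The population both were run on.
#' @param by One of \code{"age_band"}, \code{"sex"},
#'   \code{"race_ethnicity"}, \code{"education"}, \code{"insurance"}.
#' @return \code{data.frame} with one row per stratum.
#' @export
stratified_outcomes <- function(base, scenario, population, by = "sex") {
  if (by == "age_band") {
    bands <- default_marginal_targets()$age_band
    e <- age_band_edges(bands)
    g <- names(bands)[pmin(findInterval(population$age, e$lo),
                           length(bands))]
  } else {
    g <- population[[by]]
    if (is.null(g)) stop("unknown stratification field: ", by)
  }
  w <- base$expansion
  bp <- base$per_person; sp <- scenario$per_person
  agg <- function(v) tapply(w * v, g, sum)
  data.frame(stratum = names(agg(bp$events)),
             cvd_events_averted = as.numeric(agg(bp$events - sp$events)),
             cvd_deaths_averted = as.numeric(agg(bp$cvd_death -
                                                   sp$cvd_death)),
             diabetes_averted = as.numeric(agg(bp$diab - sp$diab)),
             qalys_gained = as.numeric(agg(sp$qaly - bp$qaly)),
             hc_savings = as.numeric(agg(bp$cost - sp$cost)),
             stringsAsFactors = FALSE, row.names = NULL)
}
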