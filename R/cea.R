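#' Discount a cash flow or health amount
#'
#' \code{amount / (1 + rate)^year_index}; year 0 is undiscounted.
#'
#' @param amount Amount (dollars or QALYs).
#' @param year_index Non-negative integer year offset.
#' @param rate Annual discount rate (default 0.03).
#' @return Discounted amount.
#' @export
discounted <- function(amount, year_index, rate = 0.03) {
  if (any(year_index < 0)) stop("year_index must be >= 0")
  amount / (1 + rate)^year_index
}

discount_sum <- function(years, rate = 0.03) {
  sum((1 + rate)^(-(seq_len(years) - 1)))
}

#' Program cost inputs
#'
#' Participant counts, discounting, the administrative-cost schedule, and
#' per-participant annual SNAP-dollar food spending by category (2017 USD).
#' Shipped defaults are calibration inputs: spends are back-solved so the
#' 5-year discounted food-subsidy costs sit on the published scale, and the
#' admin schedule (startup plus flat annual cost per scenario) is fitted to
#' the published near-flat cumulative discounted values.
#'
#' @param dir Directory with \code{admin_costs.csv} and
#'   \code{food_spend.csv}; defaults to the tables shipped with the
#'   package.
#' @param adults Adult (35+) SNAP participants represented.
#' @param all_participants All SNAP participants (children and adults).
#' @param discount_rate Annual discount rate.
#' @param cpi_base Price base year (all costs constant dollars).
#' @return List of class \code{snap_cost_inputs}.
#' @export
cost_inputs <- function(dir = system.file("extdata", package = "snapcea"),
                        adults = 42138000 * 0.345,
                        all_participants = 42138000,
                        discount_rate = 0.03,
                        cpi_base = 2017) {
  admin <- utils::read.csv(file.path(dir, "admin_costs.csv"),
                           stringsAsFactors = FALSE)
  spend <- utils::read.csv(file.path(dir, "food_spend.csv"),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("scenario", "startup_millions",
                  "annual_millions") %in% names(admin)),
            all(c("food", "spend_adult", "spend_child") %in% names(spend)))
  if (any(spend$spend_adult < 0 | spend$spend_child < 0))
    stop("food spending must be >= 0")
  if (discount_rate < 0 || discount_rate > 0.1)
    stop("discount_rate must lie in [0, 0.1]")
  structure(list(admin = admin, food_spend = spend, adults = adults,
                 all_participants = all_participants,
                 discount_rate = discount_rate, cpi_base = cpi_base),
            class = "snap_cost_inputs")
}

#' Cumulative discounted administrative cost of a scenario
#'
#' Startup cost plus a flat annual cost discounted over the horizon.
#'
#' @param scenario_id Scenario identifier matching the admin schedule.
#' @param inputs \code{\link{cost_inputs}}.
#' @param years Horizon length in years.
#' @param multiplier Optional scalar (probabilistic sensitivity analysis).
#' @return Dollars.
#' @export
admin_cost <- function(scenario_id, inputs, years, multiplier = 1) {
  row <- inputs$admin[inputs$admin$scenario == scenario_id, , drop = FALSE]
  if (nrow(row) != 1) stop("no admin schedule for scenario ", scenario_id)
  1e6 * multiplier * (row$startup_millions +
                        row$annual_millions *
                          discount_sum(years, inputs$discount_rate))
}

#' Net discounted food-subsidy cost of a scenario
#'
#' Incentive payments minus disincentive receipts over the horizon,
#' discounted, for either the adult cohort or all SNAP participants.
#' Restricted foods produce no program savings (the benefit dollars are
#' simply spent on other eligible foods) and contribute zero. Yearly flows
#' follow the simulated adult cohort's survival profile
#' (\code{survival_profile}; constant enrollment if omitted). Negative
#' values are net program revenue.
#'
#' @param scenario A \code{\link{snap_scenario}}.
#' @param inputs \code{\link{cost_inputs}}.
#' @param scope \code{"adults_35plus"} or \code{"all_participants"}.
#' @param years Horizon length in years.
#' @param survival_profile Optional per-year alive fraction of the adult
#'   cohort (length >= \code{years}).
#' @param spend_multiplier Optional scalar on all spends (PSA).
#' @return Signed dollars.
#' @export
food_program_cost <- function(scenario, inputs, scope = "all_participants",
                              years = 5, survival_profile = NULL,
                              spend_multiplier = 1) {
  if (!scope %in% c("adults_35plus", "all_participants"))
    stop("unknown scope: ", scope)
  sp <- inputs$food_spend
  per_capita <- function(foods, col) {
    if (length(foods) == 0) return(0)
    idx <- match(foods, sp$food)
    if (anyNA(idx)) stop("no food spending row for: ",
                         paste(foods[is.na(idx)], collapse = ", "))
    sum(sp[[col]][idx])
  }
  flow_for <- function(col, count) {
    count * (scenario$incentive_rate *
               per_capita(scenario$incentivized, col) -
             scenario$disincentive_rate *
               per_capita(scenario$disincentivized, col))
  }
  annual_flow <- flow_for("spend_adult", inputs$adults)
  if (scope == "all_participants")
    annual_flow <- annual_flow +
      flow_for("spend_child", inputs$all_participants - inputs$adults)
  if (is.null(survival_profile)) survival_profile <- rep(1, years)
  if (length(survival_profile) < years)
    stop("survival_profile shorter than the horizon")
  t <- seq_len(years)
  spend_multiplier * annual_flow *
    sum(survival_profile[t] / (1 + inputs$discount_rate)^(t - 1))
}

#' Net cost under an accounting perspective
#'
#' \describe{
#'   \item{societal}{administrative cost minus healthcare savings; food
#'     subsidies are an intra-societal transfer and are excluded.}
#'   \item{govt_adults}{adds the net food-subsidy cost for adult (35+)
#'     participants.}
#'   \item{govt_all}{adds the net food-subsidy cost for all participants
#'     (children and young adults contribute subsidy costs only, never
#'     health benefits).}
#'   \item{snap_budget}{SNAP fiscal view: administrative plus food-subsidy
#'     cost for all participants, ignoring healthcare savings.}
#' }
#'
#' @param perspective One of the four perspectives above.
#' @param components List with \code{admin}, \code{hc_savings},
#'   \code{food_adults}, \code{food_all} (dollars).
#' @return Net cost in dollars (negative = net savings).
#' @export
net_cost <- function(perspective, components) {
  need <- switch(perspective,
                 societal = c("admin", "hc_savings"),
                 govt_adults = c("admin", "hc_savings", "food_adults"),
                 govt_all = c("admin", "hc_savings", "food_all"),
                 snap_budget = c("admin", "food_all"),
                 stop("unknown perspective: ", perspective))
  missing <- setdiff(need, names(components)[!vapply(components, is.null,
                                                     logical(1))])
  if (length(missing))
    stop("missing component(s): ", paste(missing, collapse = ", "))
  switch(perspective,
         societal = components$admin - components$hc_savings,
         govt_adults = components$admin - components$hc_savings +
           components$food_adults,
         govt_all = components$admin - components$hc_savings +
           components$food_all,
         snap_budget = components$admin + components$food_all)
}

#' Incremental cost-effectiveness ratio and classification
#'
#' ICER = net cost / QALYs gained when both are positive. An intervention
#' with net savings and positive QALY gains is flagged cost-saving
#' (dominant); positive net cost with QALY losses is dominated.
#' Willingness-to-pay classification is applied exactly at $50,000/QALY
#' (very cost-effective) and $150,000/QALY (cost-effective).
#'
#' @param net_cost Net cost in dollars.
#' @param delta_qaly QALYs gained (non-zero).
#' @param thresholds Willingness-to-pay thresholds, dollars/QALY.
#' @return List with \code{icer} (dollars/QALY or \code{NA}) and
#'   \code{status}.
#' @export
icer <- function(net_cost, delta_qaly, thresholds = c(50000, 150000)) {
  if (delta_qaly == 0) stop("delta_qaly must be non-zero")
  if (delta_qaly > 0 && net_cost < 0)
    return(list(icer = NA_real_, status = "cost_saving"))
  if (delta_qaly < 0 && net_cost > 0)
    return(list(icer = NA_real_, status = "dominated"))
  value <- net_cost / delta_qaly
  status <- if (delta_qaly > 0) {
    if (value <= thresholds[1]) "very_cost_effective"
    else if (value <= thresholds[2]) "cost_effective"
    else "not_cost_effective"
  } else "cost_saving_less_effective"
  list(icer = value, status = status)
}

#' Load the published benchmark point estimates
#'
#' Point estimates for the three scenarios (cases averted, QALYs gained,
#' healthcare savings, administrative and food-subsidy costs by horizon)
#' from the published national evaluation that this package's parameter
#' defaults are calibrated toward. Used for arithmetic cross-checks of the
#' cost-effectiveness identities and as calibration targets; not produced
#' by this package's simulation.
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return \code{data.frame}, one row per scenario x horizon.
#' @export
load_benchmarks <- function(path = system.file("extdata",
                                               "published_benchmarks.csv",
                                               package = "snapcea")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cost-effectiveness summary from outcome and cost components
#'
#' Assembles net costs and ICERs for every perspective from a set of
#' components, rounding nothing (presentation rounding is left to print
#' methods).
#'
#' @param components List with \code{admin}, \code{hc_savings},
#'   \code{food_adults}, \code{food_all} (dollars) and \code{qalys_gained}.
#' @param perspectives Character vector of perspectives.
#' @return \code{data.frame} with one row per perspective: net cost, ICER,
#'   status.
#' @export
cea_from_components <- function(components,
                                perspectives = c("societal", "govt_adults",
                                                 "govt_all")) {
  rows <- lapply(perspectives, function(p) {
    nc <- net_cost(p, components)
    ic <- icer(nc, components$qalys_gained)
    data.frame(perspective = p, net_cost = nc, icer = ic$icer,
               status = ic$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
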