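#' Define a SNAP pricing scenario
#'
#' A scenario combines a financial incentive (a fraction returned to the EBT
#' account per dollar spent on incentivized foods), a disincentive (an extra
#' fraction debited per dollar spent on disincentivized foods), and/or an
#' outright restriction (a food made ineligible for SNAP purchase). A food
#' may appear in at most one of the three sets.
#'
#' @param id Scenario identifier.
#' @param incentive_rate,disincentive_rate Fractions in (0, 1); default 0.30.
#' @param incentivized,disincentivized,restricted Character vectors of food
#'   categories (see \code{\link{food_categories}}).
#' @return An object of class \code{snap_scenario}.
#' @export
snap_scenario <- function(id, incentive_rate = 0.30, disincentive_rate = 0.30,
                          incentivized = character(),
                          disincentivized = character(),
                          restricted = character()) {
  all_foods <- c(incentivized, disincentivized, restricted)
  if (anyDuplicated(all_foods))
    stop("a food may appear in at most one of the incentivized, ",
         "disincentivized, and restricted sets")
  if (!all(all_foods %in% food_categories()))
    stop("unknown food categories: ",
         paste(setdiff(all_foods, food_categories()), collapse = ", "))
  if (incentive_rate <= 0 || incentive_rate >= 1 ||
      disincentive_rate <= 0 || disincentive_rate >= 1)
    stop("rates must lie in (0, 1)")
  structure(list(id = id, incentive_rate = incentive_rate,
                 disincentive_rate = disincentive_rate,
                 incentivized = incentivized,
                 disincentivized = disincentivized,
                 restricted = restricted),
            class = "snap_scenario")
}

#' The three modelled SNAP policy scenarios
#'
#' \describe{
#'   \item{fv_incentive}{30\% incentive for fruits and vegetables.}
#'   \item{fv_ssb_restriction}{30\% F&V incentive plus restriction of SSBs.}
#'   \item{snap_plus}{30\% incentives for F&V, nuts, whole grains, fish, and
#'     plant-based oils combined with 30\% disincentives for SSBs, junk food,
#'     and processed meats.}
#' }
#'
#' @return Named list of \code{\link{snap_scenario}} objects.
#' @export
default_scenarios <- function() {
  list(
    fv_incentive = snap_scenario("fv_incentive",
      incentivized = c("fruits", "vegetables")),
    fv_ssb_restriction = snap_scenario("fv_ssb_restriction",
      incentivized = c("fruits", "vegetables"), restricted = "ssb"),
    snap_plus = snap_scenario("snap_plus",
      incentivized = c("fruits", "vegetables", "nuts", "whole_grains",
                       "fish", "plant_oils"),
      disincentivized = c("ssb", "junk_food", "processed_meat"))
  )
}

#' @export
print.snap_scenario <- function(x, ...) {
  cat("<snap_scenario> ", x$id, "\n", sep = "")
  if (length(x$incentivized))
    cat("  incentivized (", 100 * x$incentive_rate, "%): ",
        paste(x$incentivized, collapse = ", "), "\n", sep = "")
  if (length(x$disincentivized))
    cat("  disincentivized (", 100 * x$disincentive_rate, "%): ",
        paste(x$disincentivized, collapse = ", "), "\n", sep = "")
  if (length(x$restricted))
    cat("  restricted: ", paste(x$restricted, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Load the per-food policy effect components
#'
#' Reads the effect-component table (one row per scenario x food) with the
#' pieces that compose a price instrument's overall intake effect: the
#' fractional intake response to a 30\% price change at the point of
#' purchase (\code{price_response}, signed), the share of the food bought
#' with SNAP dollars (\code{snap_dollar_share}), the share bought at
#' SNAP-eligible venues (\code{snap_venue_share}), and the fraction of the
#' SNAP-dollar response offset by shifting spending to non-SNAP dollars
#' (\code{spend_shift}). Restriction rows instead carry
#' \code{snap_retail_share}. The shipped defaults are calibrated so the
#' composed overall changes equal the published per-food effects.
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return A validated \code{data.frame}.
#' @export
load_effect_components <- function(path = system.file("extdata",
                                                      "effect_components.csv",
                                                      package = "snapcea")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "food", "instrument", "price_response",
            "snap_dollar_share", "snap_venue_share", "spend_shift",
            "snap_retail_share")
  if (!all(need %in% names(x)))
    stop("effect component table must have columns: ",
         paste(need, collapse = ", "))
  shares <- c("snap_dollar_share", "snap_venue_share", "spend_shift",
              "snap_retail_share")
  for (s in shares) {
    v <- x[[s]][!is.na(x[[s]])]
    if (any(v < 0 | v > 1)) stop("column ", s, " must lie in [0, 1]")
  }
  bad <- (x$instrument == "incentive" & x$price_response < 0) |
    (x$instrument == "disincentive" & x$price_response > 0)
  if (any(bad, na.rm = TRUE))
    stop("price_response sign must match the instrument")
  x
}

#' Overall intake change composed from effect components
#'
#' Composes one food's overall fractional intake change under a price
#' incentive or disincentive:
#' \deqn{\Delta\% = price\_response \times snap\_venue\_share \times
#'   snap\_dollar\_share \times (1 - spend\_shift).}
#' The sign follows \code{price_response} (positive for incentives,
#' negative for disincentives), and the magnitude can never exceed
#' \eqn{|price\_response|} since every share is at most 1.
#'
#' @param components A one-row data.frame or list with fields
#'   \code{price_response}, \code{snap_dollar_share},
#'   \code{snap_venue_share}, \code{spend_shift}.
#' @return Signed fraction.
#' @export
overall_change_incentive <- function(components) {
  shares <- c(components$snap_dollar_share, components$snap_venue_share,
              components$spend_shift)
  if (any(is.na(shares)) || any(shares < 0 | shares > 1))
    stop("shares must lie in [0, 1]")
  components$price_response * components$snap_venue_share *
    components$snap_dollar_share * (1 - components$spend_shift)
}

#' Overall intake change under a SNAP restriction
#'
#' A restricted food can no longer be bought with SNAP dollars; participants
#' shift a fraction \code{shift} of their restricted purchases at retail
#' venues to other food dollars, so the net overall change is
#' \code{-snap_retail_share * (1 - shift)}.
#'
#' @param snap_retail_share Fraction of overall intake bought with SNAP
#'   dollars at retail venues, in [0, 1].
#' @param shift Fraction of those purchases shifted to non-SNAP dollars,
#'   in [0, 1].
#' @return Non-positive fraction.
#' @export
overall_change_restriction <- function(snap_retail_share, shift) {
  if (snap_retail_share < 0 || snap_retail_share > 1 ||
      shift < 0 || shift > 1)
    stop("snap_retail_share and shift must lie in [0, 1]")
  -snap_retail_share * (1 - shift)
}

#' Per-food overall intake changes for a scenario
#'
#' Looks up each food targeted by the scenario in the effect-component table
#' and composes its overall fractional change
#' (\code{\link{overall_change_incentive}} for incentives/disincentives,
#' \code{\link{overall_change_restriction}} for restrictions). Absolute
#' changes are reported against a baseline intake vector.
#'
#' @param scenario A \code{\link{snap_scenario}}.
#' @param effects Effect-component table from
#'   \code{\link{load_effect_components}}.
#' @param baseline Named vector of baseline intakes (g/d); default
#'   \code{\link{default_diet_means}}.
#' @return A \code{data.frame} with columns \code{food},
#'   \code{instrument}, \code{pct_change} (fraction), and
#'   \code{abs_change} (g/d), satisfying
#'   \code{abs_change == pct_change * baseline} exactly.
#' @export
intake_changes <- function(scenario, effects,
                           baseline = default_diet_means()) {
  rows <- effects[effects$scenario == scenario$id, , drop = FALSE]
  out <- list()
  lookup <- function(food) {
    r <- rows[rows$food == food, , drop = FALSE]
    if (nrow(r) != 1)
      stop("no effect components for food '", food, "' in scenario '",
           scenario$id, "'")
    r
  }
  for (food in scenario$incentivized) {
    r <- lookup(food)
    out[[food]] <- data.frame(food = food, instrument = "incentive",
                              pct_change = overall_change_incentive(r))
  }
  for (food in scenario$disincentivized) {
    r <- lookup(food)
    pc <- overall_change_incentive(r)
    if (pc > 0) stop("disincentive for '", food, "' must be non-positive")
    out[[food]] <- data.frame(food = food, instrument = "disincentive",
                              pct_change = pc)
  }
  for (food in scenario$restricted) {
    r <- lookup(food)
    out[[food]] <- data.frame(food = food, instrument = "restriction",
                              pct_change = overall_change_restriction(
                                r$snap_retail_share, r$spend_shift))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(food = character(), instrument = character(),
                      pct_change = numeric())
  res$abs_change <- res$pct_change * unname(baseline[res$food])
  rownames(res) <- NULL
  res
}

#' Apply a scenario's dietary changes to a population
#'
#' Shifts each person's intake of every targeted food multiplicatively by
#' the food's overall fractional change, from simulation year 1 with no lag.
#' Untargeted foods are unchanged and intakes remain non-negative.
#'
#' @inheritParams intake_changes
#' @param population A \code{snap_population}.
#' @param effect_multiplier Optional scalar scaling all fractional changes
#'   (used by the probabilistic sensitivity analysis); default 1.
#' @return A list with elements \code{population} (diet-shifted copy) and
#'   \code{changes} (the \code{\link{intake_changes}} table, scaled).
#' @export
apply_scenario <- function(population, scenario, effects,
                           effect_multiplier = 1) {
  ch <- intake_changes(scenario, effects)
  ch$pct_change <- ch$pct_change * effect_multiplier
  ch$pct_change <- pmax(ch$pct_change, -1)   # intakes cannot go negative
  ch$abs_change <- ch$abs_change * effect_multiplier
  shifted <- population
  for (i in seq_len(nrow(ch)))
    shifted[[ch$food[i]]] <- shifted[[ch$food[i]]] * (1 + ch$pct_change[i])
  list(population = shifted, changes = ch)
}

#' Dietary Guidelines recommendation amounts
#'
#' Recommended amounts (2,000 kcal/d diet) used to express policy-induced
#' intake changes as fractions of the recommendation: fruits 2 cups/d,
#' vegetables 2.5 cups/d, nuts 5 oz/wk, whole grains 3 oz/d, fish 8 oz/wk.
#'
#' @return data.frame with columns \code{food}, \code{amount}, \code{unit}.
#' @export
dga_recommendations <- function() {
  data.frame(
    food = c("fruits", "vegetables", "nuts", "whole_grains", "fish"),
    amount = c(2, 2.5, 5, 3, 8),
    unit = c("cup_day", "cup_day", "oz_week", "oz_day", "oz_week"),
    stringsAsFactors = FALSE
  )
}

#' Intake change as a fraction of a dietary recommendation
#'
#' Converts the recommendation to g/d (1 oz = 28.35 g; 1 cup-equivalent =
#' 100 g; weekly amounts divided by 7) and expresses the change as a
#' fraction of it.
#'
#' @param change Intake change in g/d.
#' @param amount Recommended amount.
#' @param unit One of \code{"cup_day"}, \code{"oz_day"}, \code{"oz_week"}.
#' @param grams_per_oz,grams_per_cup Unit conversions.
#' @return Fraction of the recommendation.
#' @export
dga_fraction <- function(change, amount, unit,
                         grams_per_oz = 28.35, grams_per_cup = 100) {
  if (amount <= 0) stop("recommendation amount must be > 0")
  rec_gd <- switch(unit,
    cup_day = amount * grams_per_cup,
    oz_day = amount * grams_per_oz,
    oz_week = amount * grams_per_oz / 7,
    stop("unknown unit: ", unit))
  change / rec_gd
}
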