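#' Load the diet-disease relative-risk table
#'
#' One row per food x outcome with the log-linear dose-response relative
#' risk per \code{unit_size} g/d of intake, a reference age, and a
#' fractional attenuation of the log relative risk per decade of age above
#' the reference (etiologic effects of diet are stronger at younger ages).
#' The shipped default values are calibration inputs drawn from the
#' comparative-risk-assessment literature on diet and cardiometabolic
#' disease; note there is no fruit or vegetable entry for type 2 diabetes
#' (no probable/convincing etiologic evidence).
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return Validated \code{data.frame} with columns \code{food},
#'   \code{outcome} (chd/stroke/diabetes), \code{rr_per_unit},
#'   \code{unit_size}, \code{ref_age}, \code{age_attenuation},
#'   \code{pathway}.
#' @export
load_rr_table <- function(path = system.file("extdata", "rr_table.csv",
                                             package = "snapcea")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("food", "outcome", "rr_per_unit", "unit_size", "ref_age",
            "age_attenuation", "pathway")
  if (!all(need %in% names(x)))
    stop("rr table must have columns: ", paste(need, collapse = ", "))
  if (any(x$rr_per_unit <= 0)) stop("rr_per_unit must be > 0")
  if (any(x$unit_size <= 0)) stop("unit_size must be > 0")
  if (!all(x$outcome %in% c("chd", "stroke", "diabetes")))
    stop("outcome must be one of chd, stroke, diabetes")
  if (any(x$age_attenuation < 0)) stop("age_attenuation must be >= 0")
  x
}

#' Relative risk for an intake change
#'
#' Log-linear dose-response: the log relative risk at age \eqn{a} is
#' \deqn{\ln RR(a) = \ln(rr\_per\_unit) \times
#'   \max(0,\, 1 - attenuation \times (a - ref\_age)/10),}
#' and the multiplier for an intake change \eqn{\delta} (g/d) is
#' \eqn{\exp(\ln RR(a) \times \delta / unit\_size)}, clamped to
#' \code{clamp}. RR(0 change) is exactly 1, the multiplier is continuous
#' and monotone in \eqn{\delta}, and the attenuation floor guarantees the
#' age-specific RR never crosses 1.
#'
#' @param entry One row of the relative-risk table.
#' @param delta Intake change in g/d (finite; vectorized).
#' @param age Age in years (vectorized, recycled against \code{delta}).
#' @param clamp Length-2 bounds for the returned multiplier; default
#'   \code{c(0.5, 2)}. Use \code{c(0, Inf)} to disable.
#' @return Relative-risk multiplier(s).
#' @export
rr_for_change <- function(entry, delta, age, clamp = c(0.5, 2)) {
  if (entry$rr_per_unit <= 0) stop("rr_per_unit must be > 0")
  if (any(!is.finite(delta))) stop("delta must be finite")
  atten <- pmax(0, 1 - entry$age_attenuation * (age - entry$ref_age) / 10)
  rr <- exp(log(entry$rr_per_unit) * atten * delta / entry$unit_size)
  pmin(pmax(rr, clamp[1]), clamp[2])
}

#' Load the junk-food joint-association profile
#'
#' Junk food has no single etiologic effect of its own; its cardiometabolic
#' effect is composed from its independent joint associations with other
#' dietary components. Each row gives the induced change in one linked
#' component (g/d, or g/d of sodium) per 100 g/d of junk food consumed.
#' The shipped default profile is a calibration input: it retains nine
#' joint associations with mixed directions, so reducing junk food shifts
#' some components beneficially and some harmfully.
#'
#' @param path CSV path; defaults to the profile shipped with the package.
#' @return \code{data.frame} with columns \code{component},
#'   \code{delta_per_100g}.
#' @export
load_junk_profile <- function(path = system.file("extdata",
                                                 "junk_food_profile.csv",
                                                 package = "snapcea")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("component", "delta_per_100g") %in% names(x)))
    stop("junk profile must have columns component, delta_per_100g")
  if (any(!is.finite(x$delta_per_100g))) stop("profile deltas must be finite")
  x
}

#' Load the mediated-pathway effect specification
#'
#' Three stratified linear-slope tables: the SSB effect on BMI (kg/m2 per
#' 8-fl-oz serving per day, by age group and BMI group), the
#' outcome relative risks per kg/m2 of BMI, and the sodium effect on
#' systolic blood pressure (mmHg per g/d sodium, by race and hypertensive
#' status, with an age gradient). Shipped defaults are calibration inputs.
#'
#' @param dir Directory holding \code{ssb_bmi_slopes.csv},
#'   \code{bmi_outcome_rr.csv}, and \code{sodium_sbp_slopes.csv}.
#' @return List with elements \code{ssb_bmi}, \code{bmi_rr},
#'   \code{sodium_sbp}, \code{ssb_serving_g}.
#' @export
load_mediated_spec <- function(dir = system.file("extdata",
                                                 package = "snapcea")) {
  ssb_bmi <- utils::read.csv(file.path(dir, "ssb_bmi_slopes.csv"),
                             stringsAsFactors = FALSE)
  bmi_rr <- utils::read.csv(file.path(dir, "bmi_outcome_rr.csv"),
                            stringsAsFactors = FALSE)
  sodium <- utils::read.csv(file.path(dir, "sodium_sbp_slopes.csv"),
                            stringsAsFactors = FALSE)
  stopifnot(all(c("age_group", "bmi_group", "slope") %in% names(ssb_bmi)),
            all(c("outcome", "rr_per_unit") %in% names(bmi_rr)),
            all(c("race_group", "hypertensive", "slope",
                  "age_slope_per_decade", "ref_age") %in% names(sodium)))
  if (any(!is.finite(ssb_bmi$slope)) || any(!is.finite(sodium$slope)))
    stop("mediated-effect slopes must be finite")
  list(ssb_bmi = ssb_bmi, bmi_rr = bmi_rr, sodium_sbp = sodium,
       ssb_serving_g = 236)
}

rr_rows <- function(rr_table, food, outcome) {
  rr_table[rr_table$food == food & rr_table$outcome == outcome, ,
           drop = FALSE]
}

#' Composite relative risk of a junk-food intake change
#'
#' Multiplies the relative risks induced through each retained joint
#' association: a junk-food change of \code{delta_junk} g/d induces a
#' change \code{delta_per_100g * delta_junk / 100} in each linked
#' component, whose RR is computed with \code{\link{rr_for_change}}.
#' Components without an entry for the requested outcome contribute a
#' factor of 1; a component absent from the RR table entirely (other than
#' sodium, which acts through blood pressure) is an error.
#'
#' @param profile Junk-food profile from \code{\link{load_junk_profile}}.
#' @param delta_junk Junk-food intake change, g/d.
#' @param rr_table Relative-risk table.
#' @param age Age(s) in years.
#' @param outcome One of \code{"chd"}, \code{"stroke"}, \code{"diabetes"}.
#' @param clamp Passed to \code{\link{rr_for_change}}.
#' @return Composite relative-risk multiplier (vectorized over \code{age}).
#' @export
junk_food_rr <- function(profile, delta_junk, rr_table, age,
                         outcome = "chd", clamp = c(0.5, 2)) {
  rr <- rep(1, length(age))
  for (i in seq_len(nrow(profile))) {
    comp <- profile$component[i]
    if (comp == "sodium") next  # mediated through blood pressure
    if (!comp %in% rr_table$food)
      stop("junk-food component '", comp, "' has no relative-risk entries")
    rows <- rr_rows(rr_table, comp, outcome)
    if (nrow(rows) == 0) next
    d <- profile$delta_per_100g[i] * delta_junk / 100
    for (j in seq_len(nrow(rows)))
      rr <- rr * rr_for_change(rows[j, ], d, age, clamp)
  }
  rr
}

lookup_ssb_bmi_slope <- function(spec, age, bmi) {
  tab <- spec$ssb_bmi
  age_group <- ifelse(age < 65, "35-64", "65-80")
  bmi_group <- ifelse(bmi < 25, "lt25", ifelse(bmi < 30, "25-30", "ge30"))
  key <- paste(age_group, bmi_group)
  tkey <- paste(tab$age_group, tab$bmi_group)
  idx <- match(key, tkey)
  if (anyNA(idx)) stop("unknown SSB-BMI stratum: ",
                       paste(unique(key[is.na(idx)]), collapse = ", "))
  tab$slope[idx]
}

lookup_sodium_slope <- function(spec, age, race, sbp) {
  tab <- spec$sodium_sbp
  race_group <- ifelse(race == "nh_black", "black", "nonblack")
  hyper <- ifelse(sbp >= 140, "yes", "no")
  key <- paste(race_group, hyper)
  tkey <- paste(tab$race_group, tab$hypertensive)
  idx <- match(key, tkey)
  if (anyNA(idx)) stop("unknown sodium-SBP stratum")
  tab$slope[idx] + tab$age_slope_per_decade[idx] *
    pmax(0, age - tab$ref_age[idx]) / 10
}

#' Identity risk modifiers (no dietary change)
#'
#' @param n Number of persons.
#' @return A \code{snap_modifiers} object with all relative risks 1 and all
#'   risk-factor shifts 0.
#' @export
identity_modifiers <- function(n) {
  structure(list(rr_chd = rep(1, n), rr_stroke = rep(1, n),
                 rr_diabetes = rep(1, n), d_sbp = rep(0, n),
                 d_bmi = rep(0, n)),
            class = "snap_modifiers")
}

#' Per-person risk modifiers implied by a scenario's dietary changes
#'
#' Translates an intake-change set into, for every person: multiplicative
#' relative risks for CHD, stroke, and diabetes (the product of the direct
#' log-linear food effects, the junk-food composite, the BMI-mediated
#' effects of SSB changes, and the direct BMI-independent SSB terms); a BMI
#' shift from the SSB change (via the person's age/adiposity stratum
#' slope); and a systolic blood pressure shift from the sodium change
#' induced by junk food. Per-person intake deltas are the food's overall
#' fractional change times that person's baseline intake. The BMI-mediated
#' pathway acts only through \code{bmi_outcome_rr} (the engine's diabetes
#' incidence model stratifies on the unshifted BMI trajectory), so no
#' pathway is double-counted.
#'
#' @param population A \code{snap_population}.
#' @param changes Intake-change table from \code{\link{intake_changes}} /
#'   \code{\link{apply_scenario}}.
#' @param rr_table Relative-risk table (\code{\link{load_rr_table}}).
#' @param mediated Mediated-effect spec (\code{\link{load_mediated_spec}}).
#' @param junk_profile Junk-food profile (\code{\link{load_junk_profile}}).
#' @param clamp Per-food per-outcome RR bounds; default \code{c(0.5, 2)}.
#' @param rr_log_multiplier Optional scalar scaling all log relative risks
#'   (used by the probabilistic sensitivity analysis); default 1.
#' @return A \code{snap_modifiers} object: vectors \code{rr_chd},
#'   \code{rr_stroke}, \code{rr_diabetes}, \code{d_sbp} (mmHg),
#'   \code{d_bmi} (kg/m2).
#' @export
person_modifiers <- function(population, changes, rr_table = load_rr_table(),
                             mediated = load_mediated_spec(),
                             junk_profile = load_junk_profile(),
                             clamp = c(0.5, 2), rr_log_multiplier = 1) {
  n <- nrow(population)
  mod <- identity_modifiers(n)
  if (is.null(changes) || nrow(changes) == 0) return(mod)
  if (rr_log_multiplier != 1) {
    rr_table$rr_per_unit <- exp(log(rr_table$rr_per_unit) *
                                  rr_log_multiplier)
    bmi_rr <- mediated$bmi_rr
    bmi_rr$rr_per_unit <- exp(log(bmi_rr$rr_per_unit) * rr_log_multiplier)
    mediated$bmi_rr <- bmi_rr
  }
  age <- population$age
  outcomes <- c(chd = "rr_chd", stroke = "rr_stroke",
                diabetes = "rr_diabetes")
  for (i in seq_len(nrow(changes))) {
    food <- changes$food[i]
    delta <- changes$pct_change[i] * population[[food]]
    if (food == "junk_food") {
      for (oc in names(outcomes)) {
        mod[[outcomes[[oc]]]] <- mod[[outcomes[[oc]]]] *
          junk_food_rr(junk_profile, delta, rr_table, age, oc, clamp)
      }
      # sodium induced by the junk-food change acts on blood pressure
      srow <- junk_profile[junk_profile$component == "sodium", , drop = FALSE]
      if (nrow(srow) == 1) {
        d_sodium <- srow$delta_per_100g * delta / 100
        slope <- lookup_sodium_slope(mediated, age,
                                     population$race_ethnicity,
                                     population$sbp)
        mod$d_sbp <- mod$d_sbp + slope * d_sodium
      }
      next
    }
    for (oc in names(outcomes)) {
      rows <- rr_rows(rr_table, food, oc)
      for (j in seq_len(nrow(rows)))
        mod[[outcomes[[oc]]]] <- mod[[outcomes[[oc]]]] *
          rr_for_change(rows[j, ], delta, age, clamp)
    }
    if (food == "ssb") {
      slope <- lookup_ssb_bmi_slope(mediated, age, population$bmi)
      d_bmi <- slope * delta / mediated$ssb_serving_g
      mod$d_bmi <- mod$d_bmi + d_bmi
      for (oc in names(outcomes)) {
        r <- mediated$bmi_rr[mediated$bmi_rr$outcome == oc, , drop = FALSE]
        if (nrow(r) == 1) {
          f <- exp(log(r$rr_per_unit) * d_bmi)
          f <- pmin(pmax(f, clamp[1]), clamp[2])
          mod[[outcomes[[oc]]]] <- mod[[outcomes[[oc]]]] * f
        }
      }
    }
  }
  mod
}
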