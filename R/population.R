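#' Names of the nine modelled food categories
#'
#' The simulation tracks daily intake (g/d) of nine food categories targeted
#' by the policy scenarios: fruits, vegetables, nuts, whole grains, fish,
#' plant-based oils, sugar-sweetened beverages (SSBs), processed meat, and
#' junk food.
#'
#' @return Character vector of length 9.
#' @export
food_categories <- function() {
  c("fruits", "vegetables", "nuts", "whole_grains", "fish",
    "plant_oils", "ssb", "processed_meat", "junk_food")
}

#' Default categorical marginal targets for the SNAP adult population
#'
#' Proportions for age band, sex, race/ethnicity, education, family
#' income-to-poverty ratio, and federal insurance coverage among adult SNAP
#' participants aged 35-80. Insurance is coded into four mutually exclusive
#' levels (Medicare only, Medicaid only, dual-eligible, other), so that
#' Medicare-or-Medicaid coverage is their sum minus "other".
#'
#' @return Named list of named numeric vectors, each summing to 1.
#' @export
default_marginal_targets <- function() {
  list(
    age_band = c("35-44" = 0.294, "45-54" = 0.309, "55-64" = 0.247,
                 "65-74" = 0.106, "75-80" = 0.044),
    sex = c(male = 0.457, female = 0.543),
    race_ethnicity = c(nh_white = 0.508, nh_black = 0.243,
                       hispanic = 0.189, other = 0.060),
    education = c(lt_high_school = 0.361, high_school = 0.289,
                  some_college = 0.280, college_grad = 0.070),
    income_poverty_ratio = c("lt_1.30" = 0.674, "1.30-1.84" = 0.139,
                             "1.85-2.99" = 0.112, "ge_3.00" = 0.075),
    insurance = c(medicare = 0.122, medicaid = 0.193,
                  dual = 0.102, other = 0.583)
  )
}

#' Default baseline dietary intake means (g/d)
#'
#' Mean daily intakes of the nine food categories among adult SNAP
#' participants, used as the means of the right-skewed (gamma) intake
#' distributions in the synthetic population.
#'
#' @return Named numeric vector (g/d); SSB mass uses 29.57 g per fluid ounce
#'   (414 g/d = 14.0 fl oz/d).
#' @export
default_diet_means <- function() {
  c(fruits = 81.3, vegetables = 134.8, nuts = 5.4, whole_grains = 13.9,
    fish = 20.6, plant_oils = 18.7, ssb = 414, processed_meat = 31.8,
    junk_food = 66.5)
}

default_risk_factor_distributions <- function() {
  list(
    sbp        = list(family = "normal",    mean = 127, sd = 17, min = 85),
    total_chol = list(family = "normal",    mean = 196, sd = 40, min = 90),
    hdl        = list(family = "lognormal", meanlog = log(50), sdlog = 0.28),
    bmi        = list(family = "lognormal", meanlog = log(29.5), sdlog = 0.21,
                      min = 15),
    smoker     = list(prevalence = 0.30),
    diabetic   = list(prevalence = 0.25)
  )
}

default_correlation_spec <- function() {
  vars <- c("age", "sbp", "total_chol", "hdl", "bmi", "diabetic")
  m <- diag(length(vars))
  dimnames(m) <- list(vars, vars)
  set_cor <- function(m, a, b, r) { m[a, b] <- r; m[b, a] <- r; m }
  m <- set_cor(m, "age", "sbp", 0.30)
  m <- set_cor(m, "age", "total_chol", 0.15)
  m <- set_cor(m, "bmi", "hdl", -0.25)
  m <- set_cor(m, "bmi", "diabetic", 0.30)
  m
}

#' Configuration for the synthetic SNAP population generator
#'
#' Bundles and validates everything the generator needs: the number of
#' persons, the random seed, categorical marginal targets, the target mean
#' age, risk-factor marginal distributions, a Gaussian-copula rank
#' correlation matrix over the continuous risk factors (plus a latent
#' diabetes score), and baseline dietary intake means.
#'
#' Ages are drawn band-stratified: the band marginals are matched exactly in
#' expectation, and a common within-band Beta shape is calibrated so the
#' population mean age equals \code{age_mean_target}. Note that the age SD is
#' then determined by the band masses and within-band shape (see
#' \code{\link{implied_age_moments}}).
#'
#' @param size Number of persons to generate (>= 1).
#' @param seed Integer random seed.
#' @param marginal_targets List of named proportion vectors; each must sum
#'   to 1 (tolerance 1e-9).
#' @param age_mean_target Target mean age in years.
#' @param age_beta_total Sum of the within-band Beta shape parameters
#'   (smaller = more within-band spread).
#' @param risk_factor_distributions Per-factor family and parameters.
#' @param correlation_spec Positive semidefinite correlation matrix over
#'   age, SBP, total cholesterol, HDL, BMI, and the latent diabetes score.
#' @param diet_baseline_means Named vector of mean intakes (g/d) for the 9
#'   food categories.
#' @param diet_cv Coefficient of variation of the gamma intake
#'   distributions (default 1, i.e. exponential).
#' @return An object of class \code{snap_pop_config}.
#' @export
population_config <- function(size,
                              seed = 1L,
                              marginal_targets = default_marginal_targets(),
                              age_mean_target = 52.1,
                              age_beta_total = 1.0,
                              risk_factor_distributions =
                                default_risk_factor_distributions(),
                              correlation_spec = default_correlation_spec(),
                              diet_baseline_means = default_diet_means(),
                              diet_cv = 1.0) {
  if (!is.numeric(size) || length(size) != 1L || size < 1)
    stop("`size` must be a single number >= 1")
  for (nm in names(marginal_targets)) {
    p <- marginal_targets[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("marginal targets for '", nm, "' must be non-negative and sum to 1")
  }
  ev <- eigen(correlation_spec, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation_spec is not positive semidefinite")
  if (!setequal(names(diet_baseline_means), food_categories()))
    stop("diet_baseline_means must name exactly the 9 food categories")
  if (any(diet_baseline_means < 0)) stop("diet means must be >= 0")
  cfg <- list(size = as.integer(size), seed = as.integer(seed),
              marginal_targets = marginal_targets,
              age_mean_target = age_mean_target,
              age_beta_total = age_beta_total,
              risk_factor_distributions = risk_factor_distributions,
              correlation_spec = correlation_spec,
              diet_baseline_means = diet_baseline_means[food_categories()],
              diet_cv = diet_cv)
  class(cfg) <- "snap_pop_config"
  cfg
}

age_band_edges <- function(bands) {
  # band labels "lo-hi"; upper edge is exclusive except the last (inclusive 80)
  lo <- as.numeric(sub("-.*", "", names(bands)))
  hi <- as.numeric(sub(".*-", "", names(bands)))
  hi <- hi + 1          # "35-44" covers [35, 45)
  hi[length(hi)] <- 80  # top band "75-80" covers [75, 80]
  list(lo = lo, hi = hi, w = hi - lo)
}

age_beta_mean <- function(cfg) {
  bands <- cfg$marginal_targets$age_band
  e <- age_band_edges(bands)
  m <- (cfg$age_mean_target - sum(bands * e$lo)) / sum(bands * e$w)
  if (m <= 0 || m >= 1)
    stop("age_mean_target is unattainable given the age-band marginals")
  m
}

#' Analytically implied mean and SD of age under the generator's design
#'
#' Given the configured band marginals, target mean, and within-band Beta
#' shape, returns the exact mean and standard deviation of the age
#' distribution the generator samples from.
#'
#' @param config A \code{snap_pop_config}.
#' @return Named numeric vector with elements \code{mean} and \code{sd}.
#' @export
implied_age_moments <- function(config) {
  bands <- config$marginal_targets$age_band
  e <- age_band_edges(bands)
  m <- age_beta_mean(config)
  s <- config$age_beta_total
  v <- m * (1 - m) / (s + 1)
  ex2_b <- v + m^2
  ex  <- sum(bands * (e$lo + e$w * m))
  ex2 <- sum(bands * (e$lo^2 + 2 * e$lo * e$w * m + e$w^2 * ex2_b))
  c(mean = ex, sd = sqrt(ex2 - ex^2))
}

quantile_age <- function(u, cfg) {
  bands <- cfg$marginal_targets$age_band
  e <- age_band_edges(bands)
  cum <- cumsum(bands)
  band <- findInterval(u, c(0, cum[-length(cum)]), rightmost.closed = TRUE)
  band[band < 1] <- 1L
  band[band > length(bands)] <- length(bands)
  lower_cum <- c(0, cum)[band]
  within <- (u - lower_cum) / bands[band]
  within <- pmin(pmax(within, 0), 1)
  m <- age_beta_mean(cfg)
  a <- m * cfg$age_beta_total
  b <- (1 - m) * cfg$age_beta_total
  e$lo[band] + e$w[band] * stats::qbeta(within, a, b)
}

quantile_rf <- function(u, spec) {
  x <- switch(spec$family,
    normal = stats::qnorm(u, spec$mean, spec$sd),
    lognormal = stats::qlnorm(u, spec$meanlog, spec$sdlog),
    stop("unknown risk-factor family: ", spec$family))
  if (!is.null(spec$min)) x <- pmax(x, spec$min)
  x
}

#' Generate a synthetic SNAP adult population
#'
#' Draws \code{config$size} persons with the joint structure the simulation
#' assumes: categorical demographics matched to the configured marginals,
#' continuous cardiometabolic risk factors linked through a Gaussian copula
#' (age-SBP and BMI-diabetes associations by default), and right-skewed
#' baseline intakes of the nine food categories. Survey weights are 1 for
#' synthetic persons; national expansion is handled by
#' \code{\link{scale_to_national}}. Deterministic for a fixed seed.
#'
#' @param config A \code{\link{population_config}} object.
#' @return A \code{data.frame} of class \code{snap_population} with one row
#'   per person: id, weight, demographics, risk factors, and one intake
#'   column (g/d) per food category.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "snap_pop_config"))
    config <- do.call(population_config, config)
  n <- config$size
  set.seed(config$seed)

  sigma <- config$correlation_spec
  z <- MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  colnames(z) <- colnames(sigma)
  u <- stats::pnorm(z)

  rf <- config$risk_factor_distributions
  age <- quantile_age(u[, "age"], config)
  sbp <- quantile_rf(u[, "sbp"], rf$sbp)
  tc  <- quantile_rf(u[, "total_chol"], rf$total_chol)
  hdl <- quantile_rf(u[, "hdl"], rf$hdl)
  bmi <- quantile_rf(u[, "bmi"], rf$bmi)
  diabetic <- u[, "diabetic"] < rf$diabetic$prevalence
  smoker <- stats::runif(n) < rf$smoker$prevalence

  draw_cat <- function(p) {
    names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
  mt <- config$marginal_targets
  pop <- data.frame(
    id = seq_len(n),
    weight = rep(1, n),
    age = age,
    sex = draw_cat(mt$sex),
    race_ethnicity = draw_cat(mt$race_ethnicity),
    education = draw_cat(mt$education),
    income_poverty_ratio = draw_cat(mt$income_poverty_ratio),
    insurance = draw_cat(mt$insurance),
    sbp = sbp, total_chol = tc, hdl = hdl, bmi = bmi,
    smoker = smoker, diabetic = diabetic,
    stringsAsFactors = FALSE
  )
  cv <- config$diet_cv
  shape <- 1 / cv^2
  for (f in food_categories()) {
    mu <- config$diet_baseline_means[[f]]
    pop[[f]] <- if (mu > 0) stats::rgamma(n, shape = shape,
                                          scale = mu / shape) else rep(0, n)
  }
  attr(pop, "config") <- config
  class(pop) <- c("snap_population", "data.frame")
  pop
}

#' National expansion factors for a simulated population
#'
#' Returns per-person expansion factors so that the weighted simulated
#' population represents \code{national_count} persons. With the default
#' 42,138,000 SNAP participants and 34.5 percent aged 35+, the adult target
#' is 14,537,610 (about 14.5 million).
#'
#' @param population A \code{snap_population} (or any data.frame with a
#'   \code{weight} column).
#' @param national_count Total persons represented (> 0). Default is the
#'   adult SNAP population, \code{42138000 * 0.345}.
#' @return Numeric vector of expansion factors summing to
#'   \code{national_count}.
#' @export
scale_to_national <- function(population, national_count = 42138000 * 0.345) {
  if (NROW(population) == 0) stop("population is empty")
  if (national_count <= 0) stop("national_count must be > 0")
  w <- population$weight
  if (is.null(w)) w <- rep(1, NROW(population))
  national_count * w / sum(w)
}

#' Weighted marginal summary of a population
#'
#' Weighted means (continuous fields) and proportions (categorical fields
#' and age bands) for every person-level field, in long format.
#'
#' @param population A \code{snap_population}.
#' @return A \code{data.frame} with columns \code{variable}, \code{level}
#'   (\code{NA} for continuous means), and \code{value}.
#' @export
summarize_population <- function(population) {
  if (NROW(population) == 0) stop("population is empty")
  w <- population$weight / sum(population$weight)
  rows <- list()
  add <- function(variable, level, value) {
    rows[[length(rows) + 1]] <<- data.frame(variable = variable,
                                            level = level, value = value,
                                            stringsAsFactors = FALSE)
  }
  cont <- c("age", "sbp", "total_chol", "hdl", "bmi", food_categories())
  for (v in cont) add(v, NA_character_, sum(w * population[[v]]))
  add("age", "sd", sqrt(sum(w * population$age^2) -
                          sum(w * population$age)^2))
  bands <- default_marginal_targets()$age_band
  e <- age_band_edges(bands)
  for (k in seq_along(bands)) {
    inb <- population$age >= e$lo[k] &
      (population$age < e$hi[k] | (k == length(bands) &
                                     population$age <= e$hi[k]))
    add("age_band", names(bands)[k], sum(w[inb]))
  }
  for (v in c("sex", "race_ethnicity", "education", "income_poverty_ratio",
              "insurance")) {
    for (lev in sort(unique(population[[v]])))
      add(v, lev, sum(w[population[[v]] == lev]))
  }
  for (v in c("smoker", "diabetic")) add(v, "TRUE", sum(w * population[[v]]))
  ins <- population$insurance
  add("insurance", "medicare_medicaid_or_both",
      sum(w[ins %in% c("medicare", "medicaid", "dual")]))
  do.call(rbind, rows)
}

#' @export
print.snap_population <- function(x, ...) {
  cat("<snap_population> ", nrow(x), " persons\n", sep = "")
  cat("  mean age ", round(stats::weighted.mean(x$age, x$weight), 1),
      ", female ", round(100 * stats::weighted.mean(x$sex == "female",
                                                    x$weight), 1),
      "%, diabetic ", round(100 * stats::weighted.mean(x$diabetic,
                                                       x$weight), 1),
      "%\n", sep = "")
  invisible(x)
}

#' Write / read a population as CSV
#'
#' @param population A \code{snap_population}.
#' @param path File path.
#' @return \code{read_population} returns a \code{snap_population}.
#' @export
write_population <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(pop) <- c("snap_population", "data.frame")
  pop
}
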