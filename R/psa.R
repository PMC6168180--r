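#' Load the probabilistic sensitivity analysis parameter registry
#'
#' One row per uncertain input, with a distribution family (normal,
#' lognormal, gamma, beta, uniform), its two parameters, and truncation
#' bounds. The shipped registry follows standard practice for
#' cost-effectiveness models — lognormal multipliers for relative risks and
#' epidemiologic calibration, (truncated) normal for policy effect sizes,
#' gamma for costs, beta-type for utility decrements — with every
#' distribution centered on the point estimate (multiplier 1).
#'
#' @param path CSV path; defaults to the registry shipped with the package.
#' @return Validated \code{data.frame} with columns \code{parameter},
#'   \code{family}, \code{arg1}, \code{arg2}, \code{lower}, \code{upper}.
#' @export
psa_registry <- function(path = system.file("extdata", "psa_registry.csv",
                                            package = "snapcea")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "family", "arg1", "arg2", "lower", "upper")
  if (!all(need %in% names(x)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  ok <- x$family %in% c("normal", "lognormal", "gamma", "beta", "uniform")
  if (!all(ok))
    stop("unknown distribution family: ",
         paste(unique(x$family[!ok]), collapse = ", "))
  if (any(x$lower > x$upper)) stop("lower bound exceeds upper bound")
  x
}

draw_one <- function(row, max_retries = 1000L) {
  rfun <- switch(row$family,
    normal = function() stats::rnorm(1, row$arg1, row$arg2),
    lognormal = function() stats::rlnorm(1, row$arg1, row$arg2),
    gamma = function() stats::rgamma(1, shape = row$arg1, rate = row$arg2),
    beta = function() stats::rbeta(1, row$arg1, row$arg2),
    uniform = function() stats::runif(1, row$arg1, row$arg2))
  for (i in seq_len(max_retries)) {
    v <- rfun()
    if (v >= row$lower && v <= row$upper) return(v)
  }
  stop("draw for parameter '", row$parameter,
       "' violated its bounds after ", max_retries, " retries")
}

#' Draw one coherent parameter-override set
#'
#' Independent draws across registry rows (using the current RNG state),
#' each respecting its truncation bounds. Degenerate (zero-variance)
#' distributions return the point estimate exactly.
#'
#' @param registry From \code{\link{psa_registry}}.
#' @param max_retries Retries before a bound violation is an error.
#' @return Named list of override values.
#' @export
draw_parameter_set <- function(registry, max_retries = 1000L) {
  out <- lapply(seq_len(nrow(registry)), function(i)
    draw_one(registry[i, ], max_retries))
  names(out) <- registry$parameter
  out
}

apply_psa_overrides <- function(params, overrides) {
  if (!is.null(overrides$risk_calibration))
    params$calibration_multiplier <- params$calibration_multiplier *
      overrides$risk_calibration
  if (!is.null(overrides$state_cost_multiplier)) {
    m <- overrides$state_cost_multiplier
    params$event_costs <- params$event_costs * m
    params$chronic_costs <- params$chronic_costs * m
    params$diabetes_annual_cost <- params$diabetes_annual_cost * m
    params$cvd_death_cost <- params$cvd_death_cost * m
  }
  if (!is.null(overrides$utility_decrement_multiplier)) {
    m <- overrides$utility_decrement_multiplier
    u <- params$utilities
    alive <- !names(u) %in% c("DEAD_CVD", "DEAD_OTHER")
    u[alive] <- pmin(1, pmax(0, 1 - (1 - u[alive]) * m))
    params$utilities <- u
  }
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' Joint Monte-Carlo propagation of parameter uncertainty: each iteration
#' draws one override set from the registry, re-runs the full pipeline
#' (policy effects, risk modifiers, base-case and scenario simulations
#' under common random numbers, costing) on a fixed reduced population,
#' and records incremental QALYs and net costs per scenario and
#' perspective. Summaries use 2.5th/97.5th percentiles with linear
#' interpolation between order statistics.
#'
#' @param population A (typically reduced) \code{snap_population}.
#' @param scenarios List of \code{\link{snap_scenario}} objects.
#' @param n_iter Number of iterations (>= 2).
#' @param seed Integer seed governing all draws.
#' @param horizon Analytic horizon (default 5 years).
#' @param params \code{\link{engine_params}}.
#' @param inputs \code{\link{cost_inputs}}.
#' @param effects Effect-component table.
#' @param rr_table Relative-risk table.
#' @param mediated Mediated-effect spec.
#' @param junk_profile Junk-food profile.
#' @param registry PSA registry.
#' @param perspectives Perspectives to summarize.
#' @return Object of class \code{snap_psa} with per-iteration draws
#'   (\code{draws}: scenario, iteration, \code{delta_qaly}, one net-cost
#'   column per perspective) and \code{summary} statistics.
#' @export
run_psa <- function(population, scenarios = default_scenarios(),
                    n_iter = 100L, seed = 1L, horizon = 5,
                    params = engine_params(), inputs = cost_inputs(),
                    effects = load_effect_components(),
                    rr_table = load_rr_table(),
                    mediated = load_mediated_spec(),
                    junk_profile = load_junk_profile(),
                    registry = psa_registry(),
                    perspectives = c("societal", "govt_adults",
                                     "govt_all")) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  years <- if (identical(horizon, "lifetime"))
    max(1L, as.integer(ceiling(100 - min(population$age)))) else
      as.integer(horizon)
  expansion <- scale_to_national(population)
  rows <- list()
  for (i in seq_len(n_iter)) {
    set.seed(seed + 10000L + i)
    ov <- tryCatch(draw_parameter_set(registry),
                   error = function(e) stop("PSA iteration ", i,
                                            " failed: ",
                                            conditionMessage(e)))
    p_i <- apply_psa_overrides(params, ov)
    # common random numbers across iterations as well as scenarios: with a
    # degenerate registry every iteration reproduces the point estimate
    sim_seed <- seed + 20000L
    base <- simulate_cohort(population, NULL, horizon, p_i, sim_seed,
                            expansion)
    for (sc in scenarios) {
      app <- apply_scenario(population, sc, effects,
                            effect_multiplier =
                              if (is.null(ov$effect_multiplier)) 1 else
                                ov$effect_multiplier)
      mods <- person_modifiers(population, app$changes, rr_table, mediated,
                               junk_profile,
                               rr_log_multiplier =
                                 if (is.null(ov$rr_log_multiplier)) 1 else
                                   ov$rr_log_multiplier)
      sim <- simulate_cohort(population, mods, horizon, p_i, sim_seed,
                             expansion)
      inc <- incremental_outcomes(base, sim)
      am <- if (is.null(ov$admin_cost_multiplier)) 1 else
        ov$admin_cost_multiplier
      fm <- if (is.null(ov$food_spend_multiplier)) 1 else
        ov$food_spend_multiplier
      comp <- list(
        admin = admin_cost(sc$id, inputs, years, am),
        hc_savings = inc$hc_savings,
        food_adults = food_program_cost(sc, inputs, "adults_35plus", years,
                                        base$alive_frac, fm),
        food_all = food_program_cost(sc, inputs, "all_participants", years,
                                     base$alive_frac, fm))
      row <- data.frame(scenario = sc$id, iteration = i,
                        delta_qaly = inc$qalys_gained,
                        stringsAsFactors = FALSE)
      for (p in perspectives)
        row[[paste0("net_cost_", p)]] <- net_cost(p, comp)
      rows[[length(rows) + 1]] <- row
    }
  }
  draws <- do.call(rbind, rows)
  out <- list(draws = draws, n_iter = n_iter, horizon = horizon,
              seed = seed, n = nrow(population),
              perspectives = perspectives)
  out$summary <- summarize_psa(out)
  class(out) <- "snap_psa"
  out
}

#' Summarize PSA draws
#'
#' Median and 95\% uncertainty interval (2.5th/97.5th percentiles, linear
#' interpolation) of incremental QALYs and net cost, the fraction of
#' iterations that are cost-saving, and the fractions with an ICER at or
#' below $50,000 and $150,000 per QALY (cost-saving iterations count as
#' below any threshold), per scenario and perspective.
#'
#' @param psa A \code{snap_psa} (or compatible list with \code{draws}).
#' @return \code{data.frame}.
#' @export
summarize_psa <- function(psa) {
  draws <- psa$draws
  rows <- list()
  for (sc in unique(draws$scenario)) {
    d <- draws[draws$scenario == sc, ]
    for (p in psa$perspectives) {
      nc <- d[[paste0("net_cost_", p)]]
      dq <- d$delta_qaly
      ce <- function(thr) mean((nc < 0 & dq > 0) |
                                 (nc >= 0 & dq > 0 & nc / dq <= thr))
      q <- stats::quantile(nc, c(0.5, 0.025, 0.975), type = 7)
      qq <- stats::quantile(dq, c(0.5, 0.025, 0.975), type = 7)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc, perspective = p,
        dqaly_median = qq[[1]], dqaly_lo = qq[[2]], dqaly_hi = qq[[3]],
        net_cost_median = q[[1]], net_cost_lo = q[[2]],
        net_cost_hi = q[[3]],
        frac_cost_saving = mean(nc < 0 & dq > 0),
        frac_ce_50k = ce(50000), frac_ce_150k = ce(150000),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.snap_psa <- function(x, ...) {
  cat("<snap_psa> ", x$n_iter, " iterations, n = ", x$n,
      ", horizon ", as.character(x$horizon), "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s %-12s cost-saving %5.1f%%  <=150k/QALY %5.1f%%\n",
                s$scenario[i], s$perspective[i],
                100 * s$frac_cost_saving[i], 100 * s$frac_ce_150k[i]))
  invisible(x)
}

#' Cost-effectiveness plane of PSA iterations
#'
#' Scatter of incremental QALYs against incremental (net) cost for one
#' perspective, with the willingness-to-pay threshold line.
#'
#' @param x A \code{snap_psa}.
#' @param perspective Perspective to plot.
#' @param wtp Threshold line, dollars/QALY.
#' @param ... Passed to \code{plot}.
#' @export
plot.snap_psa <- function(x, perspective = "societal", wtp = 150000, ...) {
  d <- x$draws
  col <- match(d$scenario, unique(d$scenario))
  nc <- d[[paste0("net_cost_", perspective)]]
  graphics::plot(d$delta_qaly, nc / 1e9, col = col, pch = 16,
                 cex = 0.6, xlab = "Incremental QALYs",
                 ylab = "Incremental cost ($ billions)",
                 main = paste("CE plane -", perspective), ...)
  graphics::abline(h = 0, col = "grey50")
  graphics::abline(a = 0, b = wtp / 1e9, lty = 2)
  graphics::legend("topleft", legend = unique(d$scenario),
                   col = seq_along(unique(d$scenario)), pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Export PSA iterations for external CE-plane plotting
#'
#' @param psa A \code{snap_psa}.
#' @param path CSV output path.
#' @export
write_ce_plane <- function(psa, path) {
  utils::write.csv(psa$draws, path, row.names = FALSE)
  invisible(path)
}
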