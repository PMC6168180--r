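#' Run the full policy cost-effectiveness analysis
#'
#' End-to-end orchestration: generates (or accepts) a synthetic SNAP adult
#' population, converts each scenario's price instruments into per-person
#' diet shifts and risk modifiers, runs the base case and every scenario
#' through the state-transition engine under common random numbers in a
#' single lifetime pass (recording 5/10/20-year snapshots), accrues
#' program costs, and assembles incremental outcomes, net costs, and ICERs
#' per scenario, horizon, and perspective.
#'
#' @param population A \code{snap_population}, or \code{NULL} to generate
#'   one of size \code{pop_size} from seed \code{seed}.
#' @param pop_size Population size when generating.
#' @param scenarios List of \code{\link{snap_scenario}} objects.
#' @param horizons Subset of \code{c(5, 10, 20, "lifetime")}.
#' @param seed Integer seed (population uses \code{seed}, event draws use
#'   \code{seed + 1}).
#' @param params \code{\link{engine_params}}.
#' @param inputs \code{\link{cost_inputs}}.
#' @param effects,rr_table,mediated,junk_profile Parameter tables
#'   (shipped defaults).
#' @param perspectives Accounting perspectives for the CEA table.
#' @return Object of class \code{snap_cea}: \code{cea} (scenario x horizon
#'   x perspective table), \code{outcomes} (incremental health outcomes),
#'   \code{sims} (the \code{snap_sim} objects), the population, and a run
#'   manifest.
#' @export
snap_cea <- function(population = NULL, pop_size = 20000,
                     scenarios = default_scenarios(),
                     horizons = list(5, 10, 20, "lifetime"),
                     seed = 1L, params = engine_params(),
                     inputs = cost_inputs(),
                     effects = load_effect_components(),
                     rr_table = load_rr_table(),
                     mediated = load_mediated_spec(),
                     junk_profile = load_junk_profile(),
                     perspectives = c("societal", "govt_adults",
                                      "govt_all")) {
  if (is.null(population))
    population <- generate_population(population_config(pop_size,
                                                        seed = seed))
  horizons <- lapply(horizons, function(h)
    if (identical(h, "lifetime")) "lifetime" else as.numeric(h))
  numeric_h <- unlist(Filter(is.numeric, horizons))
  run_h <- if ("lifetime" %in% horizons) "lifetime" else max(numeric_h)
  snap_years <- setdiff(numeric_h,
                        if (is.numeric(run_h)) run_h else numeric())
  sim_seed <- seed + 1L
  expansion <- scale_to_national(population)

  base <- simulate_cohort(population, NULL, run_h, params, sim_seed,
                          expansion, snapshot_years = snap_years)
  sims <- list(base = base)
  out_rows <- list()
  cea_rows <- list()
  for (sc in scenarios) {
    app <- apply_scenario(population, sc, effects)
    mods <- person_modifiers(population, app$changes, rr_table, mediated,
                             junk_profile)
    sim <- simulate_cohort(population, mods, run_h, params, sim_seed,
                           expansion, snapshot_years = snap_years)
    sims[[sc$id]] <- sim
    for (h in horizons) {
      inc <- incremental_outcomes(base, sim, h)
      years <- if (identical(h, "lifetime")) base$years else h
      comp <- list(
        admin = admin_cost(sc$id, inputs, years),
        hc_savings = inc$hc_savings,
        food_adults = food_program_cost(sc, inputs, "adults_35plus",
                                        years, base$alive_frac),
        food_all = food_program_cost(sc, inputs, "all_participants",
                                     years, base$alive_frac),
        qalys_gained = inc$qalys_gained)
      out_rows[[length(out_rows) + 1]] <-
        cbind(data.frame(scenario = sc$id, stringsAsFactors = FALSE), inc,
              data.frame(admin_cost = comp$admin,
                         food_cost_adults = comp$food_adults,
                         food_cost_all = comp$food_all))
      ct <- cea_from_components(comp, perspectives)
      ct <- cbind(data.frame(scenario = sc$id,
                             horizon = as.character(h),
                             qalys_gained = inc$qalys_gained,
                             stringsAsFactors = FALSE), ct)
      cea_rows[[length(cea_rows) + 1]] <- ct
    }
  }
  res <- list(cea = do.call(rbind, cea_rows),
              outcomes = do.call(rbind, out_rows),
              sims = sims, population = population,
              manifest = list(seed = seed, sim_seed = sim_seed,
                              pop_size = nrow(population),
                              horizons = horizons,
                              scenarios = vapply(scenarios, `[[`,
                                                 character(1), "id"),
                              package_version =
                                as.character(utils::packageVersion("snapcea")),
                              r_version = R.version.string,
                              timestamp = format(Sys.time())))
  class(res) <- "snap_cea"
  res
}

#' @export
print.snap_cea <- function(x, ...) {
  cat("<snap_cea> ", x$manifest$pop_size, " simulated persons, scenarios: ",
      paste(x$manifest$scenarios, collapse = ", "), "\n\n", sep = "")
  o <- x$outcomes
  for (i in seq_len(nrow(o)))
    cat(sprintf(
      "  %-20s %-8s events averted %8s  QALYs gained %9s  HC savings $%6.2fB\n",
      o$scenario[i], o$horizon[i],
      format(round(o$cvd_events_averted[i]), big.mark = ","),
      format(round(o$qalys_gained[i]), big.mark = ","),
      o$hc_savings[i] / 1e9))
  cat("\n")
  ce <- x$cea
  for (i in seq_len(nrow(ce))) {
    lab <- if (ce$status[i] == "cost_saving")
      sprintf("Saving ($%.2fB)", -ce$net_cost[i] / 1e9)
    else if (is.na(ce$icer[i])) ce$status[i]
    else sprintf("$%s/QALY", format(round(ce$icer[i]), big.mark = ","))
    cat(sprintf("  %-20s %-8s %-12s %s\n", ce$scenario[i], ce$horizon[i],
                ce$perspective[i], lab))
  }
  invisible(x)
}

#' @export
summary.snap_cea <- function(object, ...) {
  list(outcomes = object$outcomes, cea = object$cea,
       manifest = object$manifest)
}

#' Write result tables to a directory
#'
#' Writes the cost-effectiveness table, incremental outcomes, stratified
#' lifetime outcomes (age band, sex, race/ethnicity, education,
#' insurance), and a plain-text run manifest.
#'
#' @param x A \code{snap_cea} result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$cea, file.path(dir, "cea_table.csv"),
                   row.names = FALSE)
  utils::write.csv(x$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  base <- x$sims$base
  for (sc in setdiff(names(x$sims), "base")) {
    for (by in c("age_band", "sex", "race_ethnicity", "education",
                 "insurance")) {
      st <- stratified_outcomes(base, x$sims[[sc]], x$population, by)
      st <- cbind(data.frame(scenario = sc, stratum_type = by,
                             stringsAsFactors = FALSE), st)
      path <- file.path(dir, paste0("strata_", sc, "_", by, ".csv"))
      utils::write.csv(st, path, row.names = FALSE)
    }
  }
  mf <- x$manifest
  writeLines(c(paste0("seed: ", mf$seed),
               paste0("sim_seed: ", mf$sim_seed),
               paste0("pop_size: ", mf$pop_size),
               paste0("scenarios: ", paste(mf$scenarios, collapse = ", ")),
               paste0("horizons: ", paste(unlist(mf$horizons),
                                          collapse = ", ")),
               paste0("package_version: ", mf$package_version),
               paste0("r_version: ", mf$r_version),
               paste0("timestamp: ", mf$timestamp)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
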