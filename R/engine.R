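# Simulation engine: orchestrates the daily loop — supply step, service
# agents, each household's decision cycle and execution, end-of-day
# consumption — and emits the replayable event log.

#' Run a full shortage simulation
#'
#' Executes the daily loop over the scenario horizon. Each day: scheduled
#' policy events are applied/expired, the supply chain advances, the food
#' bank serves households that have run out, the health system and policy
#' program react to shortage severity, every household takes one decision
#' (theory agents via the full belief-update cycle, control agents via the
#' fixed tree) at its first work-free hour, and supply is consumed
#' overnight. The run is a pure function of `(configs, seed)`: identical
#' inputs reproduce the log byte for byte.
#'
#' @param scenario_config scenario configuration
#'   (see [default_scenario_config()]).
#' @param population_config population configuration
#'   (see [default_population_config()]).
#' @param seed integer root seed.
#' @return a `framesim_eventlog`: one row per household per day with tick,
#'   action, outcome, post-action supply and (for theory agents) a belief
#'   snapshot. Attributes `households_initial` and `households_final` carry
#'   the population state for audit.
#' @export
#' @examples
#' \donttest{
#' log <- run_simulation(seed = 1)
#' table(log$action)
#' }
run_simulation <- function(scenario_config = default_scenario_config(),
                           population_config = default_population_config(),
                           seed = 1L) {
  scenario <- make_scenario(scenario_config, seed)
  chain <- init_chain(scenario)
  households <- make_population(scenario, population_config, seed)
  households_initial <- households
  horizon <- scenario$calendar$horizon_days
  cutoffs <- population_config$urgency_cutoffs
  trigger <- scenario$crisis$severity_trigger %||% 0.3

  rows <- vector("list", horizon * length(households))
  ledger_days <- vector("list", horizon)
  ri <- 0L
  for (day in seq_len(horizon)) {
    chain$broadcast_today <- FALSE
    for (ev in scenario$policy_events) {
      if (ev$start_day == day) chain <- apply_policy(chain, ev)
      if (ev$end_day == day - 1L) chain <- expire_policy(chain, ev)
    }
    step <- step_supply(chain, day)
    chain <- step$chain
    fb <- foodbank_step(chain, households, day,
                        scenario$crisis$emergency_days %||% 2)
    chain <- fb$chain; households <- fb$households
    hs <- health_system_step(chain, households, day, trigger)
    chain <- hs$chain; households <- hs$households
    chain <- policy_step(chain, day, trigger)

    hours <- vapply(households, decision_hour, numeric(1))
    ord <- names(households)[order(hours, names(households))]
    for (id in ord) {
      hh <- households[[id]]
      hour <- decision_hour(hh)
      hh$can_shop_today <- hour >= 8 && hour < 21  # store hours overlap
      env <- list(chain = chain, scenario = scenario, day = day, hour = hour)
      if (hh$condition == "theory") {
        cues <- observe(hh, env, households, population_config)
        hh$beliefs <- update_beliefs(hh$beliefs, cues,
                                     kappa = population_config$kappa)
        weighted <- apply_trait_modifiers(hh$beliefs, hh$traits)
        scores <- compute_intentions(weighted, cues, hh, cutoffs = cutoffs)
        scores <- add_bounded_noise(scores,
                                    hash_seed(seed, "noise", id, day),
                                    population_config$epsilon)
        action <- select_action(scores)
      } else {
        action <- baseline_decide(hh, env, cutoffs)
      }
      households[[id]] <- hh
      ex <- execute_action(hh, action, env, households, population_config,
                           seed)
      chain <- ex$chain
      households <- ex$households
      hh <- households[[id]]
      ri <- ri + 1L
      bl <- if (hh$condition == "theory") hh$beliefs
            else stats::setNames(rep(NA_real_, 7), BELIEF_NAMES)
      rows[[ri]] <- data.frame(
        tick = daytime_tick(day, hour, scenario$calendar$ticks_per_day),
        day = day, hour = hour, agent_id = id, condition = hh$condition,
        action = action, success = ex$outcome$success,
        reason = ex$outcome$reason, units = ex$outcome$units,
        target = ex$outcome$target,
        supply_days_after = hh$supply_days,
        as.list(stats::setNames(bl, paste0("belief_", names(bl)))),
        stringsAsFactors = FALSE)
    }
    households <- lapply(households, consume_daily)
    if (!ledger_balanced(chain))
      stopf("supply ledger out of balance after day %d", day,
            class = "framesim_internal_error")
    ledger_days[[day]] <- data.frame(day = day,
                                     as.list(supply_ledger(chain)))
  }
  log <- do.call(rbind, rows[seq_len(ri)])
  rownames(log) <- NULL
  structure(log,
            class = c("framesim_eventlog", "data.frame"),
            seed = as.integer(seed),
            horizon = horizon,
            ledger = supply_ledger(chain),
            ledger_daily = do.call(rbind, ledger_days),
            households_initial = households_initial,
            households_final = households)
}

#' Per-day supply ledger of a run
#'
#' @param log a `framesim_eventlog`.
#' @return data frame with one row per day and the cumulative ledger
#'   fields.
#' @export
ledger_history <- function(log) attr(log, "ledger_daily")

#' Export the per-day supply ledger as CSV
#'
#' @param log a `framesim_eventlog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_supply_ledger <- function(log, path) {
  utils::write.csv(ledger_history(log), path, row.names = FALSE)
  invisible(path)
}

#' Export an event log as JSON lines
#'
#' @param log a `framesim_eventlog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eventlog <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(as.character(jsonlite::toJSON(as.list(log[i, ]),
                                             auto_unbox = TRUE, digits = NA,
                                             na = "null")), con)
  invisible(path)
}
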