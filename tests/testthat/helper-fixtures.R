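# Fixtures built in code: no data files.

# Scenario in which every store shelf stays empty for the whole horizon:
# no initial stock, no buffer, no production, no relief events.
empty_store_config <- function() {
  cfg <- default_scenario_config()
  cfg$pois$initial_stock_fraction <- 0
  cfg$supply$buffer_stock <- 0L
  cfg$supply$manufacturers <- lapply(cfg$supply$manufacturers, function(m) {
    m$daily_production <- 0L
    m
  })
  cfg$policy_events <- list()
  cfg
}

small_population <- function(n = 30L, condition = "theory") {
  pc <- default_population_config()
  pc$n_households <- as.integer(n)
  pc$condition <- condition
  pc
}

# A minimal household record for unit-level agent tests.
mk_household <- function(id = "hh_001", zone = "75216", supply = 5,
                         infants = 1L, vehicle = TRUE, wic = FALSE,
                         budget = 60, stress = 0.5, ties = character(0),
                         condition = "theory") {
  list(household_id = id, zone_id = zone, x = 1, y = 1,
       infants = infants, supply_days = supply, has_vehicle = vehicle,
       wic = wic, snap = FALSE, income_tier = "middle",
       work_window = c(NA, NA), stress = stress, budget = budget,
       traits = neutral_traits(), beliefs = initial_beliefs(),
       memory = data.frame(day = integer(0), action = character(0),
                           success = logical(0), reason = character(0),
                           stringsAsFactors = FALSE),
       social_ties = ties, condition = condition, can_shop_today = TRUE)
}

neutral_traits <- function(value = 0.5) {
  list(hbm = list(severity_sensitivity = value,
                  susceptibility_sensitivity = value,
                  barrier_weight = value, benefit_weight = value,
                  self_efficacy = value, cue_responsiveness = value),
       tpb = list(attitude = value, subjective_norm_weight = value,
                  perceived_control_base = value),
       sct = list(observational_learning_weight = value,
                  outcome_expectancy = value,
                  social_reinforcement_weight = value))
}

empty_cues <- function() {
  list(declining_supply = FALSE, store_stockout_observed = FALSE,
       transport_limited = FALSE, shortage_broadcast = FALSE,
       peer_success_via_support = FALSE,
       own_failed_strategy = stats::setNames(rep(FALSE, 7),
                                             framesim:::ACTIONS))
}

# Deterministic complete rating table: ratings are an arbitrary but fixed
# function of (rater, vignette, dimension) covering the 1..5 range.
toy_rating_table <- function(n_raters = 5) {
  dims <- frame_dimensions()
  vids <- c(paste0("T", 1:4), paste0("N", 1:4))
  grid <- expand.grid(rater_id = sprintf("r%d", seq_len(n_raters)),
                      vignette_id = vids, dimension = dims,
                      stringsAsFactors = FALSE)
  grid$condition <- ifelse(grepl("^T", grid$vignette_id), "theory",
                           "non_theory")
  ri <- as.integer(factor(grid$rater_id))
  vi <- match(grid$vignette_id, vids)
  ki <- match(grid$dimension, dims)
  grid$rating <- 1 + (ri * 2 + vi * 3 + ki * 5 + (ri * ki) %% 3) %% 5
  as_rating_table(grid[, c("rater_id", "vignette_id", "condition",
                           "dimension", "rating")])
}

# Null rating model used by the calibration experiments: no condition
# effect structure beyond delta, fixed vignette panel (sd 0) because the
# rater-level t-test treats the eight vignettes as fixed.
calibration_model <- function(delta = 0) {
  rating_model(condition_effect = delta,
               dimension_effects = c(0, 0, 0, 0),
               interaction_effects = matrix(0, 2, 4,
                                            dimnames = list(
                                              c("non_theory", "theory"),
                                              NULL)),
               rater_sd = 0.3, vignette_sd = 0, residual_sd = 1)
}
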