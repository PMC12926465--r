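# Household agents.
#
# Theory-based agents run a Belief-Desire-Intention decision cycle in which
# environmental and social cues update beliefs drawn from the Health Belief
# Model (perceived severity/susceptibility, barriers/benefits), the Theory
# of Planned Behavior (perceived behavioral control, subjective norms) and
# Social Cognitive Theory (social outcome expectancy); stable traits weight
# the beliefs, a linear rule scores the seven available strategies, bounded
# noise is added and the argmax is executed. Rule-based control agents use
# a fixed urgency decision tree with no beliefs, no social influence and no
# adaptation. Three service agents (food bank, health system, policy
# program) respond to the day's shortage severity.

ACTIONS <- c("visit_store", "contact_wic_vendor", "seek_social_help",
             "search_online", "travel_far_store", "visit_food_bank", "wait")

BELIEF_NAMES <- c("perceived_severity", "perceived_susceptibility",
                  "perceived_barriers", "perceived_benefits",
                  "perceived_behavioral_control", "subjective_norm",
                  "outcome_expectancy_social")

#' Initial belief state
#' @return named numeric vector over the seven belief constructs, in [0,1].
#' @export
initial_beliefs <- function() {
  c(perceived_severity = 0.3, perceived_susceptibility = 0.3,
    perceived_barriers = 0.4, perceived_benefits = 0.5,
    perceived_behavioral_control = 0.6, subjective_norm = 0.4,
    outcome_expectancy_social = 0.3)
}

#' Default household population configuration
#'
#' @return list with population size, condition flag (`"theory"` or
#'   `"baseline"`), tie count, initial supply range (days), trait
#'   distribution (Beta shape parameters), belief-update gain `kappa`,
#'   intention noise bound `epsilon`, per-trip purchase cap, and the
#'   social-help / online-purchase parameters.
#' @export
default_population_config <- function() {
  list(
    n_households = 100L,
    condition = "theory",
    n_ties = 3L,
    initial_supply = c(2, 8),
    trait_shape = c(2, 2),
    kappa = 0.1,
    epsilon = 0.05,
    per_trip_cap = 3L,
    surplus_threshold = 4,
    social_help_logit = c(-1, 0.8),
    online_success_p = 0.15,
    online_price_markup = 1.3,
    budget_by_tier = c(low = 40, middle = 70, high = 120),
    declining_supply_days = 5,
    urgency_cutoffs = c(critical = 2, moderate = 5)
  )
}

# Work window (busy hours) by schedule type.
work_window <- function(schedule) {
  switch(schedule, day = c(9, 17), evening = c(14, 22), flexible = c(NA, NA))
}

# First work-free hour from 9 (when most services open) onwards: the
# agent's daily decision hour. Day-shift caregivers are only free in the
# evening, which is exactly the access barrier the crisis-extended service
# hours relieve.
decision_hour <- function(household) {
  w <- household$work_window
  for (h in 9:20) {
    if (is.na(w[1]) || h < w[1] || h >= w[2]) return(h)
  }
  21L
}

#' Build a household population on a scenario
#'
#' Households are assigned to zones round-robin, placed uniformly inside
#' their zone's bounding box, and given attributes sampled from the zone's
#' configured distributions (vehicle ownership, WIC/SNAP participation,
#' income tier, employment schedule, infants, stress). Trait profiles are
#' Beta-distributed in [0,1] and fixed for the whole scenario. Every
#' stochastic draw uses a substream hashed from `(seed, household_id)`, so
#' the population is reproducible and order-independent.
#'
#' @param scenario a `framesim_scenario`.
#' @param config population configuration, see
#'   [default_population_config()].
#' @param seed integer root seed.
#' @return list of household records.
#' @export
make_population <- function(scenario, config = default_population_config(),
                            seed = 1L) {
  n <- config$n_households
  ids <- sprintf("hh_%03d", seq_len(n))
  zone_ids <- scenario$zones$zone_id[(seq_len(n) - 1L) %% nrow(scenario$zones) + 1L]
  sh <- config$trait_shape
  households <- vector("list", n)
  for (i in seq_len(n)) {
    zid <- zone_ids[i]
    z <- scenario$zones[scenario$zones$zone_id == zid, ]
    att <- scenario$zone_attributes[[zid]]
    hh <- with_seed(hash_seed(seed, "household", ids[i]), {
      tier <- sample(names(att$income_tier_probs), 1,
                     prob = att$income_tier_probs)
      schedule <- sample(names(att$schedule_probs), 1,
                         prob = att$schedule_probs)
      infants <- as.integer(sample(names(att$infants_probs), 1,
                                   prob = att$infants_probs))
      list(
        household_id = ids[i], zone_id = zid,
        x = stats::runif(1, z$xmin, z$xmax),
        y = stats::runif(1, z$ymin, z$ymax),
        infants = infants,
        supply_days = stats::runif(1, config$initial_supply[1],
                                   config$initial_supply[2]),
        has_vehicle = stats::runif(1) < att$vehicle_p,
        wic = stats::runif(1) < att$wic_p,
        snap = stats::runif(1) < att$snap_p,
        income_tier = tier,
        work_window = work_window(schedule),
        stress = clamp(stats::rnorm(1, att$stress_mean, att$stress_sd)),
        budget = config$budget_by_tier[[tier]],
        traits = list(
          hbm = list(severity_sensitivity = stats::rbeta(1, sh[1], sh[2]),
                     susceptibility_sensitivity = stats::rbeta(1, sh[1], sh[2]),
                     barrier_weight = stats::rbeta(1, sh[1], sh[2]),
                     benefit_weight = stats::rbeta(1, sh[1], sh[2]),
                     self_efficacy = stats::rbeta(1, sh[1], sh[2]),
                     cue_responsiveness = stats::rbeta(1, sh[1], sh[2])),
          tpb = list(attitude = stats::rbeta(1, sh[1], sh[2]),
                     subjective_norm_weight = stats::rbeta(1, sh[1], sh[2]),
                     perceived_control_base = stats::rbeta(1, sh[1], sh[2])),
          sct = list(observational_learning_weight = stats::rbeta(1, sh[1], sh[2]),
                     outcome_expectancy = stats::rbeta(1, sh[1], sh[2]),
                     social_reinforcement_weight = stats::rbeta(1, sh[1], sh[2]))
        ),
        beliefs = initial_beliefs(),
        memory = data.frame(day = integer(0), action = character(0),
                            success = logical(0), reason = character(0),
                            stringsAsFactors = FALSE),
        condition = config$condition
      )
    })
    households[[i]] <- hh
  }
  # social ties: same-zone peers, hashed substream per household
  by_zone <- split(ids, zone_ids)
  for (i in seq_len(n)) {
    peers <- setdiff(by_zone[[zone_ids[i]]], ids[i])
    k <- min(config$n_ties, length(peers))
    households[[i]]$social_ties <- if (k > 0)
      with_seed(hash_seed(seed, "ties", ids[i]), sort(sample(peers, k)))
    else character(0)
  }
  names(households) <- ids
  households
}

# ---- perception -------------------------------------------------------------

#' Observe the environment and social context
#'
#' Builds the agent's cue set from information genuinely available to it:
#' its own inventory, its own memory of recent attempts, global broadcasts,
#' transit availability, and the recent outcomes of its social ties.
#'
#' @param household a household record.
#' @param env list with `chain`, `scenario`, `day`, `hour`.
#' @param households full population list (for social ties).
#' @param config population configuration (cue thresholds).
#' @return a cue set: flags plus a named `own_failed_strategy` vector.
#' @export
observe <- function(household, env, households,
                    config = default_population_config()) {
  mem <- household$memory
  recent <- mem[mem$day >= env$day - 3, , drop = FALSE]
  failed2 <- vapply(ACTIONS, function(a) {
    ma <- mem[mem$action == a, , drop = FALSE]
    nrow(ma) >= 2 && !any(utils::tail(ma$success, 2))
  }, logical(1))
  peer_success <- FALSE
  for (tid in household$social_ties) {
    tm <- households[[tid]]$memory
    hit <- tm$day >= env$day - 1 & tm$success &
      tm$action %in% c("seek_social_help", "visit_food_bank",
                       "contact_wic_vendor")
    if (any(hit)) { peer_success <- TRUE; break }
  }
  list(
    declining_supply = household$supply_days <= config$declining_supply_days,
    store_stockout_observed = any(
      recent$action %in% c("visit_store", "travel_far_store") &
        !recent$success & recent$reason == "stockout"),
    transport_limited = !household$has_vehicle &&
      !transit_in_service(env$scenario, env$hour),
    shortage_broadcast = isTRUE(env$chain$broadcast_today),
    peer_success_via_support = peer_success,
    own_failed_strategy = failed2
  )
}

# ---- belief updating --------------------------------------------------------

#' Update beliefs from cues
#'
#' Bounded additive update with per-cue gain `kappa`, clamped to [0,1].
#' Directions: declining supply raises severity and susceptibility; an
#' observed stockout lowers perceived behavioral control; limited transport
#' raises barriers and lowers control; a shortage broadcast raises the
#' subjective norm and severity; peer success through support channels
#' raises social outcome expectancy and the subjective norm; one's own
#' repeatedly failed strategies shift the benefit/barrier balance against
#' acting the same way again.
#'
#' @param prior named belief vector (see [initial_beliefs()]).
#' @param cues cue set from [observe()].
#' @param social_inputs unused hook for richer social signals.
#' @param kappa per-cue gain (default 0.1).
#' @return updated belief vector in [0,1].
#' @export
update_beliefs <- function(prior, cues, social_inputs = NULL, kappa = 0.1) {
  b <- prior
  if (isTRUE(cues$declining_supply)) {
    b["perceived_severity"] <- b["perceived_severity"] + kappa
    b["perceived_susceptibility"] <- b["perceived_susceptibility"] + kappa
  }
  if (isTRUE(cues$store_stockout_observed))
    b["perceived_behavioral_control"] <- b["perceived_behavioral_control"] - kappa
  if (isTRUE(cues$transport_limited)) {
    b["perceived_barriers"] <- b["perceived_barriers"] + kappa
    b["perceived_behavioral_control"] <- b["perceived_behavioral_control"] - kappa
  }
  if (isTRUE(cues$shortage_broadcast)) {
    b["subjective_norm"] <- b["subjective_norm"] + kappa
    b["perceived_severity"] <- b["perceived_severity"] + kappa
  }
  if (isTRUE(cues$peer_success_via_support)) {
    b["outcome_expectancy_social"] <- b["outcome_expectancy_social"] + kappa
    b["subjective_norm"] <- b["subjective_norm"] + kappa
  }
  if (any(cues$own_failed_strategy)) {
    b["perceived_barriers"] <- b["perceived_barriers"] + kappa
    b["perceived_benefits"] <- b["perceived_benefits"] - kappa
  }
  clamp(b)
}

#' Modulate beliefs by stable traits
#'
#' Elementwise product of each belief with its matching trait sensitivity:
#' severity and susceptibility by the HBM sensitivities, barriers and
#' benefits by the HBM weights, behavioral control by the TPB control base,
#' the subjective norm by the TPB norm weight, and social outcome
#' expectancy by the SCT observational-learning weight.
#'
#' @param beliefs named belief vector.
#' @param traits a trait profile (`hbm` / `tpb` / `sct` lists, entries in
#'   [0,1]).
#' @return weighted belief vector in [0,1].
#' @export
apply_trait_modifiers <- function(beliefs, traits) {
  sens <- c(
    perceived_severity = traits$hbm$severity_sensitivity,
    perceived_susceptibility = traits$hbm$susceptibility_sensitivity,
    perceived_barriers = traits$hbm$barrier_weight,
    perceived_benefits = traits$hbm$benefit_weight,
    perceived_behavioral_control = traits$tpb$perceived_control_base,
    subjective_norm = traits$tpb$subjective_norm_weight,
    outcome_expectancy_social = traits$sct$observational_learning_weight)
  clamp(beliefs * sens[names(beliefs)])
}

# ---- intention formation ----------------------------------------------------

#' Default intention weight matrix
#'
#' Linear weights from the seven weighted beliefs to the seven strategies.
#' Signs follow the construct mapping: threat perceptions drive all active
#' strategies, barriers penalize travel-based options and reward waiting,
#' behavioral control enables store trips and far travel, and norms plus
#' social outcome expectancy drive the support-seeking strategies.
#' Magnitudes are package defaults, overridable per call.
#'
#' @return 7 x 7 numeric matrix (actions x beliefs).
#' @export
default_intention_weights <- function() {
  W <- rbind(
    visit_store        = c(0.30, 0.20, -0.20, 0.30, 0.30, 0.00, 0.00),
    contact_wic_vendor = c(0.20, 0.10, 0.00, 0.20, 0.10, 0.20, 0.10),
    seek_social_help   = c(0.20, 0.10, 0.10, 0.10, 0.00, 0.30, 0.40),
    search_online      = c(0.20, 0.10, 0.00, 0.20, 0.20, 0.00, 0.10),
    travel_far_store   = c(0.30, 0.20, -0.40, 0.20, 0.40, 0.00, 0.00),
    visit_food_bank    = c(0.20, 0.10, 0.10, 0.10, 0.00, 0.30, 0.30),
    wait               = c(-0.30, -0.10, 0.30, -0.10, 0.00, -0.10, 0.00))
  colnames(W) <- BELIEF_NAMES
  W
}

#' Urgency tier from days of supply
#' @param supply_days days of formula supply remaining.
#' @param cutoffs named vector `c(critical = 2, moderate = 5)`.
#' @return `"critical"`, `"moderate"` or `"low"`.
#' @export
urgency_tier <- function(supply_days, cutoffs = c(critical = 2, moderate = 5)) {
  if (supply_days <= cutoffs[["critical"]]) "critical"
  else if (supply_days <= cutoffs[["moderate"]]) "moderate"
  else "low"
}

#' Score the seven strategies
#'
#' Linear combination of the weighted beliefs (via the intention weight
#' matrix), an urgency bonus on the active strategies, cue-driven bonuses
#' (peer success boosts support channels scaled by the SCT reinforcement
#' trait; broadcasts raise all active strategies scaled by cue
#' responsiveness), penalties for strategies the agent itself has seen fail
#' repeatedly, a stress-proportional pull toward longer trips, and hard
#' feasibility gates (-Inf): WIC contact without enrollment, far travel
#' with neither vehicle nor transit, store trips when no work-free shopping
#' hour exists.
#'
#' @param weighted_beliefs output of [apply_trait_modifiers()].
#' @param cues cue set from [observe()].
#' @param household household record (urgency, stress, traits, gates).
#' @param weights intention weight matrix.
#' @param cutoffs urgency tier cutoffs.
#' @return named score vector over the seven strategies.
#' @export
compute_intentions <- function(weighted_beliefs, cues, household,
                               weights = default_intention_weights(),
                               cutoffs = c(critical = 2, moderate = 5)) {
  scores <- drop(weights %*% weighted_beliefs[colnames(weights)])
  names(scores) <- rownames(weights)
  scores["wait"] <- scores["wait"] + 0.15

  tier <- urgency_tier(household$supply_days, cutoffs)
  u <- c(critical = 1, moderate = 0.5, low = 0)[[tier]]
  bonus <- c(visit_store = 0.35, contact_wic_vendor = 0.25,
             seek_social_help = 0.30, search_online = 0.20,
             travel_far_store = 0.25, visit_food_bank = 0.30, wait = 0)
  scores <- scores + u * bonus

  tr <- household$traits
  active <- setdiff(ACTIONS, "wait")
  scores[active] <- scores[active] + 0.10 * (tr$tpb$attitude %||% 0.5)
  if (isTRUE(cues$peer_success_via_support)) {
    boost <- 0.20 * (0.5 + (tr$sct$social_reinforcement_weight %||% 0.5))
    sup <- c("seek_social_help", "visit_food_bank", "contact_wic_vendor")
    scores[sup] <- scores[sup] + boost
  }
  if (isTRUE(cues$shortage_broadcast)) {
    scores[active] <- scores[active] +
      0.10 * (0.5 + (tr$hbm$cue_responsiveness %||% 0.5))
  }
  if (isTRUE(cues$store_stockout_observed))
    scores["visit_store"] <- scores["visit_store"] - 0.15
  fails <- cues$own_failed_strategy
  if (!is.null(fails)) scores[names(fails)[fails]] <-
      scores[names(fails)[fails]] - 0.30
  # caregiver stress pulls toward longer trips once the need is pressing
  scores["travel_far_store"] <- scores["travel_far_store"] +
    0.20 * u * (household$stress %||% 0)

  # feasibility gates
  if (!isTRUE(household$wic)) scores["contact_wic_vendor"] <- -Inf
  if (isTRUE(cues$transport_limited)) scores["travel_far_store"] <- -Inf
  if (isFALSE(household$can_shop_today))
    scores[c("visit_store", "travel_far_store")] <- -Inf
  scores
}

#' Add bounded stochastic variation to intention scores
#'
#' Uniform perturbation on `[-epsilon, epsilon]` per non-gated strategy,
#' drawn from the agent's own seeded substream; gated (-Inf) entries are
#' untouched. With the same seed the perturbation replays exactly.
#'
#' @param scores named score vector.
#' @param seed integer substream seed.
#' @param epsilon noise bound (>= 0, default 0.05).
#' @return perturbed score vector.
#' @export
add_bounded_noise <- function(scores, seed, epsilon = 0.05) {
  stopifnot(epsilon >= 0)
  if (epsilon == 0) return(scores)
  eps <- with_seed(seed, stats::runif(length(scores), -epsilon, epsilon))
  out <- scores + ifelse(is.finite(scores), eps, 0)
  out
}

#' Select the highest-scoring strategy
#'
#' Argmax with exact ties broken by the fixed strategy order
#' (`visit_store` first, `wait` last). If every strategy is gated the
#' agent waits.
#'
#' @param scores named score vector over the seven strategies.
#' @return the chosen action kind (character scalar).
#' @export
select_action <- function(scores) {
  scores <- scores[ACTIONS]
  if (all(!is.finite(scores))) return("wait")
  ACTIONS[which.max(scores)]
}

#' Rule-based control decision tree
#'
#' Fixed heuristics with no beliefs, noise or memory: critically low supply
#' with transport available means a store visit and without transport a
#' request for help; moderate urgency means a store visit if a stocked
#' store is known in the zone, otherwise waiting; low urgency always waits.
#'
#' @param household household record.
#' @param env list with `chain`, `scenario`, `hour`.
#' @param cutoffs urgency tier cutoffs.
#' @return action kind (character scalar).
#' @export
baseline_decide <- function(household, env,
                            cutoffs = c(critical = 2, moderate = 5)) {
  tier <- urgency_tier(household$supply_days, cutoffs)
  transport <- isTRUE(household$has_vehicle) ||
    transit_in_service(env$scenario, env$hour)
  if (tier == "critical") {
    if (transport) "visit_store" else "seek_social_help"
  } else if (tier == "moderate") {
    p <- env$chain$pois
    stocked <- p$kind == "store" & p$zone_id == household$zone_id &
      p$shelf_stock > 0
    if (any(stocked)) "visit_store" else "wait"
  } else "wait"
}

# ---- execution --------------------------------------------------------------

nearest_poi <- function(pois, household, kinds, zone = NULL,
                        exclude_zone = NULL, open_tick = NULL,
                        crisis_active = FALSE) {
  sel <- pois$kind %in% kinds
  if (!is.null(zone)) sel <- sel & pois$zone_id == zone
  if (!is.null(exclude_zone)) sel <- sel & pois$zone_id != exclude_zone
  p <- pois[sel, , drop = FALSE]
  if (!is.null(open_tick) && nrow(p)) {
    keep <- vapply(seq_len(nrow(p)), function(i)
      open_at(p[i, ], open_tick, crisis_active), logical(1))
    p <- p[keep, , drop = FALSE]
  }
  if (!nrow(p)) return(NULL)
  d <- sqrt((p$x - household$x)^2 + (p$y - household$y)^2)
  p[which.min(d), , drop = FALSE]
}

remember <- function(household, day, action, success, reason) {
  household$memory <- utils::tail(rbind(household$memory, data.frame(
    day = day, action = action, success = success, reason = reason,
    stringsAsFactors = FALSE)), 14L)
  household
}

outcome_rec <- function(action, success, reason, units = 0L, target = NA_character_) {
  list(action = action, success = success, reason = reason,
       units = as.integer(units), target = target)
}

# Buy up to `q_desired` units at a selling POI; WIC vouchers first when the
# household is enrolled and the store is authorized, then cash.
buy_at <- function(household, poi, chain, q_desired) {
  stock <- poi$shelf_stock
  if (stock <= 0)
    return(list(household = household, chain = chain,
                outcome = outcome_rec("", FALSE, "stockout", target = poi$poi_id)))
  q_wic <- 0L
  if (isTRUE(household$wic) && isTRUE(poi$wic_authorized))
    q_wic <- min(q_desired, floor(stock * poi$wic_fraction))
  if (q_wic >= 1) {
    chain <- sell_units(chain, poi$poi_id, q_wic)
    household$supply_days <- household$supply_days + q_wic / household$infants
    return(list(household = household, chain = chain,
                outcome = outcome_rec("", TRUE, "purchased_wic", q_wic,
                                      poi$poi_id)))
  }
  afford <- floor(household$budget / poi$price)
  q <- min(q_desired, stock, afford)
  if (q >= 1) {
    chain <- sell_units(chain, poi$poi_id, q)
    household$budget <- household$budget - q * poi$price
    household$supply_days <- household$supply_days + q / household$infants
    return(list(household = household, chain = chain,
                outcome = outcome_rec("", TRUE, "purchased", q, poi$poi_id)))
  }
  reason <- if (isTRUE(household$wic) && isTRUE(poi$wic_authorized) &&
                afford < 1) "wic_ineligible" else "unaffordable"
  list(household = household, chain = chain,
       outcome = outcome_rec("", FALSE, reason, target = poi$poi_id))
}

#' Execute a selected strategy
#'
#' Applies the strategy against the environment: store and far-store visits
#' purchase up to the per-trip cap (amplified under the panic regime) from
#' open stocked stores, WIC contact requires enrollment and WIC-eligible
#' stock, social help succeeds with probability logistic in the number of
#' ties holding surplus supply, online search succeeds with a configured
#' probability at a price markup, and food banks serve eligible low-supply
#' households during opening hours. Infeasible strategies yield a failure
#' outcome with a reason, never an error, and every outcome is appended to
#' the agent's memory.
#'
#' @param household household record.
#' @param action action kind (one of the seven strategies).
#' @param env list with `chain`, `scenario`, `day`, `hour`.
#' @param households full population list (social transfers mutate peers).
#' @param config population configuration.
#' @param seed root seed (execution draws use a hashed substream).
#' @return list with updated `household`, `chain`, `households`, `outcome`.
#' @export
execute_action <- function(household, action, env, households,
                           config = default_population_config(), seed = 1L) {
  chain <- env$chain
  tick <- daytime_tick(env$day, env$hour,
                       env$scenario$calendar$ticks_per_day)
  crisis <- isTRUE(chain$crisis_active)
  cap <- config$per_trip_cap
  out <- switch(action,
    wait = list(household = household, chain = chain,
                outcome = outcome_rec(action, TRUE, "waited")),
    visit_store = {
      poi <- nearest_poi(chain$pois, household, "store",
                         zone = household$zone_id, open_tick = tick,
                         crisis_active = crisis)
      if (is.null(poi))
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE, "closed"))
      else {
        panic <- panic_state(poi$shelf_stock / poi$baseline_stock,
                             chain$panic_threshold)
        r <- buy_at(household, poi, chain,
                    effective_demand(cap, panic, chain$panic_multiplier))
        r$outcome$action <- action
        r
      }
    },
    travel_far_store = {
      transport <- isTRUE(household$has_vehicle) ||
        transit_in_service(env$scenario, env$hour)
      poi <- nearest_poi(chain$pois, household, "store",
                         exclude_zone = household$zone_id, open_tick = tick,
                         crisis_active = crisis)
      if (!transport)
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE, "no_transport"))
      else if (is.null(poi))
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE, "closed"))
      else {
        panic <- panic_state(poi$shelf_stock / poi$baseline_stock,
                             chain$panic_threshold)
        r <- buy_at(household, poi, chain,
                    effective_demand(cap, panic, chain$panic_multiplier))
        r$outcome$action <- action
        r
      }
    },
    contact_wic_vendor = {
      if (!isTRUE(household$wic))
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE, "not_enrolled"))
      else {
        poi <- nearest_poi(chain$pois, household,
                           c("wic_vendor", "store"), open_tick = tick,
                           crisis_active = crisis)
        if (!is.null(poi) && !isTRUE(poi$wic_authorized)) poi <- NULL
        if (is.null(poi))
          list(household = household, chain = chain,
               outcome = outcome_rec(action, FALSE, "closed"))
        else {
          r <- buy_at(household, poi, chain, cap)
          r$outcome$action <- action
          r
        }
      }
    },
    seek_social_help = {
      surplus <- vapply(household$social_ties, function(tid)
        households[[tid]]$supply_days > config$surplus_threshold, logical(1))
      n_sur <- sum(surplus)
      p <- stats::plogis(config$social_help_logit[1] +
                           config$social_help_logit[2] * n_sur)
      ok <- with_seed(hash_seed(seed, "social", household$household_id,
                                env$day), stats::runif(1) < p)
      if (ok && n_sur > 0) {
        donor <- household$social_ties[surplus][1]
        gift <- 2
        households[[donor]]$supply_days <-
          max(0, households[[donor]]$supply_days -
                gift / households[[donor]]$infants)
        household$supply_days <- household$supply_days +
          gift / household$infants
        list(household = household, chain = chain, households = households,
             outcome = outcome_rec(action, TRUE, "peer_transfer", gift, donor))
      } else if (ok) {
        # informal help without a surplus tie: a single unit found via the
        # wider community network (outside the regional ledger)
        household$supply_days <- household$supply_days + 1 / household$infants
        list(household = household, chain = chain,
             outcome = outcome_rec(action, TRUE, "community_help", 1L))
      } else {
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE, "no_help"))
      }
    },
    search_online = {
      price <- chain$pois$base_price[1] * config$online_price_markup
      ok <- with_seed(hash_seed(seed, "online", household$household_id,
                                env$day),
                      stats::runif(1) < config$online_success_p)
      q <- min(cap, floor(household$budget / price))
      if (ok && q >= 1) {
        household$budget <- household$budget - q * price
        household$supply_days <- household$supply_days + q / household$infants
        list(household = household, chain = chain,
             outcome = outcome_rec(action, TRUE, "delivered", q))
      } else {
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE,
                                   if (q < 1) "unaffordable" else "sold_out"))
      }
    },
    visit_food_bank = {
      poi <- nearest_poi(chain$pois, household, "food_bank",
                         open_tick = tick, crisis_active = crisis)
      if (is.null(poi))
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE, "closed"))
      else if (household$supply_days > config$urgency_cutoffs[["moderate"]])
        list(household = household, chain = chain,
             outcome = outcome_rec(action, FALSE, "not_eligible"))
      else {
        u <- min(2L * household$infants, poi$shelf_stock)
        if (u < 1)
          list(household = household, chain = chain,
               outcome = outcome_rec(action, FALSE, "stockout",
                                     target = poi$poi_id))
        else {
          chain <- distribute_units(chain, poi$poi_id, u)
          household$supply_days <- household$supply_days +
            u / household$infants
          list(household = household, chain = chain,
               outcome = outcome_rec(action, TRUE, "food_bank", u,
                                     poi$poi_id))
        }
      }
    },
    stopf("unknown action '%s'", action)
  )
  out$household <- remember(out$household, env$day, action,
                            out$outcome$success, out$outcome$reason)
  if (is.null(out$households)) out$households <- households
  out$households[[out$household$household_id]] <- out$household
  out
}

#' Daily formula consumption
#'
#' Supply decreases by one day-equivalent per infant, floored at zero; a
#' household at zero is critically low and becomes a priority for the
#' service agents.
#'
#' @param household household record.
#' @return updated household (with logical `critical` field).
#' @export
consume_daily <- function(household) {
  household$supply_days <- max(0, household$supply_days - household$infants)
  household$critical <- household$supply_days <= 0
  household
}

# ---- service agents ---------------------------------------------------------

#' Food bank emergency distribution
#'
#' Households that have run out of formula receive emergency units (default
#' two days of supply) from the nearest stocked food bank, neediest first
#' (lowest supply, then most infants), while stock lasts.
#'
#' @param chain a `framesim_chain`.
#' @param households population list.
#' @param day simulation day.
#' @param emergency_days days of supply per emergency distribution.
#' @return list with `chain`, `households`, `distributions` data frame.
#' @export
foodbank_step <- function(chain, households, day, emergency_days = 2) {
  supply <- vapply(households, `[[`, numeric(1), "supply_days")
  infants <- vapply(households, `[[`, numeric(1), "infants")
  needy <- names(households)[supply <= 0]
  needy <- needy[order(supply[needy], -infants[needy])]
  dist <- list()
  for (id in needy) {
    hh <- households[[id]]
    fb <- nearest_poi(chain$pois[chain$pois$shelf_stock > 0, , drop = FALSE],
                      hh, "food_bank")
    if (is.null(fb)) next
    u <- as.integer(min(emergency_days * hh$infants, fb$shelf_stock))
    if (u < 1) next
    chain <- distribute_units(chain, fb$poi_id, u)
    households[[id]]$supply_days <- hh$supply_days + u / hh$infants
    dist[[length(dist) + 1L]] <- data.frame(
      day = day, household_id = id, poi_id = fb$poi_id, units = u,
      stringsAsFactors = FALSE)
  }
  list(chain = chain, households = households,
       distributions = if (length(dist)) do.call(rbind, dist)
       else data.frame(day = integer(0), household_id = character(0),
                       poi_id = character(0), units = integer(0)))
}

#' Health-system response
#'
#' When the day's shortage severity (fraction of selling POIs in the panic
#' regime) exceeds the trigger, clinics activate crisis-extended hours and
#' distribute limited formula samples (one day per infant) to critically
#' low households, bounded by each clinic's sample stock.
#'
#' @param chain a `framesim_chain`.
#' @param households population list.
#' @param day simulation day.
#' @param trigger severity trigger in [0,1].
#' @return list with `chain`, `households`, `samples` data frame.
#' @export
health_system_step <- function(chain, households, day, trigger = 0.3) {
  severity <- shortage_severity(chain)
  chain$crisis_active <- severity > trigger
  samples <- list()
  if (chain$crisis_active) {
    supply <- vapply(households, `[[`, numeric(1), "supply_days")
    crit <- names(households)[supply <= 2]
    for (id in crit) {
      hh <- households[[id]]
      cl <- nearest_poi(chain$pois[chain$pois$shelf_stock > 0, , drop = FALSE],
                        hh, "clinic", zone = hh$zone_id)
      if (is.null(cl)) next
      u <- as.integer(min(hh$infants, cl$shelf_stock))
      if (u < 1) next
      chain <- distribute_units(chain, cl$poi_id, u)
      households[[id]]$supply_days <- hh$supply_days + u / hh$infants
      samples[[length(samples) + 1L]] <- data.frame(
        day = day, household_id = id, poi_id = cl$poi_id, units = u,
        stringsAsFactors = FALSE)
    }
  }
  list(chain = chain, households = households,
       samples = if (length(samples)) do.call(rbind, samples)
       else data.frame(day = integer(0), household_id = character(0),
                       poi_id = character(0), units = integer(0)))
}

#' Policy-program response
#'
#' Above the severity trigger the policy program issues the day's shortage
#' broadcast (a global cue consumed by every household) — the channel
#' through which scheduled interventions (waivers, price controls, brand
#' expansions) are also announced.
#'
#' @param chain a `framesim_chain`.
#' @param day simulation day.
#' @param trigger severity trigger in [0,1].
#' @return updated chain (with `broadcast_today` set when triggered).
#' @export
policy_step <- function(chain, day, trigger = 0.3) {
  if (shortage_severity(chain) > trigger)
    chain <- apply_policy(chain, list(kind = "broadcast"))
  chain
}
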