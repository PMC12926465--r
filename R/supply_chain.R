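# Discrete-time flow of formula units: manufacturers -> distributor buffer
# -> store shelves, with disruptions, panic-buying amplification and policy
# interventions. A cumulative ledger enforces unit conservation:
#   produced + initial stock =
#     in_transit + on_shelf + purchased + emergency_distributed + spoiled

#' Initialize the supply-chain state for a scenario
#'
#' @param scenario a `framesim_scenario`.
#' @return a `framesim_chain` list holding manufacturers, the distributor
#'   buffer, the POI table (shelf stock lives there) and the ledger.
#' @export
init_chain <- function(scenario) {
  sup <- scenario$supply
  man <- do.call(rbind, lapply(sup$manufacturers, function(m)
    data.frame(name = m$name, share = m$share,
               daily_production = m$daily_production,
               operational = isTRUE(m$operational),
               stringsAsFactors = FALSE)))
  buffer <- as.numeric(sup$buffer_stock)
  initial <- buffer + sum(scenario$pois$shelf_stock)
  structure(list(
    pois = scenario$pois,
    manufacturers = man,
    buffer = buffer,
    restock_interval = as.integer(sup$restock_interval),
    panic_threshold = sup$panic_threshold %||% 0.30,
    panic_multiplier = sup$panic_multiplier %||% 1.5,
    initial_stock = initial,
    produced = 0, purchased = 0, emergency_distributed = 0, spoiled = 0,
    broadcast_today = FALSE,
    crisis_active = FALSE
  ), class = "framesim_chain")
}

#' Current supply ledger
#'
#' @param chain a `framesim_chain`.
#' @return named numeric vector of the ledger fields.
#' @export
supply_ledger <- function(chain) {
  c(produced = chain$produced,
    initial_stock = chain$initial_stock,
    in_transit = chain$buffer,
    on_shelf = sum(chain$pois$shelf_stock),
    purchased = chain$purchased,
    emergency_distributed = chain$emergency_distributed,
    spoiled = chain$spoiled)
}

#' Does the ledger balance?
#' @param chain a `framesim_chain`.
#' @param tol numeric tolerance.
#' @return logical.
#' @export
ledger_balanced <- function(chain, tol = 1e-9) {
  l <- supply_ledger(chain)
  abs((l[["produced"]] + l[["initial_stock"]]) -
        (l[["in_transit"]] + l[["on_shelf"]] + l[["purchased"]] +
           l[["emergency_distributed"]] + l[["spoiled"]])) < tol
}

#' Advance the supply chain by one day
#'
#' Operational manufacturers add their daily production to the distributor
#' buffer; on multiples of the restock interval the buffer is delivered to
#' selling POIs (stores and WIC vendors) proportional to their baseline
#' stock, with the integer remainder held back.
#'
#' @param chain a `framesim_chain`.
#' @param day simulation day (1-based).
#' @return list with elements `chain` (updated state) and `deliveries`
#'   (data frame `poi_id`, `units`).
#' @export
step_supply <- function(chain, day) {
  prod <- sum(chain$manufacturers$daily_production[chain$manufacturers$operational])
  chain$buffer <- chain$buffer + prod
  chain$produced <- chain$produced + prod

  sells <- chain$pois$kind %in% c("store", "wic_vendor")
  deliveries <- data.frame(poi_id = character(0), units = integer(0))
  if (day %% chain$restock_interval == 0 && chain$buffer >= 1) {
    base <- chain$pois$baseline_stock[sells]
    units <- floor(chain$buffer * base / sum(base))
    chain$pois$shelf_stock[sells] <- chain$pois$shelf_stock[sells] + units
    chain$buffer <- chain$buffer - sum(units)
    deliveries <- data.frame(poi_id = chain$pois$poi_id[sells],
                             units = as.integer(units))
  }
  if (any(chain$pois$shelf_stock < 0) || chain$buffer < 0)
    stopf("negative stock after supply step on day %d", day,
          class = "framesim_internal_error")
  list(chain = chain, deliveries = deliveries)
}

#' Panic-buying state of a store
#'
#' Panic buying engages when consumer-visible inventory falls strictly
#' below the threshold fraction of baseline (default 30%).
#'
#' @param visible_fraction shelf stock / baseline stock, >= 0.
#' @param threshold panic threshold (default 0.30).
#' @return logical.
#' @export
#' @examples
#' panic_state(0.29)  # TRUE
#' panic_state(0.30)  # FALSE
panic_state <- function(visible_fraction, threshold = 0.30) {
  stopifnot(all(visible_fraction >= 0))
  visible_fraction < threshold
}

#' Demand under panic amplification
#'
#' @param base_demand units demanded absent panic (>= 0).
#' @param panic logical panic flag.
#' @param multiplier demand multiplier under panic (>= 1, default 1.5).
#' @return integer units (half-up rounding).
#' @export
effective_demand <- function(base_demand, panic, multiplier = 1.5) {
  stopifnot(base_demand >= 0)
  if (multiplier < 1)
    stopf("panic multiplier must be >= 1 (got %g)", multiplier,
          class = "framesim_config_error")
  as.integer(round_half_up(if (panic) base_demand * multiplier else base_demand))
}

# Fraction of selling POIs currently in the panic regime: the day's
# shortage-severity metric used by the service agents.
shortage_severity <- function(chain) {
  sells <- chain$pois$kind %in% c("store", "wic_vendor")
  vf <- chain$pois$shelf_stock[sells] / chain$pois$baseline_stock[sells]
  mean(panic_state(vf, chain$panic_threshold))
}

#' Apply a policy event to the supply chain
#'
#' Kinds: `plant_closure` (manufacturer off-line), `import_waiver`
#' (emergency importation surge added to the distributor buffer and the
#' produced ledger), `tariff_increase` (prices scaled by 1 + magnitude),
#' `price_control` (prices capped at base price), `wic_brand_expansion`
#' (all selling stock becomes WIC-eligible), `emergency_funding`
#' (purchasing-power boost handled by the engine), `broadcast` (global
#' shortage cue for households).
#'
#' @param chain a `framesim_chain`.
#' @param event list with `kind`, `start_day`, `end_day`, `magnitude` and
#'   optionally `target` (manufacturer name).
#' @return updated chain.
#' @export
apply_policy <- function(chain, event) {
  switch(event$kind,
    plant_closure = {
      i <- if (!is.null(event$target))
        match(event$target, chain$manufacturers$name) else 1L
      if (is.na(i))
        stopf("plant_closure: unknown manufacturer '%s'", event$target,
              class = "framesim_config_error")
      chain$manufacturers$operational[i] <- FALSE
    },
    import_waiver = {
      chain$buffer <- chain$buffer + event$magnitude
      chain$produced <- chain$produced + event$magnitude
    },
    tariff_increase = {
      chain$pois$price <- chain$pois$price * (1 + event$magnitude)
    },
    price_control = {
      chain$pois$price <- pmin(chain$pois$price, chain$pois$base_price)
    },
    wic_brand_expansion = {
      sells <- chain$pois$kind %in% c("store", "wic_vendor")
      chain$pois$wic_fraction[sells] <- 1.0
    },
    emergency_funding = {
      chain$emergency_funding_today <- event$magnitude
    },
    broadcast = {
      chain$broadcast_today <- TRUE
    },
    stopf("unknown policy event kind '%s'", event$kind,
          class = "framesim_config_error")
  )
  chain
}

# Reverse the reversible effects of an event once it expires.
expire_policy <- function(chain, event) {
  switch(event$kind,
    plant_closure = {
      i <- if (!is.null(event$target))
        match(event$target, chain$manufacturers$name) else 1L
      chain$manufacturers$operational[i] <- TRUE
    },
    tariff_increase = {
      chain$pois$price <- chain$pois$price / (1 + event$magnitude)
    },
    emergency_funding = {
      chain$emergency_funding_today <- NULL
    },
    NULL
  )
  chain
}

# Sell units off a shelf (household purchase). Returns updated chain.
sell_units <- function(chain, poi_id, units) {
  i <- match(poi_id, chain$pois$poi_id)
  stopifnot(!is.na(i), units <= chain$pois$shelf_stock[i])
  chain$pois$shelf_stock[i] <- chain$pois$shelf_stock[i] - units
  chain$purchased <- chain$purchased + units
  chain
}

# Emergency distribution (food bank, clinic samples). Returns updated chain.
distribute_units <- function(chain, poi_id, units) {
  i <- match(poi_id, chain$pois$poi_id)
  stopifnot(!is.na(i), units <= chain$pois$shelf_stock[i])
  chain$pois$shelf_stock[i] <- chain$pois$shelf_stock[i] - units
  chain$emergency_distributed <- chain$emergency_distributed + units
  chain
}
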