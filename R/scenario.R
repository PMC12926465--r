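# Stylized digital-twin environment: zones, points of interest, transit,
# calendar. Replaces real GIS / transit / survey layers with parameterized
# fixtures on an abstract planar grid (km).

ZONE_IDS <- c("75216", "75241", "75212", "75228", "75231")
POI_KINDS <- c("store", "wic_vendor", "clinic", "food_bank")

#' Default scenario configuration
#'
#' Returns the configuration of the default study environment: five
#' ZIP-code-like zones in a southern-Dallas-style layout, stores / WIC
#' vendors / clinics / food banks per zone, a transit fixture with nine bus
#' routes, two rail lines and twelve stops, a 14-day hourly calendar, a
#' two-manufacturer supply chain, and the shortage's policy events (a plant
#' closure followed by an import waiver and a WIC brand expansion).
#'
#' Travel speeds default to walk 5, bus 20, drive 40, rail 60 km/h. The
#' panic-buying threshold is 30% of baseline shelf stock with a 1.5x demand
#' multiplier. All values can be overridden before passing the list to
#' [make_scenario()].
#'
#' @return nested list understood by [make_scenario()].
#' @export
default_scenario_config <- function() {
  zone_boxes <- list(
    c(0, 4, 0, 4), c(4.6, 8.6, 0, 4), c(9.2, 13.2, 0, 4),
    c(0, 4, 4.6, 8.6), c(4.6, 8.6, 4.6, 8.6)
  )
  access <- c("low_income_low_access", "low_income_low_access",
              "low_income_low_access", "normal", "normal")
  zones <- Map(function(id, box, acc) {
    list(
      zone_id = id, food_access_class = acc, bbox = box,
      attributes = list(
        income_tier_probs = c(low = 0.50, middle = 0.35, high = 0.15),
        vehicle_p = if (acc == "normal") 0.70 else 0.50,
        wic_p = if (acc == "normal") 0.35 else 0.50,
        snap_p = if (acc == "normal") 0.30 else 0.45,
        schedule_probs = c(day = 0.50, evening = 0.25, flexible = 0.25),
        infants_probs = c(`1` = 0.8, `2` = 0.2),
        stress_mean = if (acc == "normal") 0.45 else 0.60,
        stress_sd = 0.15
      )
    )
  }, ZONE_IDS, zone_boxes, access)
  list(
    calendar = list(horizon_days = 14L, ticks_per_day = 24L),
    zones = zones,
    pois = list(
      per_zone = c(store = 2L, wic_vendor = 1L, clinic = 1L, food_bank = 1L),
      store_hours = c(8, 21), wic_vendor_hours = c(9, 18),
      clinic_hours = c(9, 17), clinic_crisis_hours = c(17, 20),
      food_bank_hours = c(9, 17), food_bank_crisis_hours = c(17, 19),
      base_price = 5.0, price_sigma = 0.10,
      store_baseline_stock = 40L, wic_vendor_baseline_stock = 15L,
      initial_stock_fraction = 0.35,
      clinic_sample_stock = 10L, food_bank_stock = 30L,
      wic_fraction = 0.5
    ),
    transit = list(
      n_bus = 9L, n_rail = 2L, n_stops = 12L,
      bus_headways = c(20, 25, 30), rail_headway = 15,
      fare = 2.5, bus_service = c(6, 22), rail_service = c(5, 24)
    ),
    speeds_kmh = c(walk = 5, drive = 40, bus = 20, rail = 60),
    supply = list(
      manufacturers = list(
        list(name = "manufacturer_a", share = 0.6, daily_production = 30L,
             operational = TRUE),
        list(name = "manufacturer_b", share = 0.4, daily_production = 20L,
             operational = TRUE)
      ),
      restock_interval = 3L, buffer_stock = 20L,
      panic_threshold = 0.30, panic_multiplier = 1.5
    ),
    policy_events = list(
      list(kind = "plant_closure", start_day = 1L, end_day = 10L,
           magnitude = 1, target = "manufacturer_a"),
      list(kind = "import_waiver", start_day = 8L, end_day = 8L,
           magnitude = 60),
      list(kind = "wic_brand_expansion", start_day = 9L, end_day = 14L,
           magnitude = 1)
    ),
    crisis = list(severity_trigger = 0.3, emergency_days = 2)
  )
}

#' Read or write a scenario configuration file
#'
#' Configurations are plain nested lists and serialize to YAML or JSON
#' (chosen by file extension; YAML requires the `yaml` package). Vectors
#' are preserved; section structure matches [default_scenario_config()].
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_scenario_config`: a configuration list.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  normalize_config(raw)
}

# File formats return name-preserving maps as lists; flatten the fields
# the schema defines as (possibly named) numeric vectors.
normalize_config <- function(cfg) {
  num <- function(x) if (is.list(x)) unlist(x) else x
  cfg$zones <- lapply(cfg$zones, function(z) {
    z$bbox <- as.numeric(num(z$bbox))
    z$attributes <- lapply(z$attributes, num)
    z
  })
  vec_fields <- c("per_zone", "store_hours", "wic_vendor_hours",
                  "clinic_hours", "clinic_crisis_hours", "food_bank_hours",
                  "food_bank_crisis_hours")
  for (f in intersect(vec_fields, names(cfg$pois)))
    cfg$pois[[f]] <- num(cfg$pois[[f]])
  cfg$transit <- lapply(cfg$transit, num)
  cfg$speeds_kmh <- num(cfg$speeds_kmh)
  cfg
}

#' @rdname read_scenario_config
#' @param config a scenario configuration list.
#' @return `write_scenario_config`: `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  # named atomic vectors must become maps, not arrays, so their names
  # survive the round trip
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("writing YAML configs requires the 'yaml' package")
    yaml::write_yaml(listify(config), path)
  } else {
    jsonlite::write_json(listify(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

validate_config <- function(config) {
  need <- c("calendar", "zones", "pois", "transit", "speeds_kmh", "supply")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stopf("scenario config is missing section '%s'", miss[1],
          class = "framesim_config_error")
  cal <- config$calendar
  if (!is.numeric(cal$horizon_days) || cal$horizon_days < 1)
    stopf("calendar$horizon_days must be >= 1",
          class = "framesim_config_error")
  if (!is.numeric(cal$ticks_per_day) || cal$ticks_per_day < 1)
    stopf("calendar$ticks_per_day must be >= 1",
          class = "framesim_config_error")
  for (z in config$zones) {
    a <- z$attributes
    probs <- c(a$income_tier_probs, a$vehicle_p, a$wic_p, a$snap_p,
               a$schedule_probs, a$infants_probs)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
      stopf("zones[%s]$attributes: probabilities must lie in [0,1]",
            z$zone_id, class = "framesim_config_error")
    if (length(z$bbox) != 4 || z$bbox[1] >= z$bbox[2] || z$bbox[3] >= z$bbox[4])
      stopf("zones[%s]$bbox must be c(xmin, xmax, ymin, ymax)",
            z$zone_id, class = "framesim_config_error")
  }
  if (sum(config$pois$per_zone) < 1)
    stopf("pois$per_zone: every zone needs at least one point of interest",
          class = "framesim_config_error")
  tr <- config$transit
  if (any(c(tr$bus_headways, tr$rail_headway) <= 0))
    stopf("transit headways must be > 0", class = "framesim_config_error")
  shares <- vapply(config$supply$manufacturers, `[[`, numeric(1), "share")
  if (abs(sum(shares) - 1) > 1e-8)
    stopf("supply$manufacturers: market shares must sum to 1 (got %.3f)",
          sum(shares), class = "framesim_config_error")
  invisible(config)
}

#' Build a scenario from a configuration
#'
#' Constructs the full simulation environment — zones with household
#' attribute distributions, located points of interest with operating hours
#' and stock, the transit network, and the calendar — as a pure function of
#' `(config, seed)`: repeated calls yield structurally identical scenarios.
#'
#' @param config configuration list, see [default_scenario_config()].
#' @param seed integer root seed; all sampled coordinates derive from it.
#' @return an object of class `framesim_scenario`.
#' @export
#' @examples
#' sc <- make_scenario(default_scenario_config(), seed = 1)
#' sc$zones$zone_id
make_scenario <- function(config = default_scenario_config(), seed = 1L) {
  validate_config(config)
  zones <- do.call(rbind, lapply(config$zones, function(z) {
    data.frame(zone_id = z$zone_id, food_access_class = z$food_access_class,
               xmin = z$bbox[1], xmax = z$bbox[2],
               ymin = z$bbox[3], ymax = z$bbox[4],
               stringsAsFactors = FALSE)
  }))
  zone_attributes <- stats::setNames(
    lapply(config$zones, `[[`, "attributes"),
    vapply(config$zones, `[[`, character(1), "zone_id"))

  pois <- build_pois(config, zones, seed)
  if (!all(zones$zone_id %in% pois$zone_id))
    stopf("zone %s has zero points of interest",
          setdiff(zones$zone_id, pois$zone_id)[1],
          class = "framesim_config_error")
  transit <- build_transit(config, zones, seed)

  structure(list(
    zones = zones,
    zone_attributes = zone_attributes,
    pois = pois,
    transit = transit,
    calendar = list(horizon_days = as.integer(config$calendar$horizon_days),
                    ticks_per_day = as.integer(config$calendar$ticks_per_day)),
    speeds_kmh = config$speeds_kmh,
    supply = config$supply,
    crisis = config$crisis,
    policy_events = config$policy_events %||% list(),
    seed = as.integer(seed)
  ), class = "framesim_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_pois <- function(config, zones, seed) {
  pc <- config$pois
  rows <- list()
  for (zi in seq_len(nrow(zones))) {
    z <- zones[zi, ]
    counts <- pc$per_zone
    k <- 0L
    for (kind in names(counts)) {
      for (j in seq_len(counts[[kind]])) {
        k <- k + 1L
        id <- sprintf("%s_%s_%d", z$zone_id, kind, j)
        xy <- with_seed(hash_seed(seed, "poi", id), {
          c(stats::runif(1, z$xmin, z$xmax), stats::runif(1, z$ymin, z$ymax))
        })
        hrs <- switch(kind,
          store = pc$store_hours, wic_vendor = pc$wic_vendor_hours,
          clinic = pc$clinic_hours, food_bank = pc$food_bank_hours)
        ext <- switch(kind,
          clinic = pc$clinic_crisis_hours,
          food_bank = pc$food_bank_crisis_hours, NULL)
        base_stock <- switch(kind,
          store = pc$store_baseline_stock,
          wic_vendor = pc$wic_vendor_baseline_stock,
          clinic = pc$clinic_sample_stock,
          food_bank = pc$food_bank_stock)
        sells <- kind %in% c("store", "wic_vendor")
        price <- if (sells) {
          with_seed(hash_seed(seed, "price", id),
                    pc$base_price * exp(stats::rnorm(1, 0, pc$price_sigma)))
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          poi_id = id, kind = kind, zone_id = z$zone_id,
          x = xy[1], y = xy[2],
          open_start = hrs[1], open_end = hrs[2],
          ext_start = if (is.null(ext)) NA_real_ else ext[1],
          ext_end = if (is.null(ext)) NA_real_ else ext[2],
          wic_authorized = kind == "wic_vendor" ||
            (kind == "store" && j == 1L),
          base_price = pc$base_price,
          price = price,
          shelf_stock = if (sells)
            as.integer(round(base_stock * pc$initial_stock_fraction))
          else as.integer(base_stock),
          baseline_stock = as.integer(base_stock),
          wic_fraction = if (kind == "wic_vendor") 1.0 else pc$wic_fraction,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

build_transit <- function(config, zones, seed) {
  tr <- config$transit
  xr <- range(c(zones$xmin, zones$xmax))
  yr <- range(c(zones$ymin, zones$ymax))
  stops <- with_seed(hash_seed(seed, "stops"), data.frame(
    stop_id = sprintf("stop_%02d", seq_len(tr$n_stops)),
    x = stats::runif(tr$n_stops, xr[1], xr[2]),
    y = stats::runif(tr$n_stops, yr[1], yr[2]),
    stringsAsFactors = FALSE))
  routes <- list()
  for (i in seq_len(tr$n_bus)) {
    routes[[length(routes) + 1L]] <- with_seed(hash_seed(seed, "bus", i), list(
      route_id = sprintf("bus_%d", i), mode = "bus",
      stops = sample(stops$stop_id, sample(3:5, 1)),
      headway_min = sample(tr$bus_headways, 1), fare = tr$fare,
      service_start = tr$bus_service[1], service_end = tr$bus_service[2]))
  }
  for (i in seq_len(tr$n_rail)) {
    routes[[length(routes) + 1L]] <- with_seed(hash_seed(seed, "rail", i), list(
      route_id = sprintf("rail_%d", i), mode = "rail",
      stops = sample(stops$stop_id, sample(4:6, 1)),
      headway_min = tr$rail_headway, fare = tr$fare,
      service_start = tr$rail_service[1], service_end = tr$rail_service[2]))
  }
  list(stops = stops, routes = routes)
}

#' @export
print.framesim_scenario <- function(x, ...) {
  n_bus <- sum(vapply(x$transit$routes, function(r) r$mode == "bus", logical(1)))
  n_rail <- length(x$transit$routes) - n_bus
  cat(sprintf(
    "<framesim_scenario> %d zones, %d POIs, %d bus + %d rail routes, %d stops, %d-day horizon (seed %d)\n",
    nrow(x$zones), nrow(x$pois), n_bus, n_rail, nrow(x$transit$stops),
    x$calendar$horizon_days, x$seed))
  invisible(x)
}

#' Serialize a scenario to canonical JSON
#'
#' Used by the replay tests: two scenarios built from the same
#' `(config, seed)` serialize to byte-identical strings.
#'
#' @param scenario a `framesim_scenario`.
#' @return a JSON string.
#' @export
scenario_json <- function(scenario) {
  as.character(jsonlite::toJSON(unclass(scenario), auto_unbox = TRUE,
                                digits = NA))
}

# ---- calendar ---------------------------------------------------------------

#' Convert a tick to (day, hour) and back
#'
#' Ticks are 1-based hours within the horizon: tick 1 is day 1, hour 0.
#' The mapping is bijective on `1..horizon_days * ticks_per_day`.
#'
#' @param tick integer tick.
#' @param ticks_per_day ticks per simulated day (default 24).
#' @return `tick_daytime`: list with `day` and `hour`.
#' @export
tick_daytime <- function(tick, ticks_per_day = 24L) {
  list(day = (tick - 1L) %/% ticks_per_day + 1L,
       hour = (tick - 1L) %% ticks_per_day)
}

#' @rdname tick_daytime
#' @param day,hour day (1-based) and hour (0-based).
#' @export
daytime_tick <- function(day, hour, ticks_per_day = 24L) {
  as.integer((day - 1L) * ticks_per_day + hour + 1L)
}

# ---- operating hours --------------------------------------------------------

#' Is a point of interest open at a tick?
#'
#' A POI is open when the tick's hour falls in its regular operating window,
#' or in its crisis-extension window while the crisis trigger is active.
#' Windows are half-open `[start, end)`.
#'
#' @param poi one-row data frame (a row of `scenario$pois`).
#' @param tick integer tick.
#' @param crisis_active logical; are crisis-adjusted extensions in force?
#' @param ticks_per_day ticks per day.
#' @return logical.
#' @export
open_at <- function(poi, tick, crisis_active = FALSE, ticks_per_day = 24L) {
  h <- tick_daytime(tick, ticks_per_day)$hour
  open <- h >= poi$open_start & h < poi$open_end
  if (crisis_active && !is.na(poi$ext_start))
    open <- open | (h >= poi$ext_start & h < poi$ext_end)
  open
}

# ---- travel -----------------------------------------------------------------

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Door-to-door travel time
#'
#' Walk and drive are straight-line distance at the configured speed.
#' Transit is walk to the nearest stop of an in-service route, an expected
#' wait of half the headway, in-vehicle travel along the route's stop
#' sequence, and a walk from the alighting stop; the best in-service route
#' is used. Requesting transit when no route is in service signals a
#' condition of class `framesim_no_service` — callers fall back to walking.
#'
#' @param scenario a `framesim_scenario`.
#' @param origin,dest numeric `c(x, y)` in km.
#' @param mode one of `"walk"`, `"drive"`, `"transit"`.
#' @param depart departure tick (needed for transit service hours).
#' @return travel time in minutes (>= 0).
#' @export
travel_time <- function(scenario, origin, dest,
                        mode = c("walk", "drive", "transit"), depart = 1L) {
  mode <- match.arg(mode)
  sp <- scenario$speeds_kmh
  d <- euclid(origin, dest)
  if (mode == "walk") return(d / sp[["walk"]] * 60)
  if (mode == "drive") return(d / sp[["drive"]] * 60)

  hour <- tick_daytime(depart, scenario$calendar$ticks_per_day)$hour
  stops <- scenario$transit$stops
  best <- Inf
  for (r in scenario$transit$routes) {
    if (hour < r$service_start || hour >= r$service_end) next
    rs <- stops[match(r$stops, stops$stop_id), ]
    d_o <- sqrt((rs$x - origin[1])^2 + (rs$y - origin[2])^2)
    d_d <- sqrt((rs$x - dest[1])^2 + (rs$y - dest[2])^2)
    i <- which.min(d_o); j <- which.min(d_d)
    ride <- 0
    if (i != j) {
      idx <- seq(min(i, j), max(i, j))
      seg <- sqrt(diff(rs$x[idx])^2 + diff(rs$y[idx])^2)
      ride <- sum(seg) / sp[[r$mode]] * 60
    }
    tt <- d_o[i] / sp[["walk"]] * 60 + r$headway_min / 2 + ride +
      d_d[j] / sp[["walk"]] * 60
    if (tt < best) best <- tt
  }
  if (!is.finite(best))
    stop(errorCondition("no transit service at departure time",
                        class = c("framesim_no_service", "error", "condition")))
  best
}

# Is any transit route in service at this hour?
transit_in_service <- function(scenario, hour) {
  any(vapply(scenario$transit$routes,
             function(r) hour >= r$service_start && hour < r$service_end,
             logical(1)))
}
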