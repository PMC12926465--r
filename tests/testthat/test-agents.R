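sc <- make_scenario(default_scenario_config(), seed = 1)

test_that("observation builds cues only from agent-visible information", {
  chain <- init_chain(sc)
  env <- list(chain = chain, scenario = sc, day = 5, hour = 10)

  hh <- mk_household(supply = 10)
  households <- list(hh_001 = hh)
  cues <- observe(hh, env, households)
  expect_false(any(cues$declining_supply, cues$store_stockout_observed,
                   cues$transport_limited, cues$shortage_broadcast,
                   cues$peer_success_via_support, cues$own_failed_strategy))

  hh$memory <- data.frame(day = c(3, 4), action = "visit_store",
                          success = FALSE, reason = "stockout",
                          stringsAsFactors = FALSE)
  cues <- observe(hh, env, list(hh_001 = hh))
  expect_true(cues$own_failed_strategy[["visit_store"]])
  expect_true(cues$store_stockout_observed)

  peer <- mk_household(id = "hh_002")
  peer$memory <- data.frame(day = 4, action = "visit_food_bank",
                            success = TRUE, reason = "food_bank",
                            stringsAsFactors = FALSE)
  hh2 <- mk_household(supply = 10, ties = "hh_002")
  cues <- observe(hh2, env, list(hh_001 = hh2, hh_002 = peer))
  expect_true(cues$peer_success_via_support)

  # 4 am: no transit in service, no vehicle
  env4 <- list(chain = chain, scenario = sc, day = 5, hour = 4)
  hh3 <- mk_household(vehicle = FALSE, supply = 10)
  expect_true(observe(hh3, env4, list(hh_001 = hh3))$transport_limited)
})

test_that("belief updates follow the cue directions and stay in [0,1]", {
  b0 <- initial_beliefs()
  expect_identical(update_beliefs(b0, empty_cues()), b0)

  cues <- empty_cues(); cues$declining_supply <- TRUE
  b1 <- update_beliefs(b0, cues)
  expect_gt(b1[["perceived_severity"]], b0[["perceived_severity"]])
  expect_gt(b1[["perceived_susceptibility"]], b0[["perceived_susceptibility"]])

  cues <- empty_cues(); cues$store_stockout_observed <- TRUE
  expect_lt(update_beliefs(b0, cues)[["perceived_behavioral_control"]],
            b0[["perceived_behavioral_control"]])

  cues <- empty_cues(); cues$transport_limited <- TRUE
  b2 <- update_beliefs(b0, cues)
  expect_gt(b2[["perceived_barriers"]], b0[["perceived_barriers"]])
  expect_lt(b2[["perceived_behavioral_control"]],
            b0[["perceived_behavioral_control"]])

  cues <- empty_cues(); cues$shortage_broadcast <- TRUE
  b3 <- update_beliefs(b0, cues)
  expect_gt(b3[["subjective_norm"]], b0[["subjective_norm"]])

  cues <- empty_cues(); cues$peer_success_via_support <- TRUE
  expect_gt(update_beliefs(b0, cues)[["outcome_expectancy_social"]],
            b0[["outcome_expectancy_social"]])

  # arbitrary cue sequences never escape the unit interval
  set.seed(9)
  b <- b0
  for (i in 1:200) {
    cues <- empty_cues()
    for (nm in setdiff(names(cues), "own_failed_strategy"))
      cues[[nm]] <- runif(1) < 0.5
    cues$own_failed_strategy[] <- runif(7) < 0.3
    b <- update_beliefs(b, cues)
    expect_true(all(b >= 0 & b <= 1))
  }
})

test_that("trait modulation is an elementwise product", {
  b <- initial_beliefs()
  expect_equal(apply_trait_modifiers(b, neutral_traits(1)), b)
  tr0 <- neutral_traits(1)
  tr0$hbm$severity_sensitivity <- 0
  expect_equal(apply_trait_modifiers(b, tr0)[["perceived_severity"]], 0)

  set.seed(4)
  for (i in 1:20) {
    bb <- stats::setNames(runif(7), names(b))
    vals <- runif(7)
    tr <- neutral_traits()
    tr$hbm$severity_sensitivity <- vals[1]
    tr$hbm$susceptibility_sensitivity <- vals[2]
    tr$hbm$barrier_weight <- vals[3]
    tr$hbm$benefit_weight <- vals[4]
    tr$tpb$perceived_control_base <- vals[5]
    tr$tpb$subjective_norm_weight <- vals[6]
    tr$sct$observational_learning_weight <- vals[7]
    expect_equal(unname(apply_trait_modifiers(bb, tr)),
                 unname(bb * vals))
  }
})

test_that("intention scores respond to urgency, cues and gates", {
  zero <- stats::setNames(rep(0, 7), names(initial_beliefs()))
  hh <- mk_household(supply = 10)  # low urgency
  s <- compute_intentions(zero, empty_cues(), hh)
  expect_equal(select_action(s), "wait")

  hh_crit <- mk_household(supply = 1, wic = TRUE)
  w <- apply_trait_modifiers(initial_beliefs(), neutral_traits())
  cues_peer <- empty_cues(); cues_peer$peer_success_via_support <- TRUE
  s0 <- compute_intentions(w, empty_cues(), hh_crit)
  s1 <- compute_intentions(w, cues_peer, hh_crit)
  for (a in c("seek_social_help", "visit_food_bank", "contact_wic_vendor"))
    expect_gt(s1[[a]], s0[[a]])

  cues_tr <- empty_cues(); cues_tr$transport_limited <- TRUE
  s2 <- compute_intentions(w, cues_tr, hh_crit)
  expect_lt(s2[["travel_far_store"]], s0[["travel_far_store"]])
  expect_identical(s2[["travel_far_store"]], -Inf)

  hh_nowic <- mk_household(supply = 1, wic = FALSE)
  expect_identical(
    compute_intentions(w, empty_cues(), hh_nowic)[["contact_wic_vendor"]],
    -Inf)

  cues_fail <- empty_cues()
  cues_fail$own_failed_strategy[["visit_store"]] <- TRUE
  s3 <- compute_intentions(w, cues_fail, hh_crit)
  expect_lt(s3[["visit_store"]], s0[["visit_store"]])
})

test_that("intention noise is bounded, seeded and vanishes at epsilon 0", {
  s <- stats::setNames(runif(7), framesim:::ACTIONS)
  expect_identical(add_bounded_noise(s, seed = 1, epsilon = 0), s)
  eps <- 0.05
  worst <- 0
  for (k in 1:2000) {
    d <- add_bounded_noise(s, seed = k, epsilon = eps) - s
    worst <- max(worst, max(abs(d)))
  }
  expect_lte(worst, eps)
  expect_identical(add_bounded_noise(s, seed = 77, epsilon = eps),
                   add_bounded_noise(s, seed = 77, epsilon = eps))
  gated <- s; gated[["travel_far_store"]] <- -Inf
  expect_identical(add_bounded_noise(gated, 3)[["travel_far_store"]], -Inf)
})

test_that("action selection is argmax with the documented tie order", {
  set.seed(11)
  for (i in 1:200) {
    s <- stats::setNames(runif(7), framesim:::ACTIONS)
    mx <- max(s)
    oracle <- framesim:::ACTIONS[s == mx][1]
    expect_identical(select_action(s), oracle)
  }
  tie <- stats::setNames(c(0.5, -1, -1, -1, -1, -1, 0.5),
                         framesim:::ACTIONS)
  expect_identical(select_action(tie), "visit_store")
  allgated <- stats::setNames(rep(-Inf, 7), framesim:::ACTIONS)
  expect_identical(select_action(allgated), "wait")
})

test_that("the control decision tree follows the fixed rules", {
  chain <- init_chain(sc)
  env <- list(chain = chain, scenario = sc, hour = 10)
  env_notransit <- list(chain = chain, scenario = sc, hour = 4)

  expect_identical(baseline_decide(mk_household(supply = 1), env),
                   "visit_store")
  expect_identical(
    baseline_decide(mk_household(supply = 1, vehicle = FALSE),
                    env_notransit),
    "seek_social_help")
  expect_identical(baseline_decide(mk_household(supply = 10), env), "wait")

  expect_identical(baseline_decide(mk_household(supply = 4), env),
                   "visit_store")  # stocked store known in zone
  empty_chain <- chain
  empty_chain$pois$shelf_stock[empty_chain$pois$kind == "store"] <- 0L
  env_empty <- list(chain = empty_chain, scenario = sc, hour = 10)
  expect_identical(baseline_decide(mk_household(supply = 4), env_empty),
                   "wait")
})

test_that("store execution handles purchases, stockouts and WIC eligibility", {
  chain <- init_chain(sc)
  in_zone <- chain$pois$kind == "store" & chain$pois$zone_id == "75216"
  chain$pois$shelf_stock[in_zone] <- 20L
  chain$pois$price[in_zone] <- 5
  env <- list(chain = chain, scenario = sc, day = 2, hour = 10)

  hh <- mk_household(supply = 1, budget = 60)
  r <- execute_action(hh, "visit_store", env, list(hh_001 = hh))
  expect_true(r$outcome$success)
  expect_identical(r$outcome$units, 3L)
  expect_equal(r$household$supply_days, 1 + 3)
  expect_equal(r$chain$purchased, 3)
  expect_equal(sum(r$chain$pois$shelf_stock[in_zone]), 40 - 3)
  expect_identical(utils::tail(r$household$memory$action, 1), "visit_store")

  empty <- chain
  empty$pois$shelf_stock[in_zone] <- 0L
  renv <- list(chain = empty, scenario = sc, day = 2, hour = 10)
  r2 <- execute_action(hh, "visit_store", renv, list(hh_001 = hh))
  expect_false(r2$outcome$success)
  expect_identical(r2$outcome$reason, "stockout")
  expect_identical(nrow(r2$household$memory), 1L)

  # WIC household, no cash: ineligible stock blocks the purchase until the
  # brand expansion makes all shelf stock voucher-eligible
  wchain <- chain
  wchain$pois$wic_authorized[in_zone] <- TRUE
  wchain$pois$wic_fraction[in_zone] <- 0
  wic_hh <- mk_household(supply = 1, budget = 0, wic = TRUE)
  wenv <- list(chain = wchain, scenario = sc, day = 2, hour = 10)
  r3 <- execute_action(wic_hh, "visit_store", wenv, list(hh_001 = wic_hh))
  expect_false(r3$outcome$success)
  expect_identical(r3$outcome$reason, "wic_ineligible")
  expanded <- apply_policy(wchain, list(kind = "wic_brand_expansion"))
  wenv2 <- list(chain = expanded, scenario = sc, day = 2, hour = 10)
  r4 <- execute_action(wic_hh, "visit_store", wenv2, list(hh_001 = wic_hh))
  expect_true(r4$outcome$success)
  expect_identical(r4$outcome$reason, "purchased_wic")
})

test_that("supply accounting: units to days, purchase and consumption", {
  chain <- init_chain(sc)
  in_zone <- chain$pois$kind == "store" & chain$pois$zone_id == "75216"
  chain$pois$shelf_stock[in_zone] <- 20L
  env <- list(chain = chain, scenario = sc, day = 2, hour = 10)
  twins <- mk_household(supply = 1, infants = 2L)
  r <- execute_action(twins, "visit_store", env, list(hh_001 = twins))
  expect_equal(r$household$supply_days, 1 + r$outcome$units / 2)

  expect_equal(consume_daily(mk_household(supply = 5))$supply_days, 4)
  expect_equal(consume_daily(mk_household(supply = 5,
                                          infants = 2L))$supply_days, 3)
  out <- consume_daily(mk_household(supply = 0.5))
  expect_equal(out$supply_days, 0)
  expect_true(out$critical)
})

test_that("food bank serves the neediest first within its stock", {
  chain <- init_chain(sc)
  fb <- chain$pois$kind == "food_bank"
  chain$pois$shelf_stock[fb] <- 0L
  chain$pois$shelf_stock[which(fb & chain$pois$zone_id == "75216")] <- 4L

  a <- mk_household(id = "hh_a", supply = 0, infants = 2L)
  b <- mk_household(id = "hh_b", supply = 0, infants = 1L)
  hhs <- list(hh_a = a, hh_b = b)
  res <- foodbank_step(chain, hhs, day = 3)
  expect_identical(res$distributions$household_id, "hh_a")
  expect_identical(res$distributions$units, 4L)
  expect_equal(res$households$hh_a$supply_days, 2)  # 4 units / 2 infants
  expect_equal(res$households$hh_b$supply_days, 0)

  rich <- list(hh_a = mk_household(id = "hh_a", supply = 6))
  expect_identical(nrow(foodbank_step(chain, rich, day = 3)$distributions),
                   0L)
})

test_that("health system and policy program react to shortage severity", {
  chain <- init_chain(sc)  # shelves at 35% of baseline: no panic anywhere
  hh <- list(hh_001 = mk_household(supply = 1))
  calm <- health_system_step(chain, hh, day = 2)
  expect_false(calm$chain$crisis_active)
  expect_identical(nrow(calm$samples), 0L)
  expect_false(policy_step(chain, day = 2)$broadcast_today)

  bare <- chain
  bare$pois$shelf_stock[bare$pois$kind %in% c("store", "wic_vendor")] <- 0L
  crisis <- health_system_step(bare, hh, day = 2)
  expect_true(crisis$chain$crisis_active)
  expect_identical(sum(crisis$samples$units), 1L)
  clinic_stock <- sum(chain$pois$shelf_stock[chain$pois$kind == "clinic" &
                                               chain$pois$zone_id == "75216"])
  expect_lte(sum(crisis$samples$units), clinic_stock)
  expect_true(policy_step(bare, day = 2)$broadcast_today)
})

test_that("failure cues steer theory agents toward support channels", {
  hh <- mk_household(supply = 1, wic = TRUE)
  support <- c("seek_social_help", "visit_food_bank", "contact_wic_vendor")
  run_cycle <- function(cue_on) {
    b <- initial_beliefs()
    picks <- character(10)
    for (day in 1:10) {
      cues <- empty_cues()
      cues$declining_supply <- TRUE
      if (cue_on) {
        cues$store_stockout_observed <- TRUE
        cues$peer_success_via_support <- TRUE
        cues$own_failed_strategy[["visit_store"]] <- TRUE
      }
      b <- update_beliefs(b, cues)
      s <- compute_intentions(apply_trait_modifiers(b, hh$traits), cues, hh)
      picks[day] <- select_action(s)
    }
    mean(picks %in% support)
  }
  expect_gt(run_cycle(TRUE), run_cycle(FALSE))
})
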