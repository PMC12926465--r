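# Condition-blind vignette rendering and counterbalanced presentation
# orders. Raters must not be able to tell which agent design produced a
# narrative, so rendering is template-based and every rendered text is
# scanned against a banned-term list before release.

#' Terms that must never appear in rendered vignette text
#'
#' Lower-case substrings covering the behavioral-theory vocabulary and the
#' condition labels; [make_vignette()] fails hard if any of them appears in
#' a rendered narrative.
#'
#' @return character vector.
#' @export
banned_vignette_terms <- function() {
  c("theory", "theoretical", "belief", "desire", "intention", "construct",
    "hbm", "tpb", "sct", "bdi", "efficacy", "subjective norm", "perceived",
    "observational", "reinforcement", "heuristic", "rule-based", "utility",
    "trait", "baseline", "condition", "agent type")
}

sentence_for <- function(row) {
  u <- row$units
  ok <- isTRUE(row$success)
  switch(row$action,
    visit_store = if (ok) {
      if (row$reason == "purchased_wic")
        sprintf("used WIC vouchers to pick up %d cans of formula at a nearby store", u)
      else sprintf("bought %d cans of formula at a nearby store", u)
    } else switch(row$reason,
      stockout = "went to a nearby store but found the formula shelves empty",
      closed = "set out to buy formula but the local store was closed",
      wic_ineligible = "found formula at a nearby store but none of the brands on the shelf were covered by WIC vouchers",
      "found formula at a nearby store but could not afford it"),
    travel_far_store = if (ok) {
      sprintf("made a longer trip to a store in another neighborhood and bought %d cans", u)
    } else switch(row$reason,
      stockout = "traveled to a store in another neighborhood but found no formula there either",
      no_transport = "wanted to try a store farther away but had no way to get there",
      "made a longer trip to another neighborhood but came back empty-handed"),
    contact_wic_vendor = if (ok) {
      sprintf("used WIC vouchers to collect %d cans from an approved vendor", u)
    } else switch(row$reason,
      wic_ineligible = "contacted a WIC vendor but none of the brands in stock were covered",
      not_enrolled = "asked about WIC formula but the household is not enrolled in the program",
      stockout = "contacted a WIC vendor whose shelves were empty",
      "could not reach an open WIC vendor"),
    seek_social_help = if (ok) {
      if (row$reason == "peer_transfer")
        "received a couple of spare cans from a friend nearby"
      else "tracked down a can of formula through a neighborhood group"
    } else "asked friends and family for help, but nobody had formula to spare",
    search_online = if (ok) {
      sprintf("ordered %d cans online at a marked-up price", u)
    } else if (row$reason == "unaffordable")
      "searched online but every listing was too expensive"
    else "searched online but every seller was out of stock",
    visit_food_bank = if (ok) {
      "received an emergency supply of formula from a food bank"
    } else switch(row$reason,
      stockout = "went to a food bank that had already run out of formula",
      not_eligible = "visited a food bank but was told supplies were being held for families who had completely run out",
      "went to a food bank but it was closed"),
    wait = "decided to wait and stretch the remaining supply",
    "spent the day at home")
}

#' Render a condition-blind vignette from an event log
#'
#' Deterministic, template-based rendering of one agent's 14-day action
#' record into a day-by-day narrative, together with a structured summary
#' (per-action success/failure counts and final supply). The condition is
#' kept in the object but never rendered; the text is scanned against
#' [banned_vignette_terms()] and rendering fails hard on any hit.
#'
#' @param log a `framesim_eventlog`.
#' @param agent_id household id present in the log.
#' @param vignette_id identifier for the vignette (defaults to the agent
#'   id).
#' @return a `framesim_vignette` list: `vignette_id`, `agent_id`,
#'   `condition`, `text`, `structured_summary`.
#' @export
make_vignette <- function(log, agent_id, vignette_id = agent_id) {
  rows <- log[log$agent_id == agent_id, , drop = FALSE]
  if (!nrow(rows))
    stopf("agent '%s' not present in the log", agent_id)
  rows <- rows[order(rows$day), , drop = FALSE]
  lines <- vapply(seq_len(nrow(rows)), function(i)
    sprintf("Day %d: the household %s.", rows$day[i],
            sentence_for(rows[i, ])), character(1))
  text <- paste0(
    "During a two-week infant formula shortage, one household with a young ",
    "infant kept trying to keep enough formula at home.\n",
    paste(lines, collapse = "\n"),
    sprintf("\nAt the end of the two weeks the household had about %.0f day%s of formula left.",
            rows$supply_days_after[nrow(rows)],
            if (round(rows$supply_days_after[nrow(rows)]) == 1) "" else "s"))
  hits <- banned_vignette_terms()[vapply(banned_vignette_terms(),
                                         function(tm) grepl(tm, tolower(text),
                                                            fixed = TRUE),
                                         logical(1))]
  if (length(hits))
    stopf("rendered vignette contains banned term(s): %s",
          paste(hits, collapse = ", "),
          class = "framesim_blinding_error")
  summary <- as.data.frame(table(action = rows$action,
                                 success = rows$success),
                           stringsAsFactors = FALSE)
  summary <- summary[summary$Freq > 0, , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(
    vignette_id = vignette_id,
    agent_id = agent_id,
    condition = rows$condition[1],
    text = text,
    structured_summary = list(
      counts = summary,
      final_supply_days = rows$supply_days_after[nrow(rows)])
  ), class = "framesim_vignette")
}

#' @export
print.framesim_vignette <- function(x, ...) {
  cat(sprintf("<framesim_vignette> %s (agent %s)\n", x$vignette_id,
              x$agent_id))
  cat(x$text, "\n")
  invisible(x)
}

#' Counterbalanced vignette presentation orders
#'
#' Builds a cyclic Latin square on the eight vignettes (its symbol order
#' shuffled by the seed) and assigns its rows to participants round-robin.
#' Every participant sees all eight vignettes (four per condition); when
#' the number of participants is a multiple of eight, every vignette
#' occupies every position equally often, and otherwise the
#' (vignette, position) counts are maximally balanced (they differ by at
#' most one).
#'
#' @param n_participants number of raters.
#' @param vignettes data frame with columns `vignette_id` and `condition`;
#'   exactly eight rows, four per condition.
#' @param seed integer seed (shuffles the Latin-square symbol order).
#' @return a `framesim_plan` data frame: `participant`, `position`,
#'   `vignette_id`.
#' @export
assign_orders <- function(n_participants, vignettes, seed = 1L) {
  if (nrow(vignettes) != 8 ||
      length(unique(vignettes$condition)) != 2 ||
      any(table(vignettes$condition) != 4))
    stopf("vignette set must contain exactly 8 vignettes, 4 per condition",
          class = "framesim_config_error")
  ids <- with_seed(hash_seed(seed, "orders"),
                   sample(vignettes$vignette_id))
  base <- t(vapply(1:8, function(r) ids[((seq_len(8) + r - 2L) %% 8L) + 1L],
                   character(8)))
  plan <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    data.frame(participant = p, position = 1:8,
               vignette_id = base[((p - 1L) %% 8L) + 1L, ],
               stringsAsFactors = FALSE)
  }))
  class(plan) <- c("framesim_plan", "data.frame")
  plan
}
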