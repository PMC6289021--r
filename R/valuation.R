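# Valuation: baseline utility trajectory, event disutilities, state
# utilities/costs, discounting, and total discounted outcomes.

EQ5D_MIN <- -0.594
DAYS_PER_YEAR <- 365.25

#' Baseline utility on a given post-operative day
#'
#' Quality of life recovers linearly from the pre-operative utility at
#' surgery to the post-operative value attained at nine months (day 270),
#' and is constant thereafter within the first year.
#'
#' @param day Day offset from surgery, `>= 0`.
#' @param inputs A `vte_inputs` object (uses `utilities$preop_utility` and
#'   `utilities$post_9mo_utility`).
#' @return EQ-5D index value.
#' @export
baseline_utility <- function(day, inputs) {
  u0 <- inputs$utilities$preop_utility
  u9 <- inputs$utilities$post_9mo_utility
  pmin(u0 + pmin(day, 270) / 270 * (u9 - u0), u9)
}

#' Discount factor at a point in time
#'
#' Costs and outcomes accrued beyond the first year are discounted at the
#' annual rate; the first year is undiscounted.
#'
#' @param t Time in years since surgery, `>= 0`.
#' @param rate Annual discount rate.
#' @return Discount factor in `(0, 1]`.
#' @export
discount_factor <- function(t, rate) {
  ifelse(t <= 1, 1, (1 + rate)^(-(t - 1)))
}

# Acute disutility rules: event day (PE kinds day 21, others day 7), mode
# and value. The default window runs from the event day to day 90. Treated
# VTE events also carry the warfarin-arm decrement (50% of treated).
acute_disutility_rules <- function(inputs) {
  d <- inputs$disutility
  warf <- d$abs_warfarin_treated * 0.5
  rules <- list(
    none = list(day = NA, mode = "none", value = 0),
    sympt_prox_dvt = list(day = 7, mode = "rel", value = d$rel_sympt_prox_dvt, extra_abs = warf),
    sympt_dist_dvt = list(day = 7, mode = "rel", value = d$rel_sympt_dist_dvt, extra_abs = warf),
    nonfatal_pe = list(day = 21, mode = "rel", value = d$rel_nonfatal_pe, extra_abs = warf),
    fatal_pe = list(day = 21, mode = "death"),
    ssb_return_theatre = list(day = 7, mode = "rel", value = d$rel_major_bleed),
    gi_bleed_intervention = list(day = 7, mode = "rel", value = d$rel_major_bleed),
    gi_bleed_medical = list(day = 7, mode = "rel", value = d$rel_major_bleed),
    ich_stroke = list(day = 7, mode = "rel", value = d$rel_ich_stroke),
    other_mb = list(day = 7, mode = "rel", value = d$rel_major_bleed),
    fatal_mb = list(day = 7, mode = "death"),
    crnmb_medical = list(day = 7, mode = "abs", value = d$abs_crnmb),
    wound_haematoma = list(day = 7, mode = "abs", value = d$abs_crnmb),
    ssi_medical = list(day = 7, mode = "rel", value = d$rel_ssi),
    ssi_return_theatre = list(day = 7, mode = "rel", value = d$rel_ssi),
    ssi_revision = list(day = 7, mode = "rel", value = d$rel_ssi),
    hit_success = list(day = 7, mode = "abs", value = d$abs_hit),
    hit_thrombosis_dvt = list(day = 7, mode = "rel", value = d$rel_hit_thrombosis, extra_abs = warf),
    hit_thrombosis_pe = list(day = 21, mode = "rel", value = d$rel_hit_thrombosis, extra_abs = warf),
    hit_mb = list(day = 7, mode = "rel", value = d$rel_major_bleed),
    hit_death = list(day = 7, mode = "death"),
    hit_amputation = list(day = 7, mode = "abs", value = d$abs_post_amputation)
  )
  rules
}

# Expected QALYs over days 0-90 for each event kind: daily midpoint grid on
# the baseline trajectory with the event's disutility applied from its event
# day, floored at the EQ-5D minimum.
acute_event_qalys <- function(inputs) {
  days <- seq(0.5, 89.5, by = 1)
  base <- baseline_utility(days, inputs)
  rules <- acute_disutility_rules(inputs)
  vapply(names(rules), function(kind) {
    r <- rules[[kind]]
    u <- base
    if (r$mode != "none") {
      hit <- days >= r$day
      u[hit] <- switch(r$mode,
        rel = base[hit] * (1 - r$value),
        abs = base[hit] - r$value,
        death = 0)
      if (!is.null(r$extra_abs)) u[hit] <- u[hit] - r$extra_abs
      u <- pmax(u, EQ5D_MIN)
      if (r$mode == "death") u[hit] <- 0
    }
    sum(u) / DAYS_PER_YEAR
  }, numeric(1))
}

# Acute event cost per event kind (diagnosis, treatment, procedures);
# fatal events are charged nothing.
acute_event_costs <- function(inputs) {
  ec <- inputs$event_costs
  c(none = 0,
    sympt_prox_dvt = ec$sympt_prox_dvt,
    sympt_dist_dvt = ec$sympt_dist_dvt,
    nonfatal_pe = ec$nonfatal_pe,
    fatal_pe = 0,
    ssb_return_theatre = ec$ssb_return_theatre,
    gi_bleed_intervention = ec$gi_bleed_intervention,
    gi_bleed_medical = ec$gi_bleed_medical,
    ich_stroke = ec$stroke_admission + ec$stroke_acute_90d,
    other_mb = ec$other_mb,
    fatal_mb = 0,
    crnmb_medical = ec$crnmb,
    wound_haematoma = ec$crnmb,
    ssi_medical = ec$crnmb + ec$ssi_medical,
    ssi_return_theatre = ec$crnmb + ec$ssb_return_theatre,
    ssi_revision = ec$crnmb + ec$ssi_revision,
    hit_success = ec$hit,
    hit_thrombosis_dvt = ec$hit + ec$sympt_prox_dvt,
    hit_thrombosis_pe = ec$hit + ec$nonfatal_pe,
    hit_mb = ec$hit + ec$other_mb,
    hit_death = ec$hit,
    hit_amputation = ec$hit + ec$amputation_acute)
}

acute_cost_category <- function() c(
  none = "other", sympt_prox_dvt = "vte", sympt_dist_dvt = "vte",
  nonfatal_pe = "vte", fatal_pe = "vte", ssb_return_theatre = "bleeding",
  gi_bleed_intervention = "bleeding", gi_bleed_medical = "bleeding",
  ich_stroke = "bleeding", other_mb = "bleeding", fatal_mb = "bleeding",
  crnmb_medical = "bleeding", wound_haematoma = "bleeding",
  ssi_medical = "bleeding", ssi_return_theatre = "bleeding",
  ssi_revision = "bleeding", hit_success = "bleeding",
  hit_thrombosis_dvt = "bleeding", hit_thrombosis_pe = "bleeding",
  hit_mb = "bleeding", hit_death = "bleeding", hit_amputation = "amputation")

#' Expected discounted QALYs accrued over the 90-day acute phase
#'
#' Sums, over terminal branches, the integral of the baseline recovery
#' trajectory with each branch's event disutility applied from its event day
#' (day 7 for DVT and bleeding events, day 21 for PE) to day 90. All acute
#' flows fall inside the first year and are undiscounted.
#'
#' @param tree Branch table from [build_acute_tree()].
#' @param inputs A `vte_inputs` object.
#' @return Expected QALYs over days 0-90.
#' @export
acute_qalys <- function(tree, inputs) {
  q <- acute_event_qalys(inputs)
  sum(tree$prob * q[tree$event])
}

#' Evaluate the acute phase for one strategy
#'
#' @param inputs A `vte_inputs` object.
#' @param strategy Strategy slug.
#' @return A `vte_acute` object: branch table, per-1,000 tallies,
#'   undiscounted acute cost (intervention plus events) and QALYs, Markov
#'   entry distribution, 90-day death probability and an acute cost
#'   breakdown by category.
#' @export
run_acute <- function(inputs, strategy) {
  tree <- build_acute_tree(inputs, strategy)
  costs <- acute_event_costs(inputs)
  cat_of <- acute_cost_category()
  ev_cost <- tree$prob * costs[tree$event]
  breakdown <- tapply(ev_cost, cat_of[tree$event], sum)
  out <- c(prophylaxis = strategy_total_cost(strategy, inputs),
           vte = 0, bleeding = 0, amputation = 0)
  bn <- intersect(names(breakdown), names(out))
  out[bn] <- out[bn] + breakdown[bn]
  entry <- entry_distribution(tree)
  structure(list(
    strategy = strategy,
    branch_table = tree,
    tallies_per_1000 = tally_events(tree),
    acute_cost = sum(out),
    acute_cost_breakdown = out,
    acute_qalys = acute_qalys(tree, inputs),
    entry_distribution = entry,
    deaths_90d = unname(entry["dead"])
  ), class = "vte_acute")
}

# Per-state annual utility and cost vectors for a cycle. Cycle 0 (the first
# Markov year) uses the mean of the recovery trajectory over days 90-455 and
# year-1 stroke/amputation costs prorated for the 90 days already valued in
# the acute phase; later cycles use the settled 9-month utility and year-2+
# costs.
state_values <- function(inputs, cycle_index) {
  S <- markov_states()
  u9 <- inputs$utilities$post_9mo_utility
  u0 <- inputs$utilities$preop_utility
  if (cycle_index == 0L) {
    u90 <- baseline_utility(90, inputs)
    base <- ((u90 + u9) / 2 * 180 + u9 * (DAYS_PER_YEAR - 90 - 180)) /
      (DAYS_PER_YEAR - 90) # mean over the first Markov year (days 90-455)
    prorate <- (DAYS_PER_YEAR - 90) / DAYS_PER_YEAR
  } else {
    base <- u9
    prorate <- 1
  }
  su <- inputs$state_utility
  cteph_y1_u <- base * (1 - su$rel_cteph_y1)
  cteph_later_u <- min(cteph_y1_u * (1 + su$rel_cteph_improvement), base)
  utility <- stats::setNames(rep(base, length(S)), S)
  utility["pts_mildmod_y1"] <- utility["pts_mildmod_chronic"] <- base - su$abs_pts_mildmod
  utility["pts_severe_y1"] <- utility["pts_severe_chronic"] <- base - su$abs_pts_severe
  utility["cteph_y1"] <- cteph_y1_u
  utility[c("cteph_recurrent_y2", "cteph_chronic", "cteph_treated")] <- cteph_later_u
  utility["disabled_post_stroke"] <- base * (1 - su$rel_post_stroke)
  utility["amputated_post_hit"] <- base - inputs$disutility$abs_post_amputation
  utility["dead"] <- 0
  utility <- pmin(pmax(utility, EQ5D_MIN), 1)
  utility["dead"] <- 0
  sc <- inputs$state_costs
  lt <- inputs$long_term
  w <- sc$prop_stroke_dependent
  stroke_y1 <- w * sc$stroke_y1_dependent + (1 - w) * sc$stroke_y1_independent
  stroke_y2 <- w * sc$stroke_y2_dependent + (1 - w) * sc$stroke_y2_independent
  cteph_y1_cost <- lt$cteph_w_operable * sc$cteph_operable_y1 +
    lt$cteph_w_inoperable * sc$cteph_inoperable_y1 +
    lt$cteph_w_recurrent * sc$cteph_recurrent_y1
  cost <- stats::setNames(numeric(length(S)), S)
  cost["pts_mildmod_y1"] <- sc$pts_mildmod_y1
  cost["pts_mildmod_chronic"] <- sc$pts_mildmod_y2
  cost["pts_severe_y1"] <- sc$pts_severe_y1
  cost["pts_severe_chronic"] <- sc$pts_severe_y2
  cost["cteph_y1"] <- cteph_y1_cost
  cost["cteph_recurrent_y2"] <- sc$cteph_recurrent_y2
  cost["cteph_chronic"] <- sc$cteph_chronic_y2
  cost["cteph_treated"] <- sc$cteph_treated
  cost["disabled_post_stroke"] <- if (cycle_index == 0L) stroke_y1 * prorate else stroke_y2
  cost["amputated_post_hit"] <- if (cycle_index == 0L) sc$amputation_y1 * prorate else sc$amputation_y2
  list(utility = utility, cost = cost)
}

#' Annual utility and cost of a Markov state
#'
#' @param state A state from [markov_states()].
#' @param years_since_entry Whole years since entry to the Markov model
#'   (0 = first cycle).
#' @param inputs A `vte_inputs` object.
#' @return Named list with `utility` (annual EQ-5D weight) and `cost`
#'   (annual GBP).
#' @export
state_value <- function(state, years_since_entry, inputs) {
  if (!state %in% markov_states()) stop("unknown state: ", state)
  v <- state_values(inputs, cycle_index = if (years_since_entry < 1) 0L else 1L)
  list(utility = unname(v$utility[state]), cost = unname(v$cost[state]))
}

markov_cost_category <- function() {
  cats <- stats::setNames(rep("other", length(markov_states())), markov_states())
  cats[c("pts_mildmod_y1", "pts_severe_y1", "pts_mildmod_chronic",
         "pts_severe_chronic")] <- "pts"
  cats[c("cteph_y1", "cteph_recurrent_y2", "cteph_chronic", "cteph_treated")] <- "cteph"
  cats["disabled_post_stroke"] <- "bleeding"
  cats["amputated_post_hit"] <- "amputation"
  cats
}

#' Total discounted outcomes for one strategy
#'
#' Combines the acute-phase and Markov flows into total discounted QALYs and
#' costs, with a per-category cost breakdown (prophylaxis, VTE treatment,
#' bleeding including stroke sequelae, CTEPH, PTS, post-amputation).
#'
#' @param acute A `vte_acute` object.
#' @param trace A `vte_trace` object for the same strategy.
#' @param inputs A `vte_inputs` object.
#' @return Named list with `qalys`, `costs` and `cost_breakdown`.
#' @export
total_outcomes <- function(acute, trace, inputs) {
  qalys <- acute$acute_qalys + sum(trace$dqaly)
  costs <- acute$acute_cost + sum(trace$dcost)
  cats <- markov_cost_category()
  r <- inputs$settings$discount_rate
  k <- seq_len(trace$n_cycles) - 1L
  df <- (1 + r)^(-k)
  cost0 <- state_values(inputs, 0L)$cost
  cost1 <- state_values(inputs, 1L)$cost
  costmat <- rbind(cost0, matrix(cost1, trace$n_cycles - 1L,
                                 length(cost1), byrow = TRUE))
  dstate <- colSums(trace$occupancy * costmat * df)
  markov_by_cat <- tapply(dstate, cats[markov_states()], sum)
  bk <- c(prophylaxis = unname(acute$acute_cost_breakdown["prophylaxis"]),
          vte = unname(acute$acute_cost_breakdown["vte"]),
          bleeding = unname(acute$acute_cost_breakdown["bleeding"]) +
            unname(markov_by_cat["bleeding"]),
          cteph = unname(markov_by_cat["cteph"]),
          pts = unname(markov_by_cat["pts"]),
          amputation = unname(acute$acute_cost_breakdown["amputation"]) +
            unname(markov_by_cat["amputation"]))
  list(qalys = qalys, costs = costs, cost_breakdown = bk)
}
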