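# Lifetime annual-cycle Markov cohort model from day 90 onwards.

#' Markov health states
#'
#' Ordered state space of the long-term model. `pts_*_y1`, `cteph_y1` and
#' `cteph_recurrent_y2` are tunnel states (one-cycle residency); `dead` is
#' absorbing.
#' @return Character vector of state names.
#' @export
markov_states <- function() c(
  "well", "post_sympt_prox_dvt", "post_sympt_dist_dvt",
  "post_asympt_prox_dvt", "post_asympt_dist_dvt", "post_pe",
  "pts_mildmod_y1", "pts_severe_y1", "pts_mildmod_chronic",
  "pts_severe_chronic", "cteph_y1", "cteph_recurrent_y2", "cteph_chronic",
  "cteph_treated", "disabled_post_stroke", "amputated_post_hit",
  "post_revision_infection", "dead")

#' Convert a probability over a period to a constant annual rate
#'
#' @param P Probability of the event over `t` years, in `[0, 1)`.
#' @param t Period length in years.
#' @return Annual rate `-log(1 - P) / t`.
#' @export
rate_from_probability <- function(P, t) {
  stopifnot(all(P >= 0), t > 0)
  if (any(P >= 1)) stop("P = 1 implies an infinite rate")
  -log(1 - P) / t
}

#' Convert a constant annual rate to a probability over a period
#'
#' Inverse of [rate_from_probability()] for matching `t`.
#'
#' @param r Annual rate, `>= 0`.
#' @param t Period length in years.
#' @return Probability `1 - exp(-r * t)`.
#' @export
probability_from_rate <- function(r, t) {
  stopifnot(all(r >= 0), t > 0)
  1 - exp(-r * t)
}

# Per-cycle onset probability such that two cycles compose to the stated
# two-year incidence: 1 - (1 - p)^2 = P2.
annualise_2yr <- function(P2) probability_from_rate(rate_from_probability(P2, 2), 1)

lookup_qx <- function(life_table, age) {
  i <- pmin(pmax(round(age) - life_table$age[1] + 1L, 1L), nrow(life_table))
  life_table$qx[i]
}

state_index <- function(nm) match(nm, markov_states())

# Live-transition structure (before background mortality). Two shapes: one
# for the PTS/CTEPH onset window (first two cycles) and one for later
# cycles. CTEPH mortality in the cteph_y1 tunnel is handled separately in
# build_transition_matrix.
live_transition_matrix <- function(inputs, onset_window) {
  S <- markov_states()
  n <- length(S)
  M <- diag(n)
  dimnames(M) <- list(S, S)
  lt <- inputs$long_term
  if (onset_window) {
    onset <- c(post_sympt_prox_dvt = lt$pts_2yr_sympt_prox,
               post_sympt_dist_dvt = lt$pts_2yr_sympt_dist,
               post_asympt_prox_dvt = lt$pts_2yr_asympt_prox,
               post_asympt_dist_dvt = lt$pts_2yr_asympt_dist)
    for (s in names(onset)) {
      p <- annualise_2yr(onset[[s]])
      M[s, s] <- 1 - p
      M[s, "pts_severe_y1"] <- p * lt$prop_pts_severe
      M[s, "pts_mildmod_y1"] <- p * (1 - lt$prop_pts_severe)
    }
    # post-PE: CTEPH onset takes precedence over PTS onset
    p_c <- annualise_2yr(lt$cteph_2yr_after_pe)
    p_p <- annualise_2yr(lt$pts_2yr_pe) * (1 - p_c)
    M["post_pe", "post_pe"] <- 1 - p_c - p_p
    M["post_pe", "cteph_y1"] <- p_c
    M["post_pe", "pts_severe_y1"] <- p_p * lt$prop_pts_severe
    M["post_pe", "pts_mildmod_y1"] <- p_p * (1 - lt$prop_pts_severe)
  }
  # tunnel exits
  M["pts_mildmod_y1", "pts_mildmod_y1"] <- 0
  M["pts_mildmod_y1", "pts_mildmod_chronic"] <- 1
  M["pts_severe_y1", "pts_severe_y1"] <- 0
  M["pts_severe_y1", "pts_severe_chronic"] <- 1
  M["cteph_y1", "cteph_y1"] <- 0
  M["cteph_y1", "cteph_treated"] <- lt$cteph_w_operable
  M["cteph_y1", "cteph_chronic"] <- lt$cteph_w_inoperable
  M["cteph_y1", "cteph_recurrent_y2"] <- lt$cteph_w_recurrent
  M["cteph_recurrent_y2", "cteph_recurrent_y2"] <- 0
  M["cteph_recurrent_y2", "cteph_chronic"] <- 1
  if (any(M < -1e-12))
    stop("negative residual self-transition: competing risks over-specified")
  M
}

#' Build the annual transition matrix for one cycle
#'
#' Applies the live-transition structure (PTS/CTEPH onset restricted to the
#' first two cycles, tunnel-state exits) and overlays age-indexed background
#' mortality on every state, with the one-time CTEPH case fatality competing
#' multiplicatively in the `cteph_y1` tunnel.
#'
#' @param inputs A `vte_inputs` object.
#' @param cycle_index Zero-based cycle counter (cycle 0 is the first year
#'   after the 90-day acute phase).
#' @param current_age Cohort age in years at the start of the cycle.
#' @return A row-stochastic matrix over [markov_states()].
#' @export
build_transition_matrix <- function(inputs, cycle_index, current_age) {
  M <- live_transition_matrix(inputs, onset_window = cycle_index < 2)
  q <- lookup_qx(inputs$life_table, current_age)
  apply_mortality(M, q, inputs$long_term$cteph_mortality)
}

apply_mortality <- function(M, q, cteph_mortality) {
  live <- setdiff(rownames(M), "dead")
  Mq <- M
  Mq[live, ] <- M[live, ] * (1 - q)
  Mq[live, "dead"] <- M[live, "dead"] * (1 - q) + q
  surv <- (1 - q) * (1 - cteph_mortality)
  Mq["cteph_y1", ] <- M["cteph_y1", ] * surv
  Mq["cteph_y1", "dead"] <- M["cteph_y1", "dead"] * surv + (1 - surv)
  Mq
}

#' Run the cohort simulation from the Markov entry distribution
#'
#' Iterates annual cycles from age `start_age + 90/365.25` until the life
#' table's terminal age (or a finite horizon), accruing per-cycle utilities
#' and costs valued by [state_value()] and discounted beyond the first year.
#' Occupancy is recorded at the start of each cycle (the entry distribution
#' accrues a full first cycle) and the transition is applied at cycle end.
#'
#' @param entry Named probability vector over [markov_states()], summing to
#'   at most 1 (any remainder is assigned to `dead`).
#' @param inputs A `vte_inputs` object.
#' @param horizon_years Optional finite horizon in years; default lifetime.
#' @return A `vte_trace` object: occupancy matrix (cycle by state) plus
#'   per-cycle undiscounted and discounted cost and QALY vectors.
#' @export
run_cohort <- function(entry, inputs, horizon_years = NULL) {
  S <- markov_states()
  occ0 <- stats::setNames(numeric(length(S)), S)
  occ0[names(entry)] <- entry
  if (sum(occ0) > 1 + 1e-9) stop("entry distribution sums to more than 1")
  occ0["dead"] <- occ0["dead"] + (1 - sum(occ0))
  age0 <- inputs$cohort$start_age + 90 / 365.25
  terminal <- max(inputs$life_table$age)
  K <- ceiling(terminal - age0) + 1L
  if (!is.null(horizon_years)) {
    if (horizon_years < 1) stop("horizon shorter than one cycle")
    K <- min(K, as.integer(floor(horizon_years)))
  }
  r <- inputs$settings$discount_rate
  vals0 <- state_values(inputs, cycle_index = 0L)
  vals1 <- state_values(inputs, cycle_index = 1L)
  occ <- matrix(0, K, length(S), dimnames = list(NULL, S))
  cost <- qaly <- dcost <- dqaly <- numeric(K)
  cur <- occ0
  M_on <- NULL
  M_off <- NULL
  for (k in seq_len(K) - 1L) {
    occ[k + 1L, ] <- cur
    v <- if (k == 0L) vals0 else vals1
    cost[k + 1L] <- sum(cur * v$cost)
    qaly[k + 1L] <- sum(cur * v$utility)
    df <- (1 + r)^(-k)
    dcost[k + 1L] <- cost[k + 1L] * df
    dqaly[k + 1L] <- qaly[k + 1L] * df
    q <- lookup_qx(inputs$life_table, age0 + k)
    if (k < 2) {
      if (is.null(M_on)) M_on <- live_transition_matrix(inputs, TRUE)
      M <- apply_mortality(M_on, q, inputs$long_term$cteph_mortality)
    } else {
      if (is.null(M_off)) M_off <- live_transition_matrix(inputs, FALSE)
      M <- apply_mortality(M_off, q, inputs$long_term$cteph_mortality)
    }
    cur <- as.vector(cur %*% M)
    names(cur) <- S
  }
  structure(list(occupancy = occ, cost = cost, qaly = qaly,
                 dcost = dcost, dqaly = dqaly,
                 age = age0 + seq_len(K) - 1L, n_cycles = K),
            class = "vte_trace")
}

#' @export
print.vte_trace <- function(x, ...) {
  cat("<vte_trace>", x$n_cycles, "annual cycles | discounted QALYs",
      round(sum(x$dqaly), 3), "| discounted costs", round(sum(x$dcost)), "\n")
  invisible(x)
}
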