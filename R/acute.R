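# 90-day decision tree: four independent event arms (VTE, major bleeding,
# CRNMB, HIT) combined into mutually exclusive terminal branches under the
# one-symptomatic-event rule.

.vtecea_cache <- new.env(parent = emptyenv())

# Arm outcome categories. Order matters: it defines the combination grid.
vte_arm <- c("v_none", "asympt_dist_dvt", "asympt_prox_dvt",
             "sympt_dist_dvt", "sympt_prox_dvt", "nonfatal_pe", "fatal_pe")
bleed_arm <- c("b_none", "ssb_return_theatre", "gi_bleed_intervention",
               "gi_bleed_medical", "ich_stroke", "other_mb", "fatal_mb")
crnmb_arm <- c("c_none", "crnmb_medical", "wound_haematoma", "ssi_medical",
               "ssi_return_theatre", "ssi_revision")
hit_arm <- c("h_none", "hit_success", "hit_thrombosis_dvt",
             "hit_thrombosis_pe", "hit_mb", "hit_death", "hit_amputation")

#' Acute event kinds recognised by the decision tree
#' @return Character vector of terminal event kinds (excluding the
#'   co-occurring asymptomatic DVT attribute).
#' @export
acute_event_kinds <- function() c(
  "none", "sympt_prox_dvt", "sympt_dist_dvt", "nonfatal_pe", "fatal_pe",
  "ssb_return_theatre", "gi_bleed_intervention", "gi_bleed_medical",
  "ich_stroke", "other_mb", "fatal_mb", "crnmb_medical", "wound_haematoma",
  "ssi_medical", "ssi_return_theatre", "ssi_revision", "hit_success",
  "hit_thrombosis_dvt", "hit_thrombosis_pe", "hit_mb", "hit_death",
  "hit_amputation")

# Priority classes for the one-symptomatic-event rule: fatal > PE >
# symptomatic DVT (amputation above DVT) > major bleeding > CRNMB > benign
# HIT. Asymptomatic DVT and "none" carry no priority and always co-exist.
event_priority <- function(kind) {
  pr <- c(none = 0,
          sympt_prox_dvt = 3, sympt_dist_dvt = 3, nonfatal_pe = 4,
          fatal_pe = 5, ssb_return_theatre = 2, gi_bleed_intervention = 2,
          gi_bleed_medical = 2, ich_stroke = 2, other_mb = 2, fatal_mb = 5,
          crnmb_medical = 1, wound_haematoma = 1, ssi_medical = 1,
          ssi_return_theatre = 1, ssi_revision = 1, hit_success = 0.5,
          hit_thrombosis_dvt = 3, hit_thrombosis_pe = 4, hit_mb = 2,
          hit_death = 5, hit_amputation = 3.5)
  unname(pr[kind])
}

arm_event <- function(cat) {
  # map an arm category to its terminal event kind ("none" for the benign
  # and asymptomatic categories)
  ifelse(cat %in% c("v_none", "b_none", "c_none", "h_none",
                    "asympt_dist_dvt", "asympt_prox_dvt"), "none", cat)
}

# Static combination grid: indices into the four arm probability vectors and
# the aggregation matrix mapping joint outcomes to resolved branches.
tree_structure <- function() {
  if (!is.null(.vtecea_cache$tree)) return(.vtecea_cache$tree)
  grid <- expand.grid(iv = seq_along(vte_arm), ib = seq_along(bleed_arm),
                      ic = seq_along(crnmb_arm), ih = seq_along(hit_arm),
                      KEEP.OUT.ATTRS = FALSE)
  ev <- cbind(arm_event(vte_arm[grid$iv]), arm_event(bleed_arm[grid$ib]),
              arm_event(crnmb_arm[grid$ic]), arm_event(hit_arm[grid$ih]))
  pr <- matrix(event_priority(ev), ncol = 4L)
  # highest priority wins; ties resolve in arm order (VTE first)
  win <- max.col(pr, ties.method = "first")
  resolved <- ev[cbind(seq_len(nrow(ev)), win)]
  resolved[pr[cbind(seq_len(nrow(ev)), win)] == 0] <- "none"
  asympt <- ifelse(vte_arm[grid$iv] == "asympt_prox_dvt", "prox",
                   ifelse(vte_arm[grid$iv] == "asympt_dist_dvt", "dist", "none"))
  branches <- expand.grid(event = acute_event_kinds(),
                          asympt = c("none", "dist", "prox"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gid <- match(paste(resolved, asympt), paste(branches$event, branches$asympt))
  G <- matrix(0, nrow(branches), nrow(grid))
  G[cbind(gid, seq_len(nrow(grid)))] <- 1
  # branch -> Markov entry state aggregation matrix (see entry_distribution)
  st <- branch_entry_states(branches)
  E <- matrix(0, length(markov_states()), nrow(branches),
              dimnames = list(markov_states(), NULL))
  E[cbind(match(st, markov_states()), seq_len(nrow(branches)))] <- 1
  .vtecea_cache$tree <- list(grid = grid, branches = branches, G = G,
                             tG = t(G), E = E, tE = t(E))
  .vtecea_cache$tree
}

branch_entry_states <- function(branches) {
  state_of <- c(
    none = "", sympt_prox_dvt = "post_sympt_prox_dvt",
    sympt_dist_dvt = "post_sympt_dist_dvt", nonfatal_pe = "post_pe",
    fatal_pe = "dead", ssb_return_theatre = "", gi_bleed_intervention = "",
    gi_bleed_medical = "", ich_stroke = "disabled_post_stroke",
    other_mb = "", fatal_mb = "dead", crnmb_medical = "",
    wound_haematoma = "", ssi_medical = "", ssi_return_theatre = "",
    ssi_revision = "post_revision_infection", hit_success = "",
    hit_thrombosis_dvt = "post_sympt_prox_dvt",
    hit_thrombosis_pe = "post_pe", hit_mb = "", hit_death = "dead",
    hit_amputation = "amputated_post_hit")
  st <- state_of[branches$event]
  if (anyNA(st)) stop("unmapped branch event: ",
                      paste(unique(branches$event[is.na(st)]), collapse = ", "))
  fallback <- ifelse(branches$asympt == "prox", "post_asympt_prox_dvt",
                     ifelse(branches$asympt == "dist", "post_asympt_dist_dvt",
                            "well"))
  ifelse(st == "", fallback, st)
}

# Strategy-specific arm probability vectors -------------------------------

strategy_risk_row <- function(inputs, strategy) {
  ar <- inputs$absolute_risks
  i <- match(strategy, ar$strategy)
  if (is.na(i)) stop("unknown strategy: ", strategy)
  ar[i, ]
}

# HIT is heparin-induced: the risk applies to LMWH-containing strategies
# only (consistent with the zero post-amputation costs reported for all
# other strategies).
hit_risk_for <- function(inputs, strategy) {
  if (grepl("^lmwh", strategy)) inputs$baseline$hit else 0
}

fatal_pe_prob <- function(nonfatal, case_fatality, form = c("odds", "ratio")) {
  form <- match.arg(form)
  if (form == "odds") nonfatal * case_fatality / (1 - case_fatality)
  else nonfatal * case_fatality
}

arm_probabilities <- function(inputs, strategy, cap = FALSE) {
  r <- strategy_risk_row(inputs, strategy)
  bl <- inputs$baseline
  ot <- inputs$other
  # VTE arm: split all-DVT using the baseline symptomatic share, then the
  # proximal fractions; fatal PE on top of the printed non-fatal risk
  sympt_share <- bl$symptomatic_dvt / bl$total_dvt
  sympt <- r$dvt * sympt_share
  asympt <- r$dvt - sympt
  fpe <- fatal_pe_prob(r$pe, bl$pe_case_fatality, inputs$config$pe_fatal_form)
  v <- c(0, asympt * (1 - bl$prop_asympt_proximal), asympt * bl$prop_asympt_proximal,
         sympt * (1 - bl$prop_sympt_proximal), sympt * bl$prop_sympt_proximal,
         r$pe, fpe)
  v[1] <- 1 - sum(v[-1])
  # bleeding arm
  gi <- r$gi_ich * ot$gi_frac_of_gi_ich
  ich <- r$gi_ich - gi
  b <- c(0, r$ssb, gi * ot$gi_intervention_frac, gi * (1 - ot$gi_intervention_frac),
         ich, r$other_mb, ot$fatal_mb)
  b[1] <- 1 - sum(b[-1])
  # CRNMB arm: wound haematoma, then surgical-site infection and its
  # management split
  haem <- r$crnmb * bl$wound_haematoma_frac
  ssi <- haem * ot$ssi_given_haematoma
  surg <- ssi * ot$surgical_mgmt_given_ssi
  cc <- c(0, r$crnmb - haem, haem - ssi, ssi - surg,
          surg * (1 - ot$revision_vs_return_ratio), surg * ot$revision_vs_return_ratio)
  cc[1] <- 1 - sum(cc[-1])
  # HIT arm: amputation carved from the thrombosis outcome, remainder 1:1
  # proximal DVT : PE
  hit <- hit_risk_for(inputs, strategy)
  amp <- hit * ot$hit_amputation_prob
  thr <- hit * ot$hit_thrombosis - amp
  h <- c(0, hit * ot$hit_success, thr / 2, thr / 2, hit * ot$hit_mb,
         hit * ot$hit_death, amp)
  h[1] <- 1 - sum(h[-1])
  out <- list(v = v, b = b, c = cc, h = h)
  capped <- FALSE
  for (nm in names(out)) {
    a <- out[[nm]]
    s <- sum(a[-1])
    if (s > 1) {
      if (!cap) stop("arm probabilities outside [0, 1] after combination ",
                     "for strategy ", strategy)
      # extreme PSA draw: rescale the arm onto the simplex and flag it
      a[-1] <- a[-1] / s
      a[1] <- 0
      out[[nm]] <- a
      capped <- TRUE
    }
    if (any(a < -1e-12))
      stop("arm probabilities outside [0, 1] after combination for strategy ",
           strategy)
  }
  attr(out, "capped") <- capped
  out
}

# Vectorised arm probabilities for every strategy at once (rows =
# strategies, columns = arm categories); used by the PSA inner loop.
arm_prob_matrix <- function(inputs, cap = FALSE) {
  ar <- inputs$absolute_risks
  bl <- inputs$baseline
  ot <- inputs$other
  sympt <- ar$dvt * (bl$symptomatic_dvt / bl$total_dvt)
  asympt <- ar$dvt - sympt
  fpe <- fatal_pe_prob(ar$pe, bl$pe_case_fatality, inputs$config$pe_fatal_form)
  V <- cbind(0, asympt * (1 - bl$prop_asympt_proximal),
             asympt * bl$prop_asympt_proximal,
             sympt * (1 - bl$prop_sympt_proximal),
             sympt * bl$prop_sympt_proximal, ar$pe, fpe)
  gi <- ar$gi_ich * ot$gi_frac_of_gi_ich
  B <- cbind(0, ar$ssb, gi * ot$gi_intervention_frac,
             gi * (1 - ot$gi_intervention_frac), ar$gi_ich - gi,
             ar$other_mb, ot$fatal_mb)
  haem <- ar$crnmb * bl$wound_haematoma_frac
  ssi <- haem * ot$ssi_given_haematoma
  surg <- ssi * ot$surgical_mgmt_given_ssi
  C <- cbind(0, ar$crnmb - haem, haem - ssi, ssi - surg,
             surg * (1 - ot$revision_vs_return_ratio),
             surg * ot$revision_vs_return_ratio)
  hit <- ifelse(grepl("^lmwh", ar$strategy), bl$hit, 0)
  amp <- hit * ot$hit_amputation_prob
  thr <- hit * ot$hit_thrombosis - amp
  H <- cbind(0, hit * ot$hit_success, thr / 2, thr / 2, hit * ot$hit_mb,
             hit * ot$hit_death, amp)
  capped <- logical(nrow(ar))
  close_arm <- function(M) {
    s <- rowSums(M[, -1, drop = FALSE])
    over <- s > 1
    if (any(over)) {
      if (!cap) stop("arm probabilities outside [0, 1] after combination")
      M[over, -1] <- M[over, -1, drop = FALSE] / s[over]
      s[over] <- 1
      capped[over] <<- TRUE
    }
    M[, 1] <- 1 - s
    M
  }
  out <- list(V = close_arm(V), B = close_arm(B), C = close_arm(C),
              H = close_arm(H), capped = capped)
  out
}

#' Build the 90-day decision tree for one strategy
#'
#' Enumerates the mutually exclusive terminal branches obtained by combining
#' the four independent event arms (VTE outcome, major bleeding, clinically
#' relevant non-major bleeding with its infection sequelae, and
#' heparin-induced thrombocytopaenia), resolving joint symptomatic
#' occurrences to a single event in a fixed priority order (fatal events,
#' then PE, then symptomatic DVT, then major bleeding, then CRNMB).
#' Asymptomatic DVT is undetected and co-exists with any other outcome.
#'
#' @param inputs A `vte_inputs` object.
#' @param strategy Strategy slug present in `inputs$strategies`.
#' @param cap When `TRUE` (used inside the probabilistic analysis), an arm
#'   whose event probabilities sum past 1 under an extreme draw is rescaled
#'   onto the simplex and flagged via the `"capped"` attribute instead of
#'   raising an error.
#' @return A data frame with columns `event`, `asympt`
#'   (`none`/`dist`/`prox`) and `prob`, summing to 1.
#' @export
build_acute_tree <- function(inputs, strategy, cap = FALSE) {
  ts <- tree_structure()
  a <- arm_probabilities(inputs, strategy, cap = cap)
  p <- a$v[ts$grid$iv] * a$b[ts$grid$ib] * a$c[ts$grid$ic] * a$h[ts$grid$ih]
  out <- ts$branches
  out$prob <- as.vector(ts$G %*% p)
  attr(out, "strategy") <- strategy
  attr(out, "capped") <- attr(a, "capped")
  out
}

#' Expected event tallies per cohort
#'
#' @param tree Branch table from [build_acute_tree()].
#' @param cohort_size Cohort denominator (default 1,000, matching the
#'   reported outcome tables).
#' @return Data frame with one row per reported outcome, expected
#'   (unrounded) counts and counts rounded to the nearest integer with ties
#'   to even.
#' @export
tally_events <- function(tree, cohort_size = 1000) {
  by_event <- function(kinds) sum(tree$prob[tree$event %in% kinds])
  asympt_prox <- sum(tree$prob[tree$asympt == "prox"])
  asympt_dist <- sum(tree$prob[tree$asympt == "dist"])
  sympt_dvt <- by_event(c("sympt_prox_dvt", "sympt_dist_dvt"))
  pe <- by_event("nonfatal_pe")
  vals <- c(
    sympt_dvt = sympt_dvt,
    sympt_prox_dvt = by_event("sympt_prox_dvt"),
    asympt_dvt = asympt_prox + asympt_dist,
    pe = pe,
    total_vte = sympt_dvt + asympt_prox + asympt_dist + pe,
    ssb = by_event("ssb_return_theatre"),
    gi_bleed = by_event(c("gi_bleed_intervention", "gi_bleed_medical")),
    ich_stroke = by_event("ich_stroke"),
    crnmb = by_event(c("crnmb_medical", "wound_haematoma", "ssi_medical",
                       "ssi_return_theatre", "ssi_revision")),
    ssi = by_event(c("ssi_medical", "ssi_return_theatre", "ssi_revision")),
    hit = by_event(c("hit_success", "hit_thrombosis_dvt", "hit_thrombosis_pe",
                     "hit_mb", "hit_death", "hit_amputation")),
    deaths = by_event(c("fatal_pe", "fatal_mb", "hit_death"))
  ) * cohort_size
  data.frame(outcome = names(vals), expected = unname(vals),
             rounded = round(unname(vals)), stringsAsFactors = FALSE)
}

#' Distribution over Markov entry states implied by the acute tree
#'
#' Terminal branches map to the nine live entry states plus dead; branches
#' with no long-term sequela enter the asymptomatic post-DVT state when an
#' asymptomatic event co-occurred, otherwise "well".
#'
#' @param tree Branch table from [build_acute_tree()].
#' @return Named probability vector over [markov_states()].
#' @export
entry_distribution <- function(tree) {
  st <- branch_entry_states(tree)
  out <- stats::setNames(numeric(length(markov_states())), markov_states())
  agg <- tapply(tree$prob, st, sum)
  out[names(agg)] <- agg
  out
}

#' Acute VTE treatment cost bundle
#'
#' Symptomatic proximal DVT, symptomatic distal DVT and non-fatal PE are
#' diagnosed and treated (a DOAC or LMWH followed by warfarin, 50% each,
#' assumed 100% effective); asymptomatic DVT is not diagnosed in practice
#' and carries no cost.
#'
#' @param vte_kind One of the acute event kinds.
#' @param inputs A `vte_inputs` object.
#' @return Expected treatment/diagnosis cost in GBP.
#' @export
acute_treatment_assignment <- function(vte_kind, inputs) {
  ec <- inputs$event_costs
  switch(vte_kind,
    sympt_prox_dvt = , hit_thrombosis_dvt = ec$sympt_prox_dvt,
    sympt_dist_dvt = ec$sympt_dist_dvt,
    nonfatal_pe = , hit_thrombosis_pe = ec$nonfatal_pe,
    asympt_prox_dvt = , asympt_dist_dvt = 0,
    stop("not a VTE kind: ", vte_kind))
}
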