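#' @keywords internal
"_PACKAGE"

# Canonical population labels.
#' Populations covered by the packaged input sets
#'
#' @return Character vector of population labels: `"eTHR"` (elective total
#'   hip replacement) and `"eTKR"` (elective total knee replacement).
#' @export
vte_populations <- function() c("eTHR", "eTKR")

fixture_file <- function(population) {
  fn <- switch(population,
    eTHR = "ethr_inputs.csv",
    eTKR = "etkr_inputs.csv",
    stop("unknown population: ", population, " (expected one of ",
         paste(vte_populations(), collapse = ", "), ")")
  )
  system.file("extdata", fn, package = "vtecea", mustWork = TRUE)
}

read_raw_inputs <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(block = "character", name = "character",
                                        value = "numeric", se = "numeric",
                                        low95 = "numeric", high95 = "numeric",
                                        note = "character"))
  need <- c("block", "name", "value", "se", "low95", "high95", "note")
  if (!all(need %in% names(raw)))
    stop("input table must have columns: ", paste(need, collapse = ", "))
  raw
}

blk <- function(raw, block) {
  r <- raw[raw$block == block, ]
  stats::setNames(r$value, r$name)
}

blk_col <- function(raw, block, strategies, col = "value") {
  r <- raw[raw$block == block, ]
  i <- match(strategies, r$name)
  if (anyNA(i)) stop("block '", block, "' missing strategies: ",
                     paste(strategies[is.na(i)], collapse = ", "))
  r[[col]][i]
}

#' Derive the asymptomatic DVT probability from the symptomatic probability
#'
#' The registry sources report symptomatic deep-vein thrombosis only; the
#' asymptomatic burden is recovered by scaling with an
#' asymptomatic-to-symptomatic ratio, so that the total DVT risk is the sum
#' of the two components.
#'
#' @param symptomatic Probability of symptomatic DVT over the acute window.
#' @param asympt_to_sympt_ratio Non-negative ratio of asymptomatic to
#'   symptomatic events.
#' @return Probability of asymptomatic DVT.
#' @export
derive_asymptomatic_dvt <- function(symptomatic, asympt_to_sympt_ratio) {
  stopifnot(symptomatic >= 0, symptomatic <= 1, asympt_to_sympt_ratio >= 0)
  out <- symptomatic * asympt_to_sympt_ratio
  if (out > 1) stop("asymptomatic DVT probability exceeds 1; ratio inconsistent")
  out
}

#' Apply a relative risk to a baseline probability
#'
#' Absolute event risks for each prophylaxis strategy are obtained by
#' multiplying the baseline risk by the strategy's risk ratio. The result is
#' capped at 1 (with a warning), which can occur for extreme draws in the
#' probabilistic analysis.
#'
#' @param baseline Baseline probability in `[0, 1]`.
#' @param rr Risk ratio, `> 0`.
#' @return Probability `min(baseline * rr, 1)`.
#' @export
apply_relative_risk <- function(baseline, rr) {
  stopifnot(all(baseline >= 0), all(baseline <= 1), all(rr > 0))
  out <- baseline * rr
  if (any(out > 1)) {
    warning("relative risk capped: baseline * rr exceeded 1")
    out <- pmin(out, 1)
  }
  out
}

#' Apply an odds ratio to a baseline probability
#'
#' Bleeding effects are expressed as odds ratios against the comparator
#' strategy; the absolute risk is recovered on the odds scale:
#' `p' = inv_odds(or * p / (1 - p))`.
#'
#' @param baseline Baseline probability strictly inside `(0, 1)`.
#' @param or_value Odds ratio, `> 0`.
#' @return Transformed probability.
#' @export
apply_odds_ratio <- function(baseline, or_value) {
  if (any(baseline <= 0) || any(baseline >= 1))
    stop("baseline must be in (0, 1): odds undefined at 0 or 1")
  stopifnot(all(or_value > 0))
  odds <- or_value * baseline / (1 - baseline)
  odds / (1 + odds)
}

#' Total intervention cost of a prophylaxis strategy
#'
#' @param strategy Strategy identifier (normalised slug or display label).
#' @param inputs A `vte_inputs` object.
#' @return Pharmacological plus mechanical component cost in GBP
#'   (2016 prices).
#' @export
strategy_total_cost <- function(strategy, inputs) {
  st <- inputs$strategies
  i <- match(strategy, st$strategy)
  if (is.na(i)) i <- match(strategy, st$label)
  if (is.na(i)) stop("unknown strategy: ", strategy)
  unname(st$pharm_cost[i] + st$mech_cost[i])
}

# Derive relative effects (RR for VTE outcomes, OR for bleeding outcomes)
# from the per-strategy absolute-risk table, expressed vs the comparator row.
derive_effects <- function(risks, comparator) {
  ref <- risks[risks$strategy == comparator, ]
  if (nrow(ref) != 1L) stop("comparator strategy not found: ", comparator)
  # log-scale SD from a 95% interval; when the lower bound is printed as
  # zero (truncated), fall back to the upper half-interval
  log_sigma <- function(point, lo, hi) {
    ifelse(is.na(hi) | hi <= 0, NA_real_,
           ifelse(!is.na(lo) & lo > 0, (log(hi) - log(lo)) / 3.92,
                  (log(hi) - log(point)) / 1.96))
  }
  odds <- function(p) p / (1 - p)
  data.frame(
    strategy = risks$strategy,
    rr_dvt = risks$dvt / ref$dvt,
    rr_pe = risks$pe / ref$pe,
    sigma_dvt = log_sigma(risks$dvt / ref$dvt, risks$dvt_lo / ref$dvt,
                          risks$dvt_hi / ref$dvt),
    sigma_pe = log_sigma(risks$pe / ref$pe, risks$pe_lo / ref$pe,
                         risks$pe_hi / ref$pe),
    prop_dvt = is.na(risks$dvt_lo) & is.na(risks$dvt_hi),
    prop_pe = is.na(risks$pe_lo) & is.na(risks$pe_hi),
    or_gi_ich = odds(risks$gi_ich) / odds(ref$gi_ich),
    or_ssb = odds(risks$ssb) / odds(ref$ssb),
    or_other_mb = odds(risks$other_mb) / odds(ref$other_mb),
    or_crnmb = odds(risks$crnmb) / odds(ref$crnmb),
    stringsAsFactors = FALSE
  )
}

# Absolute per-strategy event probabilities used by the acute model: the
# comparator baselines carry the relative effects (RR on the risk scale for
# DVT/PE, OR on the odds scale for bleeding).
derive_absolute_risks <- function(baseline, effects) {
  suppress_cap <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("relative risk capped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(
    strategy = effects$strategy,
    dvt = suppress_cap(apply_relative_risk(baseline[["total_dvt"]], effects$rr_dvt)),
    pe = suppress_cap(apply_relative_risk(baseline[["nonfatal_pe"]], effects$rr_pe)),
    gi_ich = apply_odds_ratio(baseline[["mb_gi_ich"]], effects$or_gi_ich),
    ssb = apply_odds_ratio(baseline[["mb_surgical_site"]], effects$or_ssb),
    other_mb = apply_odds_ratio(baseline[["mb_other"]], effects$or_other_mb),
    crnmb = apply_odds_ratio(baseline[["crnmb"]], effects$or_crnmb),
    stringsAsFactors = FALSE
  )
}

assemble_inputs <- function(raw, population, life_table = NULL) {
  strat_rows <- raw[raw$block == "strategy", ]
  strat_rows <- strat_rows[order(strat_rows$value), ]
  slugs <- strat_rows$name
  strategies <- data.frame(
    strategy = slugs,
    label = strat_rows$note,
    pharm_cost = blk_col(raw, "cost_pharm", slugs),
    mech_cost = blk_col(raw, "cost_mech", slugs),
    duration_days = blk_col(raw, "duration_days", slugs),
    stringsAsFactors = FALSE
  )
  risks <- data.frame(
    strategy = slugs,
    dvt = blk_col(raw, "risk_dvt", slugs),
    dvt_lo = blk_col(raw, "risk_dvt", slugs, "low95"),
    dvt_hi = blk_col(raw, "risk_dvt", slugs, "high95"),
    pe = blk_col(raw, "risk_pe", slugs),
    pe_lo = blk_col(raw, "risk_pe", slugs, "low95"),
    pe_hi = blk_col(raw, "risk_pe", slugs, "high95"),
    gi_ich = blk_col(raw, "risk_gi_ich", slugs),
    ssb = blk_col(raw, "risk_ssb", slugs),
    other_mb = blk_col(raw, "risk_other_mb", slugs),
    crnmb = blk_col(raw, "risk_crnmb", slugs),
    stringsAsFactors = FALSE
  )
  comparator <- if ("lmwh_std_std_aes" %in% slugs) "lmwh_std_std_aes" else slugs[1]
  effects <- derive_effects(risks, comparator)
  baseline <- as.list(blk(raw, "baseline"))
  # bounds must hold before odds-scale derivations are attempted
  for (nm in names(baseline)) check_prob(baseline[[nm]], nm)
  settings <- as.list(blk(raw, "settings"))
  settings$time_horizon <- "lifetime"
  if (is.null(life_table)) life_table <- make_life_table()
  inputs <- structure(list(
    population = population,
    comparator = comparator,
    cohort = as.list(blk(raw, "cohort")),
    strategies = strategies,
    baseline = baseline,
    other = as.list(blk(raw, "other")),
    long_term = as.list(blk(raw, "long_term")),
    utilities = as.list(blk(raw, "utility")),
    disutility = as.list(blk(raw, "disutility")),
    state_utility = as.list(blk(raw, "state_utility")),
    event_costs = as.list(blk(raw, "event_cost")),
    state_costs = as.list(blk(raw, "state_cost")),
    settings = settings,
    risks = risks,
    effects = effects,
    absolute_risks = derive_absolute_risks(baseline, effects),
    life_table = life_table,
    config = list(pe_fatal_form = "odds", half_cycle = FALSE),
    raw = raw
  ), class = "vte_inputs")
  validate_inputs(inputs)
  inputs
}

#' Load and validate a population's full model parameter set
#'
#' Reads the packaged parameter tables (or a user-supplied table in the same
#' long CSV format with columns `block, name, value, se, low95, high95,
#' note`), derives the relative effects and per-strategy absolute risks from
#' the comparator row, attaches a life table and validates the result.
#'
#' @param population `"eTHR"` or `"eTKR"`.
#' @param path Optional path to an input CSV; defaults to the packaged
#'   fixture for the population.
#' @param life_table Optional data frame with columns `age` and `qx`;
#'   defaults to the synthetic Gompertz-Makeham table from
#'   [make_life_table()].
#' @return A validated `vte_inputs` object.
#' @export
load_inputs <- function(population = c("eTHR", "eTKR"), path = NULL,
                        life_table = NULL) {
  population <- match.arg(population)
  if (is.null(path)) path <- fixture_file(population)
  if (!file.exists(path)) stop("input file not found: ", path)
  assemble_inputs(read_raw_inputs(path), population, life_table)
}

#' Write a parameter set back to its long CSV representation
#'
#' The inverse of [load_inputs()]: `load_inputs(path = write_inputs(x, f))`
#' reproduces `x` field for field.
#'
#' @param inputs A `vte_inputs` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  stopifnot(inherits(inputs, "vte_inputs"))
  utils::write.csv(inputs$raw, path, row.names = FALSE, na = "")
  invisible(path)
}

check_prob <- function(x, nm) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) stop("validation error: ", nm,
                     " must lie in [0, 1], got ", paste(x[bad], collapse = ", "))
}

#' Validate a parameter set
#'
#' Checks probability bounds, cost signs, the symptomatic/total DVT ordering,
#' the HIT outcome split, and that the per-strategy tables name-match the
#' strategy panel.
#'
#' @param inputs A `vte_inputs` object.
#' @return `inputs`, invisibly.
#' @export
validate_inputs <- function(inputs) {
  co <- inputs$cohort
  if (co$start_age <= 0 || co$start_age >= 110)
    stop("validation error: start_age must be in (0, 110)")
  check_prob(co$proportion_male, "proportion_male")
  bl <- inputs$baseline
  for (nm in names(bl)) {
    if (nm == "pe_case_fatality" || grepl("^prop_|frac", nm)) check_prob(bl[[nm]], nm)
    else check_prob(bl[[nm]], nm)
  }
  if (bl$symptomatic_dvt > bl$total_dvt)
    stop("validation error: symptomatic_dvt exceeds total_dvt")
  for (nm in names(inputs$other)) {
    if (nm != "prop_sympt_distal_treated") check_prob(inputs$other[[nm]], nm)
  }
  hs <- with(inputs$other, hit_success + hit_thrombosis + hit_mb + hit_death)
  if (abs(hs - 1) > 1e-9) stop("validation error: HIT outcome split must sum to 1")
  if (inputs$other$hit_amputation_prob > inputs$other$hit_thrombosis + 1e-12)
    stop("validation error: hit_amputation_prob exceeds the HIT thrombosis share")
  for (nm in names(inputs$long_term)) check_prob(inputs$long_term[[nm]], nm)
  ws <- with(inputs$long_term, cteph_w_operable + cteph_w_inoperable + cteph_w_recurrent)
  if (abs(ws - 1) > 1e-9) stop("validation error: CTEPH stratum weights must sum to 1")
  ut <- inputs$utilities
  for (nm in names(ut))
    if (!is.na(ut[[nm]]) && (ut[[nm]] < -0.594 || ut[[nm]] > 1))
      stop("validation error: utility ", nm, " outside EQ-5D bounds [-0.594, 1]")
  if (ut$preop_utility >= ut$post_9mo_utility)
    stop("validation error: preop utility must be below the 9-month utility")
  for (nm in names(inputs$disutility))
    if (grepl("^rel_", nm)) check_prob(inputs$disutility[[nm]], nm)
  costs <- c(unlist(inputs$event_costs), unlist(inputs$state_costs),
             inputs$strategies$pharm_cost, inputs$strategies$mech_cost)
  costs <- costs[names(costs) != "prop_stroke_dependent" | !nzchar(names(costs))]
  if (any(costs < 0)) stop("validation error: costs must be non-negative")
  se <- inputs$settings
  if (se$threshold_lambda <= 0) stop("validation error: threshold_lambda must be > 0")
  if (se$discount_rate < 0 || se$discount_rate >= 1)
    stop("validation error: discount_rate must be in [0, 1)")
  if (se$cycle_length <= 0) stop("validation error: cycle_length must be > 0")
  for (tab in c("risks", "effects", "absolute_risks"))
    if (!setequal(inputs[[tab]]$strategy, inputs$strategies$strategy))
      stop("validation error: strategy names in ", tab, " do not match the panel")
  ar <- inputs$absolute_risks
  for (nm in c("dvt", "pe", "gi_ich", "ssb", "other_mb", "crnmb"))
    check_prob(ar[[nm]], paste0("absolute_risks$", nm))
  lt <- inputs$life_table
  if (!all(c("age", "qx") %in% names(lt))) stop("life table needs columns age, qx")
  check_prob(lt$qx, "life table qx")
  if (lt$qx[nrow(lt)] != 1) stop("life table must end with qx = 1")
  invisible(inputs)
}

#' @export
print.vte_inputs <- function(x, ...) {
  cat("<vte_inputs> population:", x$population,
      "|", nrow(x$strategies), "strategies | comparator:", x$comparator, "\n")
  invisible(x)
}
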