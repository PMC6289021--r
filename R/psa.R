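# Probabilistic sensitivity analysis: sampling distributions, Monte-Carlo
# propagation through the full model, and decision-uncertainty summaries.

#' Assign sampling distributions to the model parameters
#'
#' Default families: beta for probabilities (from printed counts where
#' available, otherwise moment-matched from mean and SE, with SE defaulting
#' to `se_frac` of the mean when unprinted); gamma for event and state costs
#' (SE = `se_frac` of the mean); lognormal for DVT/PE risk ratios with the
#' log-scale SD matched to the printed credible intervals; lognormal for
#' bleeding odds ratios with a default SD (`or_sigma`, no intervals
#' printed); beta for the 9-month utility (printed SE); fixed for
#' structural fractions, unprinted decrements and intervention costs.
#' Proportionality-imputed DVT/PE effects share a single standard-normal
#' draw (perfect correlation).
#'
#' @param inputs A `vte_inputs` object.
#' @param se_frac SE as a fraction of the mean for parameters without a
#'   printed SE (default 0.2).
#' @param or_sigma Log-scale SD for bleeding odds ratios (default 0.3).
#' @return Data frame with columns `block`, `name`, `strategy`, `family`,
#'   `mean`, `se`, `sigma`, `shape1`, `shape2`.
#' @export
assign_distributions <- function(inputs, se_frac = 0.2, or_sigma = 0.3) {
  rows <- list()
  add <- function(block, name, strategy = NA_character_, family, mean = NA,
                  se = NA, sigma = NA, shape1 = NA, shape2 = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, name = name, strategy = strategy, family = family,
      mean = mean, se = se, sigma = sigma, shape1 = shape1, shape2 = shape2,
      stringsAsFactors = FALSE)
  }
  raw_se <- function(block, name) {
    r <- inputs$raw[inputs$raw$block == block & inputs$raw$name == name, ]
    if (nrow(r) != 1) return(NA_real_)
    if (!is.na(r$se)) return(r$se)
    if (!is.na(r$low95) && !is.na(r$high95)) return((r$high95 - r$low95) / 3.92)
    NA_real_
  }
  bl <- inputs$baseline
  beta_prob <- function(block, name, value, counts = NULL) {
    if (!is.null(counts)) {
      add(block, name, family = "beta", mean = value,
          shape1 = counts[1], shape2 = counts[2])
    } else {
      s <- raw_se(block, name)
      if (is.na(s)) s <- se_frac * value
      if (value <= 0 || value >= 1 || s == 0) add(block, name, family = "fixed", mean = value)
      else add(block, name, family = "beta", mean = value, se = s)
    }
  }
  beta_prob("baseline", "total_dvt", bl$total_dvt)
  beta_prob("baseline", "nonfatal_pe", bl$nonfatal_pe)
  beta_prob("baseline", "mb_surgical_site", bl$mb_surgical_site)
  beta_prob("baseline", "mb_gi_ich", bl$mb_gi_ich)
  beta_prob("baseline", "mb_other", bl$mb_other)
  beta_prob("baseline", "crnmb", bl$crnmb)
  beta_prob("baseline", "hit", bl$hit)
  wh_counts <- if (inputs$population == "eTHR") c(5, 17) else c(11, 47)
  beta_prob("baseline", "wound_haematoma_frac", bl$wound_haematoma_frac, wh_counts)
  beta_prob("other", "ssi_given_haematoma", inputs$other$ssi_given_haematoma, c(25, 72))
  beta_prob("other", "surgical_mgmt_given_ssi", inputs$other$surgical_mgmt_given_ssi, c(11, 14))
  lt <- inputs$long_term
  for (nm in c("pts_2yr_sympt_prox", "pts_2yr_sympt_dist", "pts_2yr_asympt_prox",
               "pts_2yr_asympt_dist", "pts_2yr_pe", "prop_pts_severe",
               "cteph_2yr_after_pe"))
    beta_prob("long_term", nm, lt[[nm]])
  beta_prob("utility", "post_9mo_utility", inputs$utilities$post_9mo_utility)
  for (nm in names(inputs$event_costs)) {
    v <- inputs$event_costs[[nm]]
    if (v > 0) add("event_cost", nm, family = "gamma", mean = v, se = se_frac * v)
    else add("event_cost", nm, family = "fixed", mean = v)
  }
  for (nm in setdiff(names(inputs$state_costs), "prop_stroke_dependent")) {
    v <- inputs$state_costs[[nm]]
    if (v > 0) add("state_cost", nm, family = "gamma", mean = v, se = se_frac * v)
    else add("state_cost", nm, family = "fixed", mean = v)
  }
  ef <- inputs$effects
  for (i in seq_len(nrow(ef))) {
    s <- ef$strategy[i]
    if (s == inputs$comparator) {
      add("effect", "rr_dvt", s, "fixed", mean = 1)
      add("effect", "rr_pe", s, "fixed", mean = 1)
    } else {
      sd_dvt <- if (ef$prop_dvt[i]) ef$sigma_pe[i] else ef$sigma_dvt[i]
      sd_pe <- if (ef$prop_pe[i]) ef$sigma_dvt[i] else ef$sigma_pe[i]
      add("effect", "rr_dvt", s, "lognormal", mean = ef$rr_dvt[i], sigma = sd_dvt)
      add("effect", "rr_pe", s, "lognormal", mean = ef$rr_pe[i], sigma = sd_pe)
    }
    for (nm in c("or_gi_ich", "or_ssb", "or_other_mb", "or_crnmb")) {
      v <- ef[[nm]][i]
      if (s == inputs$comparator || abs(v - 1) < 1e-12)
        add("effect", nm, s, "fixed", mean = v)
      else add("effect", nm, s, "lognormal", mean = v, sigma = or_sigma)
    }
  }
  out <- do.call(rbind, rows)
  infeasible <- out$family == "beta" & is.na(out$shape1) &
    out$se^2 >= out$mean * (1 - out$mean)
  if (any(infeasible))
    stop("infeasible beta moment match for: ",
         paste(out$name[infeasible], collapse = ", "))
  out
}

beta_shapes <- function(mean, se) {
  phi <- mean * (1 - mean) / se^2 - 1
  c(mean * phi, (1 - mean) * phi)
}

# Precompute a vectorised sampling plan from the distribution table:
# moment-matched beta/gamma shapes for the scalar parameters and per-strategy
# lognormal parameters for the relative effects.
prep_draw_plan <- function(inputs, dists) {
  ne <- dists[dists$block != "effect", ]
  tgt <- c(baseline = "baseline", other = "other", long_term = "long_term",
           utility = "utilities", event_cost = "event_costs",
           state_cost = "state_costs")[ne$block]
  sh1 <- ne$shape1
  sh2 <- ne$shape2
  need <- ne$family == "beta" & is.na(sh1)
  if (any(need)) {
    phi <- ne$mean[need] * (1 - ne$mean[need]) / ne$se[need]^2 - 1
    sh1[need] <- ne$mean[need] * phi
    sh2[need] <- (1 - ne$mean[need]) * phi
  }
  sl <- inputs$effects$strategy
  ef <- dists[dists$block == "effect", ]
  ef_par <- function(name) {
    r <- ef[ef$name == name, ]
    i <- match(sl, r$strategy)
    list(mean = r$mean[i],
         sigma = ifelse(r$family[i] == "lognormal" & !is.na(r$sigma[i]),
                        r$sigma[i], 0))
  }
  list(tgt = unname(tgt), name = ne$name, family = ne$family, mean = ne$mean,
       shape1 = sh1, shape2 = sh2,
       g_shape = (ne$mean / ne$se)^2, g_rate = ne$mean / ne$se^2,
       is_beta = ne$family == "beta", is_gamma = ne$family == "gamma",
       rr_dvt = ef_par("rr_dvt"), rr_pe = ef_par("rr_pe"),
       prop_dvt = inputs$effects$prop_dvt, prop_pe = inputs$effects$prop_pe,
       or_gi_ich = ef_par("or_gi_ich"), or_ssb = ef_par("or_ssb"),
       or_other_mb = ef_par("or_other_mb"), or_crnmb = ef_par("or_crnmb"),
       n_strat = length(sl))
}

# Draw one parameter set and patch it into the inputs, recomputing the
# per-strategy absolute risks. Proportionality-linked DVT/PE effects share
# one standard-normal draw per strategy.
draw_from_plan <- function(inputs, prep) {
  new <- inputs
  vals <- prep$mean
  ib <- which(prep$is_beta)
  if (length(ib)) vals[ib] <- stats::rbeta(length(ib), prep$shape1[ib], prep$shape2[ib])
  ig <- which(prep$is_gamma)
  if (length(ig)) vals[ig] <- stats::rgamma(length(ig), prep$g_shape[ig], prep$g_rate[ig])
  for (i in seq_along(vals)) new[[prep$tgt[i]]][[prep$name[i]]] <- vals[i]
  S <- prep$n_strat
  z1 <- stats::rnorm(S)
  z2 <- stats::rnorm(S)
  z_dvt <- z1
  z_pe <- z2
  z_dvt[prep$prop_dvt] <- z2[prep$prop_dvt] # imputed effects share the
  z_pe[prep$prop_pe] <- z1[prep$prop_pe]    # sibling outcome's draw
  ef <- new$effects
  ef$rr_dvt <- exp(log(prep$rr_dvt$mean) + prep$rr_dvt$sigma * z_dvt)
  ef$rr_pe <- exp(log(prep$rr_pe$mean) + prep$rr_pe$sigma * z_pe)
  for (nm in c("or_gi_ich", "or_ssb", "or_other_mb", "or_crnmb")) {
    p <- prep[[nm]]
    ef[[nm]] <- exp(log(p$mean) + p$sigma * stats::rnorm(S))
  }
  new$effects <- ef
  n_capped <- sum(ef$rr_dvt * new$baseline$total_dvt > 1) +
    sum(ef$rr_pe * new$baseline$nonfatal_pe > 1)
  new$absolute_risks <- derive_absolute_risks(new$baseline, ef)
  attr(new, "n_capped") <- n_capped
  new
}

# Strategy-independent discounted Markov value vectors: expected discounted
# QALYs and costs accrued from entering each state at cycle 0. The Markov
# phase is treatment-independent, so per-strategy Markov totals are dot
# products of these vectors with the entry distribution.
markov_value_vectors <- function(inputs) {
  S <- markov_states()
  age0 <- inputs$cohort$start_age + 90 / 365.25
  K <- ceiling(max(inputs$life_table$age) - age0) + 1L
  r <- inputs$settings$discount_rate
  v0 <- state_values(inputs, 0L)
  v1 <- state_values(inputs, 1L)
  M_on <- live_transition_matrix(inputs, TRUE)
  M_off <- live_transition_matrix(inputs, FALSE)
  occ <- diag(length(S))
  Vq <- Vc <- numeric(length(S))
  for (k in seq_len(K) - 1L) {
    v <- if (k == 0L) v0 else v1
    df <- (1 + r)^(-k)
    Vq <- Vq + df * as.vector(occ %*% v$utility)
    Vc <- Vc + df * as.vector(occ %*% v$cost)
    q <- lookup_qx(inputs$life_table, age0 + k)
    M <- apply_mortality(if (k < 2) M_on else M_off, q,
                         inputs$long_term$cteph_mortality)
    occ <- occ %*% M
  }
  list(qalys = stats::setNames(Vq, S), costs = stats::setNames(Vc, S))
}

# Totals for every strategy in one vectorised pass (no tally/breakdown
# bookkeeping): branch probabilities for all strategies via one matrix
# product, then acute values and Markov entry dot products.
all_strategy_totals <- function(inputs, eq, ecost, mv) {
  ts <- tree_structure()
  am <- arm_prob_matrix(inputs, cap = TRUE)
  P <- am$V[, ts$grid$iv] * am$B[, ts$grid$ib] *
    am$C[, ts$grid$ic] * am$H[, ts$grid$ih]
  bp <- P %*% ts$tG
  entry <- bp %*% ts$tE
  qalys <- as.vector(bp %*% eq[ts$branches$event] + entry %*% mv$qalys)
  costs <- inputs$strategies$pharm_cost + inputs$strategies$mech_cost +
    as.vector(bp %*% ecost[ts$branches$event] + entry %*% mv$costs)
  list(qalys = qalys, costs = costs, capped = am$capped)
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_iter` parameter sets from the assigned distributions and
#' propagates each through the acute tree, the Markov model and the
#' valuation, summarising decision uncertainty: means and percentile
#' intervals of QALYs, costs and INMB, the probability each strategy is the
#' most cost-effective at the configured threshold, rank intervals, a
#' cost-effectiveness acceptability curve over a threshold grid, and
#' incremental scatter points vs the comparator.
#'
#' @param inputs A `vte_inputs` object.
#' @param n_iter Number of Monte-Carlo iterations (default from settings).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param dists Optional distribution table from [assign_distributions()].
#' @param lambda_grid Thresholds for the acceptability curve.
#' @return A `vte_psa` object.
#' @export
run_psa <- function(inputs, n_iter = NULL, seed = 1L, dists = NULL,
                    lambda_grid = seq(0, 50000, by = 2500)) {
  if (is.null(n_iter)) n_iter <- inputs$settings$psa_iterations
  stopifnot(n_iter >= 1)
  if (is.null(dists)) dists <- assign_distributions(inputs)
  set.seed(seed)
  sl <- inputs$strategies$strategy
  S <- length(sl)
  prep <- prep_draw_plan(inputs, dists)
  qalys <- costs <- matrix(NA_real_, n_iter, S, dimnames = list(NULL, sl))
  n_capped <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    di <- draw_from_plan(inputs, prep)
    tot <- all_strategy_totals(di, acute_event_qalys(di),
                               acute_event_costs(di), markov_value_vectors(di))
    qalys[it, ] <- tot$qalys
    costs[it, ] <- tot$costs
    n_capped[it] <- attr(di, "n_capped") + sum(tot$capped)
  }
  lambda <- inputs$settings$threshold_lambda
  i0 <- match(inputs$comparator, sl)
  nmb_m <- qalys * lambda - costs
  inmb <- nmb_m - nmb_m[, i0]
  ranks <- t(apply(nmb_m, 1, function(x)
    rank_by_nmb(x, costs = rep(0, S), names = sl)))
  best <- max.col(nmb_m, ties.method = "first")
  pci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summ <- data.frame(
    strategy = sl,
    mean_qalys = colMeans(qalys),
    qalys_lo = apply(qalys, 2, function(x) pci(x)[1]),
    qalys_hi = apply(qalys, 2, function(x) pci(x)[2]),
    mean_costs = colMeans(costs),
    costs_lo = apply(costs, 2, function(x) pci(x)[1]),
    costs_hi = apply(costs, 2, function(x) pci(x)[2]),
    mean_inmb = colMeans(inmb),
    inmb_lo = apply(inmb, 2, function(x) pci(x)[1]),
    inmb_hi = apply(inmb, 2, function(x) pci(x)[2]),
    prob_ce = tabulate(best, nbins = S) / n_iter,
    mean_rank = colMeans(ranks),
    rank_lo = apply(ranks, 2, function(x) pci(x)[1]),
    rank_hi = apply(ranks, 2, function(x) pci(x)[2]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    population = inputs$population, n_iter = n_iter, seed = seed,
    lambda = lambda, strategies = sl, comparator = inputs$comparator,
    qalys = qalys, costs = costs, summary = summ,
    ceac = ceac(qalys, costs, lambda_grid),
    scatter = data.frame(
      iteration = rep(seq_len(n_iter), S),
      strategy = rep(sl, each = n_iter),
      inc_qalys = as.vector(qalys - qalys[, i0]),
      inc_costs = as.vector(costs - costs[, i0])),
    n_capped = n_capped, dists = dists
  ), class = "vte_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold in the grid, the fraction of iterations in which each
#' strategy attains the maximum net monetary benefit.
#'
#' @param qalys,costs Iteration-by-strategy matrices.
#' @param lambda_grid Numeric vector of thresholds.
#' @return Long data frame with columns `lambda`, `strategy`,
#'   `probability`; probabilities sum to 1 at every threshold.
#' @export
ceac <- function(qalys, costs, lambda_grid = seq(0, 50000, by = 2500)) {
  stopifnot(nrow(qalys) >= 1, all(dim(qalys) == dim(costs)))
  sl <- colnames(qalys)
  out <- lapply(lambda_grid, function(l) {
    best <- max.col(qalys * l - costs, ties.method = "first")
    data.frame(lambda = l, strategy = sl,
               probability = tabulate(best, nbins = ncol(qalys)) / nrow(qalys),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.vte_psa <- function(x, ...) {
  cat("<vte_psa>", x$population, "|", x$n_iter, "iterations | seed", x$seed, "\n")
  s <- x$summary[order(-x$summary$prob_ce), c("strategy", "mean_inmb", "prob_ce")]
  print(utils::head(s, 5), row.names = FALSE)
  invisible(x)
}

#' Probabilistic analysis with file outputs
#'
#' Wrapper over [run_psa()] writing `psa_summary.csv`, `ceac.csv`,
#' `scatter.csv` and a `manifest.json` recording the seed.
#'
#' @param population `"eTHR"` or `"eTKR"`, ignored when `inputs` is given.
#' @param inputs Optional pre-loaded `vte_inputs`.
#' @param n_iter Number of iterations.
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return The `vte_psa` object, invisibly.
#' @export
run_probabilistic <- function(population = c("eTHR", "eTKR"), inputs = NULL,
                              n_iter = NULL, seed = 1L, outdir = NULL) {
  if (is.null(inputs)) inputs <- load_inputs(match.arg(population))
  psa <- run_psa(inputs, n_iter = n_iter, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(psa$summary, file.path(outdir, "psa_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(psa$ceac, file.path(outdir, "ceac.csv"), row.names = FALSE)
    utils::write.csv(psa$scatter, file.path(outdir, "scatter.csv"),
                     row.names = FALSE)
    write_manifest(outdir, command = "run_probabilistic",
                   population = inputs$population, n_iter = psa$n_iter,
                   seed = seed)
  }
  invisible(psa)
}
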