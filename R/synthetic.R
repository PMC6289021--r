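# Synthetic data generators: life tables, random valid parameter sets, and
# known-answer panels for the cost-effectiveness oracles. Everything the
# pipeline needs can be generated here without external downloads.

#' Synthetic Gompertz-Makeham life table
#'
#' Annual death probabilities `qx(age) = min(1, a + b * exp(c * age))` on
#' ages 0-110 with a terminal probability of 1. The defaults are calibrated
#' so that life expectancy at age 68.7 is roughly 17 years, a plausible
#' figure for an elective arthroplasty cohort; this is a synthetic stand-in,
#' not a published national life table (real tables load via the
#' `life_table` argument of [load_inputs()]).
#'
#' @param a Makeham age-independent hazard component.
#' @param b,c Gompertz baseline and log-slope.
#' @param max_age Terminal age (qx forced to 1).
#' @return Data frame with columns `age`, `qx`.
#' @export
make_life_table <- function(a = 5e-4, b = 1.4e-5, c = 0.102, max_age = 110) {
  stopifnot(a >= 0, b >= 0, c > 0)
  age <- 0:max_age
  qx <- pmin(1, a + b * exp(c * age))
  qx[length(qx)] <- 1
  data.frame(age = age, qx = qx)
}

#' Life expectancy implied by a life table
#'
#' Closed-form summation under the model's accrual convention: the entry
#' year counts in full and survival compounds annually
#' (`sum_k prod_{j<k} (1 - qx(age0 + j))`).
#'
#' @param life_table Data frame with columns `age`, `qx`.
#' @param age0 Age at entry.
#' @return Expected years lived from `age0`.
#' @export
life_expectancy <- function(life_table, age0) {
  ages <- seq(age0, max(life_table$age))
  qx <- lookup_qx(life_table, ages)
  sum(cumprod(c(1, 1 - qx[-length(qx)])))
}

#' Generate a random but internally consistent parameter set
#'
#' Emulates the statistical structure the probabilistic analysis assumes:
#' event probabilities inside their stated ranges, lognormal relative
#' effects around 1 (with credible intervals consistent with the sampling
#' noise model), costs uniform in a range, ordered utilities, and the full
#' long-term/structural block at base-case defaults. Deterministic under
#' `seed`; the result passes [validate_inputs()] and round-trips through
#' [write_inputs()]/[load_inputs()].
#'
#' @param n_strategies Number of strategies in the panel (the first is the
#'   comparator).
#' @param seed Integer seed.
#' @param effect_range Range of risk ratios for DVT/PE effects.
#' @param cost_range Intervention cost range in GBP.
#' @param noise_frac SE as a fraction of the mean used to synthesise
#'   credible intervals.
#' @return A validated `vte_inputs` object (population label
#'   `"synthetic"`).
#' @export
make_inputs <- function(n_strategies = 6, seed = 1L,
                        effect_range = c(0.3, 3), cost_range = c(0, 400),
                        noise_frac = 0.2) {
  stopifnot(n_strategies >= 2)
  set.seed(seed)
  template <- read_raw_inputs(fixture_file("eTHR"))
  raw <- template[!template$block %in%
                    c("strategy", "risk_dvt", "risk_pe", "risk_gi_ich",
                      "risk_ssb", "risk_other_mb", "risk_crnmb",
                      "cost_pharm", "cost_mech", "duration_days"), ]
  setv <- function(raw, block, name, value) {
    raw$value[raw$block == block & raw$name == name] <- value
    raw
  }
  total_dvt <- stats::runif(1, 0.04, 0.15)
  sympt <- total_dvt * stats::runif(1, 0.05, 0.3)
  raw <- setv(raw, "baseline", "total_dvt", total_dvt)
  raw <- setv(raw, "baseline", "symptomatic_dvt", sympt)
  raw <- setv(raw, "baseline", "asymptomatic_dvt", total_dvt - sympt)
  raw <- setv(raw, "baseline", "nonfatal_pe", stats::runif(1, 0.002, 0.02))
  raw <- setv(raw, "baseline", "mb_surgical_site", stats::runif(1, 0.005, 0.03))
  raw <- setv(raw, "baseline", "mb_gi_ich", stats::runif(1, 0.002, 0.01))
  raw <- setv(raw, "baseline", "crnmb", stats::runif(1, 0.01, 0.05))
  u9 <- stats::runif(1, 0.55, 0.75)
  raw <- setv(raw, "utility", "post_9mo_utility", u9)
  raw <- setv(raw, "utility", "preop_utility", stats::runif(1, 0.3, u9 - 0.1))
  slugs <- c("lmwh_std_std_aes",
             sprintf("strategy_%02d", seq_len(n_strategies - 1L)))
  addrow <- function(block, name, value, lo = NA, hi = NA, note = "") {
    data.frame(block = block, name = name, value = value, se = NA_real_,
               low95 = lo, high95 = hi, note = note, stringsAsFactors = FALSE)
  }
  rows <- list(addrow("strategy", slugs, seq_along(slugs),
                      note = toupper(slugs)))
  bl <- function(nm) raw$value[raw$block == "baseline" & raw$name == nm]
  for (rk in c("risk_dvt", "risk_pe", "risk_gi_ich", "risk_ssb",
               "risk_other_mb", "risk_crnmb")) {
    base <- switch(rk, risk_dvt = bl("total_dvt"), risk_pe = bl("nonfatal_pe"),
                   risk_gi_ich = bl("mb_gi_ich"), risk_ssb = bl("mb_surgical_site"),
                   risk_other_mb = bl("mb_other"), risk_crnmb = bl("crnmb"))
    rr <- c(1, pmin(pmax(stats::rlnorm(n_strategies - 1L, 0, 0.35),
                         effect_range[1]), effect_range[2]))
    v <- pmin(base * rr, 0.95)
    width <- 1.96 * noise_frac * v
    rows[[length(rows) + 1L]] <-
      addrow(rk, slugs, v, lo = pmax(v - width, v * 0.1), hi = pmin(v + width, 0.99))
  }
  rows[[length(rows) + 1L]] <-
    addrow("cost_pharm", slugs, stats::runif(n_strategies, cost_range[1], cost_range[2]))
  rows[[length(rows) + 1L]] <- addrow("cost_mech", slugs, 0)
  rows[[length(rows) + 1L]] <-
    addrow("duration_days", slugs, sample(7:35, n_strategies, replace = TRUE))
  raw <- rbind(raw, do.call(rbind, rows))
  assemble_inputs(raw, "synthetic")
}

# Brute-force oracles used when constructing known-answer panels: exhaustive
# pairwise dominance and the exhaustive two-point blend (segment) test for
# extended dominance.
brute_force_statuses <- function(costs, qalys) {
  n <- length(costs)
  dominated <- vapply(seq_len(n), function(i)
    any(costs <= costs[i] & qalys >= qalys[i] &
          (costs < costs[i] | qalys > qalys[i])), logical(1))
  ext <- rep(FALSE, n)
  for (i in which(!dominated)) {
    for (j in which(!dominated)) {
      for (k in which(!dominated)) {
        if (j == i || k == i || qalys[j] >= qalys[k]) next
        if (qalys[j] <= qalys[i] && qalys[i] <= qalys[k]) {
          lam <- (qalys[i] - qalys[k]) / (qalys[j] - qalys[k])
          blend_cost <- lam * costs[j] + (1 - lam) * costs[k]
          if (blend_cost < costs[i] - 1e-12) ext[i] <- TRUE
        }
      }
    }
  }
  ifelse(dominated, "dominated",
         ifelse(ext, "extendedly_dominated", "nondominated"))
}

#' Construct a (cost, QALY) panel with a known cost-effectiveness answer
#'
#' Generates a random strategy cloud plus one constructed point guaranteeing
#' the feature of interest (a strictly dominated point, an above-hull point,
#' or distinct NMBs), and stores the expected answer computed at generation
#' time by exhaustive brute force (pairwise checks for dominance, the
#' two-point blend test for extended dominance, argsort for NMB ranks) —
#' independent of the package's frontier algorithms.
#'
#' @param kind `"dominance"`, `"extended_dominance"` or `"nmb_rank"`.
#' @param n Panel size before the constructed point is added.
#' @param seed Integer seed.
#' @param lambda Threshold used for the `nmb_rank` answer.
#' @return List with `points` (data frame `strategy`, `costs`, `qalys`) and
#'   `expected` (statuses or ranks).
#' @export
make_known_answer_panel <- function(kind = c("dominance", "extended_dominance",
                                             "nmb_rank"),
                                    n = 6, seed = 1L, lambda = 20000) {
  kind <- match.arg(kind)
  set.seed(seed)
  costs <- stats::runif(n, 0, 1500)
  qalys <- stats::runif(n, 8, 11)
  if (kind == "dominance") {
    i <- which.min(costs)
    costs <- c(costs, costs[i] + 50)
    qalys <- c(qalys, qalys[i] - 0.1)
  } else if (kind == "extended_dominance") {
    o <- order(qalys)
    j <- o[1]; k <- o[n]
    qm <- (qalys[j] + qalys[k]) / 2
    lam <- (qm - qalys[k]) / (qalys[j] - qalys[k])
    blend <- lam * costs[j] + (1 - lam) * costs[k]
    costs <- c(costs, blend + 200)
    qalys <- c(qalys, qm)
  }
  points <- data.frame(strategy = sprintf("s%02d", seq_along(costs)),
                       costs = costs, qalys = qalys, stringsAsFactors = FALSE)
  expected <- if (kind == "nmb_rank") {
    nmbv <- qalys * lambda - costs
    ord <- order(-nmbv, costs, points$strategy)
    r <- integer(length(nmbv)); r[ord] <- seq_along(nmbv); r
  } else brute_force_statuses(costs, qalys)
  list(points = points, expected = expected, kind = kind, lambda = lambda)
}

#' Write packaged fixtures and synthetic inputs to a directory
#'
#' @param outdir Target directory.
#' @param seed Seed for the synthetic life table/input examples.
#' @return `outdir`, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (pop in vte_populations())
    file.copy(fixture_file(pop), file.path(outdir, basename(fixture_file(pop))),
              overwrite = TRUE)
  utils::write.csv(make_life_table(), file.path(outdir, "synthetic_life_table.csv"),
                   row.names = FALSE)
  write_inputs(make_inputs(seed = seed),
               file.path(outdir, "synthetic_inputs.csv"))
  write_manifest(outdir, command = "make_fixtures", seed = seed)
  invisible(outdir)
}
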