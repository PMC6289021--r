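# Deterministic cost-effectiveness analytics: net monetary benefit,
# dominance, extended dominance, ICER frontier and ranking.

#' Net monetary benefit
#'
#' @param qalys Total QALYs.
#' @param costs Total costs in GBP.
#' @param lambda Willingness-to-pay threshold in GBP per QALY, `> 0`.
#' @return `qalys * lambda - costs`.
#' @export
nmb <- function(qalys, costs, lambda) {
  stopifnot(lambda > 0)
  qalys * lambda - costs
}

#' Mark strictly dominated strategies
#'
#' A point is dominated if another point has lower-or-equal cost and
#' higher-or-equal QALYs with at least one strict inequality. Exact ties on
#' both axes are retained (neither dominates).
#'
#' @param costs,qalys Numeric vectors of equal length (`>= 2`).
#' @return Logical vector: `TRUE` where dominated.
#' @export
dominance_filter <- function(costs, qalys) {
  n <- length(costs)
  stopifnot(n >= 2, length(qalys) == n)
  vapply(seq_len(n), function(i) {
    any(costs <= costs[i] & qalys >= qalys[i] &
          (costs < costs[i] | qalys > qalys[i]))
  }, logical(1))
}

#' Extended dominance and the ICER frontier
#'
#' Starting from the strategies surviving strict dominance, iteratively
#' removes points lying above the lower-left convex hull in (QALY, cost)
#' space — equivalently, points whose removal restores a non-decreasing ICER
#' sequence along the cost-ordered frontier.
#'
#' @param costs,qalys Numeric vectors of equal length.
#' @param dominated Optional logical vector from [dominance_filter()];
#'   computed if missing.
#' @return List with `status` (character: `nondominated`, `dominated`,
#'   `extendedly_dominated`), `frontier` (indices ordered by cost) and
#'   `icer` (NA off the frontier; the first frontier member has no ICER).
#' @export
extended_dominance_filter <- function(costs, qalys, dominated = NULL) {
  n <- length(costs)
  if (is.null(dominated)) {
    dominated <- if (n >= 2) dominance_filter(costs, qalys) else rep(FALSE, n)
  }
  status <- ifelse(dominated, "dominated", "nondominated")
  cand <- which(!dominated)
  cand <- cand[order(costs[cand], -qalys[cand])]
  repeat {
    if (length(cand) < 3) break
    ic <- diff(costs[cand]) / diff(qalys[cand])
    drop <- which(diff(ic) < 0)
    if (!length(drop)) break
    status[cand[drop[1] + 1L]] <- "extendedly_dominated"
    cand <- cand[-(drop[1] + 1L)]
  }
  icer <- rep(NA_real_, n)
  if (length(cand) > 1)
    icer[cand[-1]] <- diff(costs[cand]) / diff(qalys[cand])
  list(status = status, frontier = cand, icer = icer)
}

#' Rank strategies by net monetary benefit
#'
#' Rank 1 is the highest NMB; ties are broken by lower cost, then by
#' lexicographic name.
#'
#' @param nmb_values Numeric vector of NMBs.
#' @param costs Numeric vector of total costs (tie-break).
#' @param names Character vector of strategy names (tie-break).
#' @return Integer ranks (a permutation of `seq_along(nmb_values)`).
#' @export
rank_by_nmb <- function(nmb_values, costs = NULL, names = NULL) {
  n <- length(nmb_values)
  if (is.null(costs)) costs <- numeric(n)
  if (is.null(names)) names <- as.character(seq_len(n))
  ord <- order(-nmb_values, costs, names)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  ranks
}

#' Assemble the deterministic cost-effectiveness table
#'
#' @param results Data frame with columns `strategy`, `qalys`, `costs`.
#' @param lambda Threshold in GBP per QALY.
#' @param comparator Strategy name for the INMB reference.
#' @return A `vte_ce` data frame: totals, incrementals vs the comparator,
#'   NMB/INMB, dominance status, frontier ICERs and NMB rank.
#' @export
ce_table <- function(results, lambda, comparator) {
  stopifnot(all(c("strategy", "qalys", "costs") %in% names(results)))
  i0 <- match(comparator, results$strategy)
  if (is.na(i0)) stop("comparator not in results: ", comparator)
  out <- results
  out$nmb <- nmb(out$qalys, out$costs, lambda)
  out$inc_qalys <- out$qalys - out$qalys[i0]
  out$inc_costs <- out$costs - out$costs[i0]
  out$inmb <- out$nmb - out$nmb[i0]
  ed <- extended_dominance_filter(out$costs, out$qalys)
  out$status <- ed$status
  out$icer <- ed$icer
  out$rank <- rank_by_nmb(out$nmb, out$costs, out$strategy)
  attr(out, "lambda") <- lambda
  attr(out, "comparator") <- comparator
  class(out) <- c("vte_ce", "data.frame")
  out
}
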