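# Pipeline glue: evaluate all strategies, assemble result tables, write
# reports and run manifests.

#' Evaluate one strategy end to end
#'
#' Runs the 90-day decision tree, chains its entry distribution into the
#' lifetime Markov model and returns total discounted outcomes.
#'
#' @param inputs A `vte_inputs` object.
#' @param strategy Strategy slug.
#' @return List with the `vte_acute` object, the `vte_trace`, and `totals`
#'   (QALYs, costs, cost breakdown).
#' @export
run_strategy <- function(inputs, strategy) {
  acute <- run_acute(inputs, strategy)
  trace <- run_cohort(acute$entry_distribution, inputs)
  list(acute = acute, trace = trace,
       totals = total_outcomes(acute, trace, inputs))
}

model_results <- function(inputs) {
  sl <- inputs$strategies$strategy
  runs <- lapply(sl, function(s) run_strategy(inputs, s))
  names(runs) <- sl
  res <- data.frame(
    strategy = sl,
    label = inputs$strategies$label,
    qalys = vapply(runs, function(r) r$totals$qalys, numeric(1)),
    costs = vapply(runs, function(r) r$totals$costs, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(results = res, runs = runs)
}

#' Deterministic base-case analysis for one population
#'
#' Point-estimate run of every strategy, ranked by net monetary benefit at
#' the configured threshold, with per-1,000 event tallies and a
#' per-category cost breakdown. When `outdir` is given, writes
#' `ce_results.csv`, `tallies.csv`, `cost_breakdown.csv` and a
#' `manifest.json`.
#'
#' @param population `"eTHR"` or `"eTKR"`, ignored when `inputs` is given.
#' @param inputs Optional pre-loaded `vte_inputs` (overrides `population`).
#' @param lambda Optional threshold override (GBP/QALY).
#' @param outdir Optional output directory.
#' @return A `vte_base_case` list: `ce` table, `tallies`, `cost_breakdown`,
#'   and the per-strategy runs.
#' @export
run_base_case <- function(population = c("eTHR", "eTKR"), inputs = NULL,
                          lambda = NULL, outdir = NULL) {
  if (is.null(inputs)) inputs <- load_inputs(match.arg(population))
  if (is.null(lambda)) lambda <- inputs$settings$threshold_lambda
  mr <- model_results(inputs)
  ce <- ce_table(mr$results, lambda, inputs$comparator)
  tallies <- do.call(rbind, lapply(names(mr$runs), function(s) {
    t <- mr$runs[[s]]$acute$tallies_per_1000
    cbind(strategy = s, t)
  }))
  breakdown <- do.call(rbind, lapply(names(mr$runs), function(s) {
    as.data.frame(c(list(strategy = s),
                    as.list(mr$runs[[s]]$totals$cost_breakdown)))
  }))
  out <- structure(list(population = inputs$population, ce = ce,
                        tallies = tallies, cost_breakdown = breakdown,
                        runs = mr$runs, inputs = inputs),
                   class = "vte_base_case")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(ce), file.path(outdir, "ce_results.csv"),
                     row.names = FALSE)
    utils::write.csv(tallies, file.path(outdir, "tallies.csv"),
                     row.names = FALSE)
    utils::write.csv(breakdown, file.path(outdir, "cost_breakdown.csv"),
                     row.names = FALSE)
    write_manifest(outdir, command = "run_base_case",
                   population = inputs$population, lambda = lambda)
  }
  out
}

#' @export
print.vte_base_case <- function(x, ...) {
  cat("<vte_base_case>", x$population, "\n")
  ce <- as.data.frame(x$ce)
  ce <- ce[order(ce$rank), c("strategy", "qalys", "costs", "inmb", "rank")]
  ce$qalys <- round(ce$qalys, 3)
  ce$costs <- round(ce$costs)
  ce$inmb <- round(ce$inmb)
  print(ce, row.names = FALSE)
  invisible(x)
}

write_manifest <- function(outdir, ...) {
  info <- list(...)
  info$package_version <- as.character(utils::packageVersion("vtecea"))
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(info, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(info)
}
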