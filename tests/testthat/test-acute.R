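test_that("terminal branch probabilities conserve mass for every strategy", {
  for (pop in vte_populations()) {
    inp <- get_inputs(pop)
    for (s in inp$strategies$strategy) {
      tree <- build_acute_tree(inp, s)
      expect_lt(abs(sum(tree$prob) - 1), 1e-12)
      expect_true(all(tree$prob >= 0))
    }
  }
})

test_that("zero event risks collapse the tree to a single no-event branch", {
  inp <- zero_acute_risks(get_inputs("eTHR"))
  tree <- build_acute_tree(inp, "lmwh_std_std_aes")
  expect_equal(tree$prob[tree$event == "none" & tree$asympt == "none"], 1)
  expect_equal(sum(tree$prob), 1)
})

test_that("GI bleeds split 13% intervention and SSI surgery splits 1:1", {
  inp <- get_inputs("eTHR")
  tree <- build_acute_tree(inp, "lmwh_std_std_aes")
  p <- function(ev) sum(tree$prob[tree$event == ev])
  expect_equal(p("gi_bleed_intervention") /
                 (p("gi_bleed_intervention") + p("gi_bleed_medical")), 0.13,
               tolerance = 1e-12)
  expect_equal(p("ssi_revision"), p("ssi_return_theatre"), tolerance = 1e-15)
})

test_that("raising one event risk raises its tally and lowers no-event mass", {
  inp <- get_inputs("eTHR")
  base_tree <- build_acute_tree(inp, "lmwh_std_std_aes")
  up <- inp
  i <- up$absolute_risks$strategy == "lmwh_std_std_aes"
  up$absolute_risks$ssb[i] <- up$absolute_risks$ssb[i] * 2
  up_tree <- build_acute_tree(up, "lmwh_std_std_aes")
  tally <- function(tr, ev) sum(tr$prob[tr$event == ev])
  expect_gt(tally(up_tree, "ssb_return_theatre"), tally(base_tree, "ssb_return_theatre"))
  expect_lt(tally(up_tree, "none"), tally(base_tree, "none"))
})

test_that("three-event toy tallies match exhaustive enumeration", {
  p_dvt <- 0.10; p_ssb <- 0.05; p_crnmb <- 0.08
  inp <- toy_three_event_inputs(get_inputs("eTHR"), p_dvt, p_ssb, p_crnmb)
  tree <- build_acute_tree(inp, inp$comparator)
  # independent oracle: enumerate the 8 joint outcomes of three independent
  # events resolved by priority DVT > major bleeding > CRNMB
  oracle <- c(dvt = 0, ssb = 0, crnmb = 0, none = 0)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    pr <- (if (a) p_dvt else 1 - p_dvt) * (if (b) p_ssb else 1 - p_ssb) *
      (if (cc) p_crnmb else 1 - p_crnmb)
    win <- if (a) "dvt" else if (b) "ssb" else if (cc) "crnmb" else "none"
    oracle[win] <- oracle[win] + pr
  }
  p <- function(ev) sum(tree$prob[tree$event == ev])
  expect_equal(p("sympt_prox_dvt"), unname(oracle["dvt"]), tolerance = 1e-12)
  expect_equal(p("ssb_return_theatre"), unname(oracle["ssb"]), tolerance = 1e-12)
  expect_equal(p("crnmb_medical"), unname(oracle["crnmb"]), tolerance = 1e-12)
  expect_equal(p("none"), unname(oracle["none"]), tolerance = 1e-12)
})

test_that("HIT branches carry mass only for heparin-containing strategies", {
  inp <- get_inputs("eTHR")
  hit_kinds <- c("hit_success", "hit_thrombosis_dvt", "hit_thrombosis_pe",
                 "hit_mb", "hit_death", "hit_amputation")
  tree_aes <- build_acute_tree(inp, "aes")
  expect_equal(sum(tree_aes$prob[tree_aes$event %in% hit_kinds]), 0)
  tree_lmwh <- build_acute_tree(inp, "lmwh_std_std")
  expect_gt(sum(tree_lmwh$prob[tree_lmwh$event %in% hit_kinds]), 0)
})

test_that("branches map to the correct Markov entry states", {
  inp <- get_inputs("eTHR")
  tree <- build_acute_tree(inp, "lmwh_std_std_aes")
  entry <- entry_distribution(tree)
  expect_lt(abs(sum(entry) - 1), 1e-12)
  p <- function(ev) sum(tree$prob[tree$event %in% ev])
  expect_equal(unname(entry["dead"]),
               p(c("fatal_pe", "fatal_mb", "hit_death")), tolerance = 1e-15)
  expect_equal(unname(entry["disabled_post_stroke"]), p("ich_stroke"),
               tolerance = 1e-15)
  expect_equal(unname(entry["post_revision_infection"]), p("ssi_revision"),
               tolerance = 1e-15)
  expect_equal(unname(entry["amputated_post_hit"]), p("hit_amputation"),
               tolerance = 1e-15)
  expect_equal(unname(entry["post_pe"]),
               p(c("nonfatal_pe", "hit_thrombosis_pe")), tolerance = 1e-15)
})

test_that("VTE treatment bundles cost nothing for undiagnosed events", {
  inp <- get_inputs("eTHR")
  expect_equal(acute_treatment_assignment("asympt_prox_dvt", inp), 0)
  expect_equal(acute_treatment_assignment("asympt_dist_dvt", inp), 0)
  expect_equal(acute_treatment_assignment("sympt_prox_dvt", inp), 457)
  expect_equal(acute_treatment_assignment("nonfatal_pe", inp), 991)
  expect_error(acute_treatment_assignment("ssb_return_theatre", inp), "not a VTE kind")
})
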