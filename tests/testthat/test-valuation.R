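test_that("the baseline trajectory interpolates preop to the 9-month value", {
  inp <- get_inputs("eTHR")
  u0 <- inp$utilities$preop_utility
  u9 <- inp$utilities$post_9mo_utility
  expect_equal(baseline_utility(0, inp), u0)
  expect_equal(baseline_utility(270, inp), u9)
  expect_equal(baseline_utility(135, inp), (u0 + u9) / 2)
  expect_equal(baseline_utility(500, inp), u9) # constant after nine months
  expect_equal(baseline_utility(270, get_inputs("eTHR")), 0.579)
  expect_equal(baseline_utility(270, get_inputs("eTKR")), 0.582)
})

test_that("discounting spares the first year and compounds afterwards", {
  expect_equal(discount_factor(0.5, 0.035), 1)
  expect_equal(discount_factor(2, 0.035), 1.035^-1, tolerance = 1e-9)
  expect_equal(discount_factor(10, 0), 1)
  expect_true(all(diff(discount_factor(seq(0, 30, 0.5), 0.035)) <= 0))
})

test_that("acute QALYs are bounded by the 90-day window", {
  for (pop in vte_populations()) {
    inp <- get_inputs(pop)
    for (s in inp$strategies$strategy) {
      q <- acute_qalys(build_acute_tree(inp, s), inp)
      expect_lte(q, 90 / 365.25)
      expect_gte(q, -0.594 * 90 / 365.25)
    }
  }
})

test_that("a risk-free cohort accrues the plain trajectory integral", {
  inp <- zero_acute_risks(get_inputs("eTHR"))
  tree <- build_acute_tree(inp, "lmwh_std_std_aes")
  # analytic integral of the linear trajectory over days 0-90 (the daily
  # midpoint rule is exact for a linear function)
  u0 <- inp$utilities$preop_utility
  u9 <- inp$utilities$post_9mo_utility
  expected <- (u0 + (u0 + 90 / 270 * (u9 - u0))) / 2 * 90 / 365.25
  expect_equal(acute_qalys(tree, inp), expected, tolerance = 1e-12)
})

test_that("removing an event disutility weakly increases acute QALYs", {
  inp <- get_inputs("eTHR")
  q0 <- acute_qalys(build_acute_tree(inp, "lmwh_std_std_aes"), inp)
  inp2 <- inp
  inp2$disutility$rel_major_bleed <- 0
  q1 <- acute_qalys(build_acute_tree(inp2, "lmwh_std_std_aes"), inp2)
  expect_gte(q1, q0)
})

test_that("Markov state values expose the printed annual costs", {
  inp <- get_inputs("eTHR")
  expect_equal(state_value("pts_severe_y1", 0, inp)$cost, 3824)
  expect_equal(state_value("cteph_chronic", 3, inp)$cost, 13967)
  expect_equal(state_value("well", 3, inp)$cost, 0)
  expect_equal(state_value("well", 3, inp)$utility,
               inp$utilities$post_9mo_utility)
  expect_error(state_value("limbo", 1, inp), "unknown state")
})

test_that("cost breakdown categories sum to the total cost", {
  inp <- get_inputs("eTHR")
  for (s in c("lmwh_std_std_aes", "none", "aspirin")) {
    r <- run_strategy(inp, s)
    expect_equal(sum(r$totals$cost_breakdown), r$totals$costs, tolerance = 0.01)
  }
})

test_that("costs scale linearly and QALYs are unaffected", {
  inp <- get_inputs("eTHR")
  r1 <- run_strategy(inp, "lmwh_std_std_aes")
  r2 <- run_strategy(vtecea:::scale_all_costs(inp, 2), "lmwh_std_std_aes")
  expect_equal(r2$totals$costs, 2 * r1$totals$costs, tolerance = 1e-9)
  expect_equal(r2$totals$qalys, r1$totals$qalys)
})

test_that("discounted totals never exceed undiscounted, equal at rate zero", {
  inp <- get_inputs("eTHR")
  acute <- run_acute(inp, "lmwh_std_std_aes")
  tr <- run_cohort(acute$entry_distribution, inp)
  expect_lte(sum(tr$dqaly), sum(tr$qaly))
  expect_lte(sum(tr$dcost), sum(tr$cost))
  inp0 <- inp
  inp0$settings$discount_rate <- 0
  tr0 <- run_cohort(acute$entry_distribution, inp0)
  expect_equal(sum(tr0$dqaly), sum(tr0$qaly))
  expect_equal(sum(tr0$dcost), sum(tr0$cost))
})

test_that("a zero-risk strategy costs exactly its intervention cost", {
  inp <- zero_acute_risks(get_inputs("eTHR"))
  r <- run_strategy(inp, "lmwh_std_std_aes")
  expect_equal(r$totals$costs, strategy_total_cost("lmwh_std_std_aes", inp),
               tolerance = 1e-9)
})

test_that("a frozen toy strategy matches a hand-audited spreadsheet oracle", {
  # one event only (symptomatic proximal DVT, p = 0.1), flat 1% mortality,
  # no long-term morbidity, 3-year horizon, zero discounting
  p <- 0.1
  inp <- toy_three_event_inputs(get_inputs("eTHR"), p, 0, 0)
  inp <- zero_morbidity(inp)
  inp$life_table <- flat_life_table(0.01)
  inp$settings$discount_rate <- 0
  acute <- run_acute(inp, inp$comparator)
  tr <- run_cohort(acute$entry_distribution, inp, horizon_years = 3)
  tot <- total_outcomes(acute, tr, inp)
  # oracle: explicit spreadsheet-style arithmetic
  u0 <- inp$utilities$preop_utility
  u9 <- inp$utilities$post_9mo_utility
  traj <- function(d) u0 + pmin(d, 270) / 270 * (u9 - u0)
  days <- seq(0.5, 89.5)
  q_none <- sum(traj(days)) / 365.25
  q_dvt <- sum(ifelse(days < 7, traj(days),
                      traj(days) * (1 - 0.14) - 0.012 * 0.5)) / 365.25
  exp_acute_q <- (1 - p) * q_none + p * q_dvt
  exp_acute_c <- 169 + p * 457
  expect_equal(acute$acute_qalys, exp_acute_q, tolerance = 1e-12)
  expect_equal(acute$acute_cost, exp_acute_c, tolerance = 1e-12)
  # Markov: everyone alive stays well-like; utility year 1 is the mean of
  # the trajectory over days 90-455, later years the 9-month value
  u90 <- traj(90)
  base0 <- ((u90 + u9) / 2 * 180 + u9 * (365.25 - 270)) / (365.25 - 90)
  alive <- c(1, 0.99, 0.99^2)
  exp_markov_q <- alive[1] * base0 + (alive[2] + alive[3]) * u9
  expect_equal(sum(tr$qaly), exp_markov_q, tolerance = 1e-12)
  expect_equal(tot$costs, exp_acute_c, tolerance = 1e-12) # no state costs accrue
  expect_equal(tot$qalys, exp_acute_q + exp_markov_q, tolerance = 1e-12)
})
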