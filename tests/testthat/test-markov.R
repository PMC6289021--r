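test_that("rate and probability conversions match closed forms and invert", {
  expect_equal(rate_from_probability(0, 5), 0)
  expect_equal(rate_from_probability(0.032, 2), -log(0.968) / 2, tolerance = 1e-12)
  expect_equal(rate_from_probability(0.40, 2), -log(0.6) / 2, tolerance = 1e-12)
  expect_error(rate_from_probability(1, 2), "infinite rate")
  expect_equal(probability_from_rate(0, 1), 0)
  expect_equal(probability_from_rate(0.0162624, 1), 1 - exp(-0.0162624),
               tolerance = 1e-12)
  # round trip: 2-year probability -> annual probability -> recomposition
  p_annual <- probability_from_rate(rate_from_probability(0.15, 2), 1)
  expect_equal(1 - (1 - p_annual)^2, 0.15, tolerance = 1e-12)
})

test_that("transition matrix rows are stochastic and mortality enters each row", {
  inp <- get_inputs("eTHR")
  for (k in c(0, 1, 2, 10)) {
    M <- build_transition_matrix(inp, k, 70 + k)
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0))
  }
  # with background mortality q only, the well row is (1-q, 0, ..., q)
  inp0 <- zero_morbidity(inp)
  inp0$life_table <- flat_life_table(0.02)
  M <- build_transition_matrix(inp0, 0, 70)
  expect_equal(unname(M["well", "well"]), 0.98)
  expect_equal(unname(M["well", "dead"]), 0.02)
  # zero morbidity and zero mortality: every entry state is absorbing
  inp0$life_table <- flat_life_table(0)
  M0 <- build_transition_matrix(inp0, 0, 70)
  entry_states <- c("well", "post_sympt_prox_dvt", "post_sympt_dist_dvt",
                    "post_asympt_prox_dvt", "post_asympt_dist_dvt", "post_pe",
                    "disabled_post_stroke", "amputated_post_hit",
                    "post_revision_infection", "dead")
  expect_equal(unname(diag(M0[entry_states, entry_states])),
               rep(1, length(entry_states)))
})

test_that("tunnel states hold occupancy for exactly one cycle", {
  inp <- get_inputs("eTHR")
  inp$life_table <- flat_life_table(0)
  M <- build_transition_matrix(inp, 0, 70)
  for (s in c("pts_mildmod_y1", "pts_severe_y1", "cteph_y1", "cteph_recurrent_y2"))
    expect_equal(unname(M[s, s]), 0)
  # once the onset window closes, no new tunnel entries occur
  entry <- c(post_pe = 1)
  tr <- run_cohort(entry, inp, horizon_years = 6)
  expect_equal(tr$occupancy[4:6, "cteph_y1"], rep(0, 3))
  expect_equal(tr$occupancy[4:6, "pts_severe_y1"], rep(0, 3))
})

test_that("two-cycle onset composes to the stated 2-year incidences", {
  inp <- zero_morbidity(get_inputs("eTHR"))
  inp$life_table <- flat_life_table(0)
  lt0 <- get_inputs("eTHR")$long_term
  # PTS from each DVT antecedent (single competing onset): exact composition
  cases <- list(post_sympt_prox_dvt = lt0$pts_2yr_sympt_prox,
                post_sympt_dist_dvt = lt0$pts_2yr_sympt_dist,
                post_asympt_prox_dvt = lt0$pts_2yr_asympt_prox,
                post_asympt_dist_dvt = lt0$pts_2yr_asympt_dist)
  for (s in names(cases)) {
    inp2 <- inp
    nm <- sub("post_(.*)_dvt", "pts_2yr_\\1", s)
    inp2$long_term[[nm]] <- cases[[s]]
    tr <- run_cohort(stats::setNames(1, s), inp2, horizon_years = 4)
    pts_mass <- sum(tr$occupancy[3, c("pts_mildmod_y1", "pts_severe_y1",
                                      "pts_mildmod_chronic", "pts_severe_chronic")])
    expect_equal(pts_mass, cases[[s]], tolerance = 1e-9)
  }
  # CTEPH after PE with no competing PTS onset: exact composition
  inp3 <- inp
  inp3$long_term$cteph_2yr_after_pe <- lt0$cteph_2yr_after_pe
  tr <- run_cohort(c(post_pe = 1), inp3, horizon_years = 4)
  cteph_mass <- sum(tr$occupancy[3, c("cteph_y1", "cteph_recurrent_y2",
                                      "cteph_chronic", "cteph_treated")])
  expect_equal(cteph_mass, lt0$cteph_2yr_after_pe, tolerance = 1e-9)
  # with the competing PTS onset active the composition attenuates slightly
  inp4 <- inp3
  inp4$long_term$pts_2yr_pe <- lt0$pts_2yr_pe
  tr4 <- run_cohort(c(post_pe = 1), inp4, horizon_years = 4)
  cteph4 <- sum(tr4$occupancy[3, c("cteph_y1", "cteph_recurrent_y2",
                                   "cteph_chronic", "cteph_treated")])
  expect_lt(cteph4, lt0$cteph_2yr_after_pe)
  expect_equal(cteph4, lt0$cteph_2yr_after_pe, tolerance = 0.1)
})

test_that("cohort traces conserve occupancy and the dead state is monotone", {
  inp <- get_inputs("eTHR")
  acute <- run_acute(inp, "lmwh_std_std_aes")
  tr <- run_cohort(acute$entry_distribution, inp)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
  expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
  expect_error(run_cohort(c(well = 1), inp, horizon_years = 0.5), "horizon")
})

test_that("trace occupancy equals the matrix-power oracle", {
  inp <- get_inputs("eTHR")
  entry <- c(well = 0.7, post_sympt_prox_dvt = 0.1, post_pe = 0.1,
             disabled_post_stroke = 0.05, dead = 0.05)
  tr <- run_cohort(entry, inp, horizon_years = 8)
  age0 <- inp$cohort$start_age + 90 / 365.25
  v <- stats::setNames(numeric(length(markov_states())), markov_states())
  v[names(entry)] <- entry
  for (k in 0:7) {
    expect_lt(max(abs(tr$occupancy[k + 1, ] - v)), 1e-12)
    v <- as.vector(v %*% build_transition_matrix(inp, k, age0 + k))
    names(v) <- markov_states()
  }
})

test_that("degenerate cohorts behave at the boundaries", {
  inp <- get_inputs("eTHR")
  tr <- run_cohort(c(dead = 1), inp, horizon_years = 5)
  expect_equal(sum(tr$dqaly), 0)
  expect_equal(sum(tr$dcost), 0)
  # certain death after the first cycle
  inp1 <- inp
  inp1$life_table <- flat_life_table(1)
  tr1 <- run_cohort(c(well = 1), inp1, horizon_years = 5)
  expect_equal(unname(tr1$occupancy[2, "dead"]), 1)
})

test_that("zero-morbidity undiscounted QALYs at full utility equal life expectancy", {
  inp <- zero_morbidity(get_inputs("eTHR"))
  inp$settings$discount_rate <- 0
  inp$utilities$preop_utility <- 1
  inp$utilities$post_9mo_utility <- 1
  tr <- run_cohort(c(well = 1), inp)
  le <- life_expectancy(inp$life_table, inp$cohort$start_age + 90 / 365.25)
  expect_equal(sum(tr$qaly), le, tolerance = 1e-9)
})
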