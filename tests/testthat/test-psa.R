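test_that("default distribution families follow the documented rules", {
  inp <- get_inputs("eTHR")
  d <- assign_distributions(inp)
  expect_true(all(d$family[d$block == "event_cost" & d$mean > 0] == "gamma"))
  expect_true(all(d$family[d$name == "total_dvt"] == "beta"))
  # printed counts drive the wound haematoma beta
  wh <- d[d$name == "wound_haematoma_frac", ]
  expect_equal(c(wh$shape1, wh$shape2), c(5, 17))
  # the comparator's effects are fixed at 1
  cmp <- d[d$block == "effect" & d$strategy == "lmwh_std_std_aes", ]
  expect_true(all(cmp$family == "fixed"))
  expect_true(all(cmp$mean[cmp$name %in% c("rr_dvt", "rr_pe")] == 1))
})

test_that("sampled parameter sets respect their domains", {
  inp <- get_inputs("eTHR")
  d <- assign_distributions(inp)
  prep <- vtecea:::prep_draw_plan(inp, d)
  set.seed(5)
  for (i in 1:50) {
    di <- vtecea:::draw_from_plan(inp, prep)
    for (nm in c("total_dvt", "nonfatal_pe", "crnmb", "hit",
                 "wound_haematoma_frac"))
      expect_true(di$baseline[[nm]] >= 0 && di$baseline[[nm]] <= 1)
    expect_true(all(unlist(di$event_costs) >= 0))
    expect_true(all(di$effects$rr_dvt > 0))
    ar <- di$absolute_risks
    expect_true(all(ar$dvt >= 0 & ar$dvt <= 1))
    expect_true(all(ar$pe >= 0 & ar$pe <= 1))
  }
})

test_that("sampling means converge to the specified moments", {
  inp <- get_inputs("eTHR")
  d <- assign_distributions(inp)
  prep <- vtecea:::prep_draw_plan(inp, d)
  set.seed(99)
  n <- 2000
  cost_draws <- prob_draws <- numeric(n)
  for (i in seq_len(n)) {
    di <- vtecea:::draw_from_plan(inp, prep)
    cost_draws[i] <- di$event_costs$sympt_prox_dvt
    prob_draws[i] <- di$baseline$crnmb
  }
  # gamma cost: mean 457, SE 20% of mean
  expect_lt(abs(mean(cost_draws) - 457), 3 * 0.2 * 457 / sqrt(n))
  expect_lt(abs(sd(cost_draws) - 0.2 * 457), 0.2 * 457 * 0.15)
  # beta probability: mean 0.0295, SE 20% of mean
  expect_lt(abs(mean(prob_draws) - 0.0295), 3 * 0.2 * 0.0295 / sqrt(n))
})

test_that("degenerate distributions reproduce the deterministic run", {
  inp <- get_inputs("eTHR")
  d <- assign_distributions(inp)
  d$family[] <- "fixed"
  psa <- run_psa(inp, n_iter = 3, seed = 1, dists = d)
  bc <- run_base_case(inputs = inp)
  expect_equal(unname(psa$qalys[1, ]), bc$ce$qalys, tolerance = 1e-10)
  expect_equal(unname(psa$costs[1, ]), bc$ce$costs, tolerance = 1e-10)
  expect_true(all(apply(psa$qalys, 2, function(x) diff(range(x))) == 0))
  # the deterministic rank lies inside every degenerate rank interval
  det_rank <- bc$ce$rank[match(psa$summary$strategy, bc$ce$strategy)]
  expect_true(all(psa$summary$rank_lo <= det_rank & det_rank <= psa$summary$rank_hi))
})

test_that("identical seeds give identical summaries", {
  inp <- get_inputs("eTKR")
  a <- run_psa(inp, n_iter = 25, seed = 123)
  b <- run_psa(inp, n_iter = 25, seed = 123)
  expect_identical(a$summary, b$summary)
  expect_identical(a$qalys, b$qalys)
  c <- run_psa(inp, n_iter = 25, seed = 124)
  expect_false(identical(a$qalys, c$qalys))
})

test_that("probabilities of being most cost-effective partition the draws", {
  inp <- get_inputs("eTKR")
  psa <- run_psa(inp, n_iter = 40, seed = 2)
  expect_lt(abs(sum(psa$summary$prob_ce) - 1), 1e-9)
  expect_true(all(psa$summary$qalys_lo <= psa$summary$qalys_hi))
  expect_true(all(psa$summary$rank_lo <= psa$summary$rank_hi))
})

test_that("acceptability curves sum to one and respect degenerate cases", {
  # single iteration: indicator curves
  q <- matrix(c(10, 9.5), 1, 2, dimnames = list(NULL, c("a", "b")))
  cc <- matrix(c(100, 50), 1, 2, dimnames = list(NULL, c("a", "b")))
  cv <- ceac(q, cc, lambda_grid = c(0, 1000, 1e6))
  expect_true(all(cv$probability %in% c(0, 1)))
  for (l in unique(cv$lambda))
    expect_equal(sum(cv$probability[cv$lambda == l]), 1)
  # at lambda 0 the cheaper strategy wins; at a high lambda the better one
  expect_equal(cv$probability[cv$lambda == 0 & cv$strategy == "b"], 1)
  expect_equal(cv$probability[cv$lambda == 1e6 & cv$strategy == "a"], 1)
})

test_that("the CEAC matches the closed-form normal benchmark", {
  # two strategies whose incremental NMB is exactly N(mu, sd): the CEAC of
  # the first equals Phi(mu/sd) up to Monte-Carlo error at n = 10,000
  set.seed(31)
  n <- 10000
  mu <- 300; s <- 900
  inmb <- rnorm(n, mu, s)
  q <- cbind(a = rep(0, n), b = rep(0, n))
  cc <- cbind(a = -inmb, b = rep(0, n))
  cv <- ceac(q, cc, lambda_grid = 20000)
  p_a <- cv$probability[cv$strategy == "a"]
  p_true <- pnorm(mu / s)
  mc_se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_a - p_true), 3 * mc_se)
})

test_that("a stochastically dominant strategy never drops below the comparator's CEAC", {
  set.seed(17)
  n <- 400
  q <- cbind(good = rnorm(n, 10.1, 0.2), base = rnorm(n, 10.1, 0.2))
  q[, "good"] <- q[, "base"] + abs(rnorm(n, 0.05, 0.01))
  cc <- cbind(good = rep(100, n), base = rep(100, n))
  cv <- ceac(q, cc, lambda_grid = c(1000, 10000, 30000))
  for (l in unique(cv$lambda)) {
    pg <- cv$probability[cv$lambda == l & cv$strategy == "good"]
    pb <- cv$probability[cv$lambda == l & cv$strategy == "base"]
    expect_gte(pg, pb)
  }
})
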