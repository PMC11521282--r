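lt0 <- zero_mortality_lt()

test_that("event-free runs match the closed-form annuity", {
  params <- toy_params()  # all event probabilities zero
  cfg <- sim_config(horizon = 5, n_trials = 10, seed = 1)
  for (fn in list(cohort_expectation, run_microsimulation)) {
    bha <- fn(cfg, params, "BHA", lt0)
    expect_equal(bha$qaly, 0.82 * annuity(5, 0.02), tolerance = 1e-9)
    expect_equal(bha$cost,
                 (2122628 + 572000 + 195000) + 1399413 * (annuity(5, 0.02) - 1),
                 tolerance = 1e-9)
  }
  ms <- run_microsimulation(cfg, params, "BHA", lt0)
  expect_equal(ms$se_cost, 0)
  expect_equal(ms$se_qaly, 0)
  # one-year horizon: the surgery bundle replaces maintenance entirely
  cfg1 <- sim_config(horizon = 1, n_trials = 10, seed = 1)
  sb <- cohort_expectation(cfg1, params, "SB_THA", lt0)
  expect_equal(sb$cost, 2191285 + 611000 + 376900)
  expect_equal(sb$qaly, 0.870)
})

test_that("death-cycle accrual follows the configured convention", {
  params <- toy_params()
  lt_certain <- life_table(65:120, rep(1, 56))
  for (da in c("none", "half", "full")) {
    cfg <- sim_config(horizon = 3, n_trials = 5, seed = 2, death_accrual = da)
    w <- c(none = 0, half = 0.5, full = 1)[[da]]
    out <- cohort_expectation(cfg, params, "SB_THA", lt_certain)
    expect_equal(out$cost, w * (2191285 + 611000 + 376900))
    expect_equal(out$qaly, w * 0.870)
    ms <- run_microsimulation(cfg, params, "SB_THA", lt_certain)
    expect_equal(ms$cost, out$cost)
    expect_equal(ms$qaly, out$qaly)
  }
})

test_that("the dislocation tracker reduces first and revises second", {
  params <- toy_params(p_dis = 1)
  cfg <- sim_config(horizon = 3, n_trials = 5, seed = 3)
  tr <- simulate_patient(cfg, params, "SB_THA", lt0)
  # certain dislocation: reduction, then revision, then reduction on the
  # new implant (tracker resets on revision)
  expect_equal(tr$events$event, c("reduction", "revision", "reduction"))
  expect_equal(tr$events$cycle, 1:3)
  # cycle 1 utility carries the dislocation disutility
  expect_equal(simulate_patient(sim_config(horizon = 1, n_trials = 5),
                                params, "BHA", lt0)$qaly, 0.820 - 0.110)
  # cycle-1 cost includes the reduction cost on top of the bundle
  expect_equal(simulate_patient(sim_config(horizon = 1, n_trials = 5),
                                params, "BHA", lt0)$cost,
               2122628 + 572000 + 195000 + 220679)
})

test_that("revision accrual follows the transition-reward convention", {
  params <- toy_params(p_revnondis = 1)
  cfg <- sim_config(horizon = 2, n_trials = 5, seed = 4)
  tr <- simulate_patient(cfg, params, "SB_THA", lt0)
  expect_equal(tr$events$event, c("revision", "re-revision"))
  # cycle 1: origin utility + R-THA disutility; cycle 2: R-THA state
  # utility + RR-THA disutility, discounted one cycle
  expect_equal(tr$qaly, (0.870 - 0.185) + (0.685 - 0.287) / 1.02)
  # a revision year carries the revision fee, DM implant and a fresh
  # initial-year THA cost on top of the base cost
  rev_cost <- 548100 + 714000 + 2191285
  expect_equal(tr$cost, (2191285 + 611000 + 376900 + rev_cost) +
                 (1399413 + rev_cost) / 1.02)
})

test_that("no events can escape the re-revision state", {
  params <- toy_params(p_dis = 1, p_revnondis = 0)
  cfg <- sim_config(horizon = 6, n_trials = 20, seed = 5)
  ms <- run_microsimulation(cfg, params, "SB_THA", lt0, keep_trials = TRUE)
  ev <- attr(ms, "trials")$events
  # dislocations every cycle: reduce, revise, reduce, re-revise, then
  # nothing more can happen
  expect_equal(ev[1, ], c(2L, 3L, 2L, 4L, 0L, 0L))
})

test_that("death is absorbing and the event log respects revision order", {
  params <- packaged_parameters()
  cfg <- sim_config(n_trials = 2e4, seed = 6, death_accrual = "none")
  lt <- packaged_life_table("female")
  ms <- run_microsimulation(cfg, params, "SB_THA", lt, keep_trials = TRUE)
  ev <- attr(ms, "trials")$events
  # at most one revision and one re-revision per trial
  expect_lte(max(rowSums(ev == 3L)), 1)
  expect_lte(max(rowSums(ev == 4L)), 1)
  # a re-revision never precedes a revision
  has_both <- rowSums(ev == 3L) > 0 & rowSums(ev == 4L) > 0
  if (any(has_both)) {
    first <- function(m, code) apply(m == code, 1, function(x) which(x)[1])
    expect_true(all(first(ev[has_both, , drop = FALSE], 3L) <
                      first(ev[has_both, , drop = FALSE], 4L)))
  }
  # nothing after death
  died <- which(rowSums(ev == 1L) > 0)
  after_death <- vapply(died, function(i) {
    d <- which(ev[i, ] == 1L)
    all(ev[i, -(1:d)] == 0L)
  }, TRUE)
  expect_true(all(after_death))
})

test_that("same seed reproduces the run exactly", {
  params <- packaged_parameters()
  lt <- packaged_life_table("female")
  cfg <- sim_config(n_trials = 5000, seed = 7)
  a <- run_microsimulation(cfg, params, "SB_THA", lt)
  b <- run_microsimulation(cfg, params, "SB_THA", lt)
  expect_identical(a, b)
  c <- run_microsimulation(sim_config(n_trials = 5000, seed = 8),
                           params, "SB_THA", lt)
  expect_false(identical(a$cost, c$cost))
})

test_that("a two-cycle run matches the brute-force outcome enumeration", {
  params <- toy_params(p_dis = 0.5, p_revdis = 0.1, p_revnondis = 0.2,
                       rr = c(0.5, 0.8, 2, 1.1, 0.6, 0.9))
  v <- param_points(params)
  cfg <- sim_config(horizon = 2, n_trials = 10, seed = 9)
  oracle <- enumerate_two_cycles(v, "SB_THA")
  got <- cohort_expectation(cfg, params, "SB_THA", lt0)
  expect_equal(got$cost, unname(oracle["cost"]), tolerance = 1e-12)
  expect_equal(got$qaly, unname(oracle["qaly"]), tolerance = 1e-12)
})

test_that("microsimulation means converge to the cohort expectation", {
  params <- random_parameter_set(21, p_max = 0.1)
  lt <- synthetic_japan_life_table("female")
  cfg <- sim_config(n_trials = 5e4, seed = 10)
  for (s in strategies()) {
    ms <- run_microsimulation(cfg, params, s, lt)
    ce <- cohort_expectation(cfg, params, s, lt)
    expect_lt(abs(ms$cost - ce$cost), 3.5 * ms$se_cost)
    expect_lt(abs(ms$qaly - ce$qaly), 3.5 * ms$se_qaly)
  }
})

test_that("identical strategy parameters give identical expectations", {
  params <- identical_strategy_params(p_dis = 0.05, p_revnondis = 0.02)
  lt <- synthetic_japan_life_table("female")
  cfg <- sim_config(seed = 11, n_trials = 100)
  res <- evaluate_strategies(cfg, params, lt, method = "cohort")
  expect_equal(res$cost[2], res$cost[1])
  expect_equal(res$cost[3], res$cost[1])
  expect_equal(res$qaly, rep(res$qaly[1], 3))
})

test_that("discounting and config validation behave", {
  params <- toy_params()
  cfg0 <- sim_config(horizon = 5, discount_rate = 0, n_trials = 10)
  cfg4 <- sim_config(horizon = 5, discount_rate = 0.04, n_trials = 10)
  q0 <- cohort_expectation(cfg0, params, "BHA", lt0)
  q4 <- cohort_expectation(cfg4, params, "BHA", lt0)
  expect_gt(q0$qaly, q4$qaly)
  expect_gt(q0$cost, q4$cost)
  expect_equal(q0$qaly, 0.82 * 5)
  # discounting from cycle 1 shifts every term by one factor
  cfg_s <- sim_config(horizon = 5, n_trials = 10, discount_first_cycle = TRUE)
  expect_equal(cohort_expectation(cfg_s, params, "BHA", lt0)$qaly,
               0.82 * annuity(5, 0.02) / 1.02)
  expect_error(sim_config(horizon = 0), "horizon")
  expect_error(run_microsimulation(sim_config(n_trials = 1), params, "BHA", lt0),
               "n_trials")
})

test_that("competing probabilities above one are a configuration error", {
  params <- toy_params(p_dis = 0.6, p_revnondis = 0.5)
  cfg <- sim_config(n_trials = 10)
  expect_error(cohort_expectation(cfg, params, "SB_THA", lt0), "exceed 1")
})
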