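lt_f <- synthetic_japan_life_table("female")

test_that("one-way analysis at a degenerate range returns the base ICER", {
  params <- packaged_parameters()
  cfg <- sim_config(seed = 1)
  base <- param_points(params)[["c_dislocation"]]
  entry <- one_way_sa(params, "c_dislocation", c("SB_THA", "BHA"), cfg, lt_f,
                      low = base, high = base)
  res <- evaluate_strategies(cfg, params, lt_f)
  base_icer <- (res$cost[2] - res$cost[1]) / (res$qaly[2] - res$qaly[1])
  expect_equal(entry$icer_low, base_icer, tolerance = 1e-12)
  expect_equal(entry$icer_high, base_icer, tolerance = 1e-12)
})

test_that("a parameter with no effect on either arm leaves the ICER flat", {
  # BHA revision relative risks are inert under the shared-rates default
  params <- packaged_parameters()
  cfg <- sim_config(seed = 1)
  entry <- one_way_sa(params, "rr_revdis_bha_dm", c("SB_THA", "BHA"), cfg, lt_f)
  expect_equal(entry$icer_low, entry$icer_high, tolerance = 1e-12)
  expect_length(entry$thresholds[[1]], 0)
})

test_that("raising the SB well utility above DM's makes DM dominated", {
  params <- packaged_parameters()
  cfg <- sim_config(seed = 1)
  entry <- one_way_sa(params, "u_well_sb", c("DM_THA", "SB_THA"), cfg, lt_f)
  expect_equal(entry$flag_high, "dominated")  # u_well_sb = 1.0 > u_well_dm
  expect_equal(entry$flag_low, "ok")
})

test_that("threshold search solves a linear toy problem exactly", {
  tb <- data.frame(name = "x", point = 2e6, low = 0, high = 1e7, role = "cost")
  params <- cea_parameters(tb)
  # evaluator in which the incremental cost equals x and the QALY gain is 1
  evaluator <- function(v) {
    tibble::tibble(strategy = c("A", "B"), cost = c(v[["x"]], 0), qaly = c(1, 0))
  }
  cfg <- sim_config(seed = 1, wtp = 5e6)
  thr <- find_threshold(params, "x", c("A", "B"), cfg, lt_f,
                        bracket = c(0, 1e7), evaluator = evaluator)
  expect_equal(thr, 5e6, tolerance = 1e-5)
  expect_error(find_threshold(params, "x", c("A", "B"), cfg, lt_f,
                              bracket = c(0, 1e6), evaluator = evaluator),
               class = "no_threshold")
})

test_that("threshold values re-evaluate to the willingness-to-pay", {
  params <- packaged_parameters()
  cfg <- sim_config(seed = 1)
  thr <- find_threshold(params, "c_initial_tha", c("SB_THA", "BHA"), cfg, lt_f,
                        bracket = c(2191285, 3050269))
  v <- param_points(params)
  v["c_initial_tha"] <- thr
  res <- evaluate_strategies(cfg, v, lt_f)
  icer_at_thr <- (res$cost[2] - res$cost[1]) / (res$qaly[2] - res$qaly[1])
  expect_lt(abs(icer_at_thr - cfg$wtp) / cfg$wtp, 1e-4)
})

test_that("degenerate distributions make the PSA reproduce the base case", {
  params <- toy_params(p_dis = 0.03, p_revnondis = 0.02)  # all ranges zero-width
  cfg <- sim_config(seed = 5)
  psa <- run_psa(params, cfg, lt_f, n_samples = 8)
  base <- evaluate_strategies(cfg, params, lt_f)
  for (i in 1:8) {
    expect_equal(unname(psa$cost[i, ]), base$cost, tolerance = 1e-12)
    expect_equal(unname(psa$qaly[i, ]), base$qaly, tolerance = 1e-12)
  }
  expect_equal(psa$n_resampled, 0L)
})

test_that("PSA is seed-reproducible and respects distribution supports", {
  params <- packaged_parameters()
  cfg <- sim_config(seed = 12)
  a <- run_psa(params, cfg, lt_f, n_samples = 50)
  b <- run_psa(params, cfg, lt_f, n_samples = 50)
  expect_identical(a$cost, b$cost)
  expect_identical(a$draws, b$draws)
  d <- a$draws
  expect_true(all(d[, "u_well_sb"] >= 0 & d[, "u_well_sb"] <= 1))
  expect_true(all(d[, "rr_dis_dm_sb"] > 0))
  expect_true(all(d[, "c_dislocation"] > 0))
  expect_true(all(d[, "c_implant_bha"] == 572000))  # fixed stays fixed
})

test_that("acceptability probabilities are hand-countable and normalized", {
  # three hand-written samples over the three strategies
  psa <- structure(list(
    cost = rbind(c(100, 200, 300), c(100, 90, 300), c(100, 200, 50)),
    qaly = rbind(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)),
    n_resampled = 0L), class = "cea_psa")
  colnames(psa$cost) <- colnames(psa$qaly) <- strategies()
  cc <- ceac(psa, wtp_grid = c(0, 1000))
  # wtp 0: lowest cost wins each sample -> BHA, SB, DM
  p0 <- cc$probability[cc$wtp == 0]
  expect_equal(p0, c(1, 1, 1) / 3)
  # wtp 1000: nmb argmax per row -> DM (2700), SB (910), BHA (2900)
  p1 <- cc$probability[cc$wtp == 1000]
  expect_equal(p1, c(1, 1, 1) / 3)
  grid_cc <- ceac(psa)
  sums <- tapply(grid_cc$probability, grid_cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("the confidence ellipse recovers a known isotropic cloud", {
  set.seed(8)
  n <- 4000
  psa <- structure(list(
    cost = cbind(BHA = rnorm(n), SB_THA = rep(0, n), DM_THA = rep(0, n)),
    qaly = cbind(BHA = rnorm(n), SB_THA = rep(0, n), DM_THA = rep(0, n)),
    n_resampled = 0L), class = "cea_psa")
  s <- scatter_summary(psa, c("BHA", "SB_THA"))
  expect_equal(unname(s$ellipse$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.08)
  expect_equal(sum(s$quadrants), n)
  # degenerate cloud: ellipse omitted with a message
  psa0 <- psa
  psa0$cost[] <- 1
  psa0$qaly[] <- 1
  expect_message(s0 <- scatter_summary(psa0, c("BHA", "SB_THA")), "singular")
  expect_null(s0$ellipse)
})

test_that("tornado entries are sorted by descending span", {
  params <- packaged_parameters()
  cfg <- sim_config(seed = 1)
  tor <- tornado(params, c("SB_THA", "BHA"), cfg, lt_f,
                 parameters = c("u_well_bha", "c_dislocation", "c_initial_tha"))
  expect_equal(nrow(tor), 3)
  spans <- tor$span[is.finite(tor$span)]
  expect_true(!is.unsorted(rev(spans)))
  # the initial-year THA cost crosses the WTP inside its printed range
  thr <- tor$thresholds[[which(tor$parameter == "c_initial_tha")]]
  expect_length(thr, 1)
})
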