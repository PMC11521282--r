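test_that("icer reproduces published incremental arithmetic and flags", {
  r <- icer(8669497, 4.021, 8326071, 3.792)
  expect_equal(r$flag, "ok")
  expect_equal(r$value, 343426 / 0.229)
  expect_equal(icer(10, 1, 5, 1)$flag, "dominated")
  expect_equal(icer(5, 2, 10, 1)$flag, "dominant")
  expect_equal(icer(5, 1, 5, 1)$flag, "undefined")
  expect_equal(icer(5, 1 + 1e-8, 5, 1)$flag, "undefined")
  # role reversal flips the sign structure but keeps the magnitude
  a <- icer(8669497, 4.021, 8326071, 3.792)
  b <- icer(8326071, 3.792, 8669497, 4.021)
  expect_equal(a$value, b$value)
})

test_that("net monetary benefit and currency conversion are plain arithmetic", {
  expect_equal(nmb(8669497, 4.021, 5e6), 11435503)
  expect_equal(nmb(123, 1, 0), -123)
  expect_equal(convert_currency(1499440, 162), 9256)
  expect_equal(convert_currency(131, 131), 1)
  expect_equal(convert_currency(0, 162), 0)
})

test_that("the frontier orders, marks dominance and computes ICERs", {
  tb <- tibble::tibble(strategy = c("BHA", "SB_THA", "DM_THA"),
                       cost = c(8326071, 8669497, 8723401),
                       qaly = c(3.792, 4.021, 4.034))
  fr <- cea_frontier(tb)
  expect_equal(fr$status, c("reference", "on-frontier", "on-frontier"))
  expect_equal(fr$icer[2], 343426 / 0.229)
  expect_equal(fr$icer[3], 53904 / 0.013)
  # strictly dominated middle strategy
  dom <- tibble::tibble(strategy = c("A", "B", "C"),
                        cost = c(100, 200, 300), qaly = c(2, 1.5, 3))
  fd <- cea_frontier(dom)
  expect_equal(fd$status[fd$strategy == "B"], "dominated")
  expect_equal(fd$incr_cost[fd$strategy == "C"], 200)
})

test_that("extended dominance removal matches the frontier definition", {
  # middle strategy's ICER (150) exceeds the next one's (50): extended
  tb <- tibble::tibble(strategy = c("A", "B", "C"),
                       cost = c(0, 150, 250), qaly = c(0, 1, 3))
  fr <- cea_frontier(tb)
  expect_equal(fr$status, c("reference", "extended-dominated", "on-frontier"))
  # C's ICER recomputed against A directly
  expect_equal(fr$icer[3], 250 / 3)
  # frontier is idempotent: rerunning on the survivors changes nothing
  surv <- fr[fr$status != "extended-dominated", c("strategy", "cost", "qaly")]
  fr2 <- cea_frontier(surv)
  expect_equal(fr2$icer[2], fr$icer[3])
  # removing a strictly dominated strategy never changes surviving ICERs
  dom <- tibble::tibble(strategy = c("A", "B", "C"),
                        cost = c(0, 100, 250), qaly = c(0, -1, 3))
  f_all <- cea_frontier(dom)
  f_red <- cea_frontier(dom[dom$strategy != "B", ])
  expect_equal(f_all$icer[f_all$strategy == "C"],
               f_red$icer[f_red$strategy == "C"])
})

test_that("frontier-ICER decisions coincide with maximal net benefit", {
  set.seed(99)
  for (i in 1:200) {
    tb <- tibble::tibble(strategy = c("BHA", "SB_THA", "DM_THA"),
                         cost = runif(3, 0, 1e7), qaly = runif(3, 0, 5))
    wtp <- runif(1, 0, 2e7)
    chosen <- wtp_decision(tb, wtp)
    # independent rule: walk the frontier, take the most effective
    # strategy whose incremental ICER clears the willingness-to-pay
    fr <- cea_frontier(tb)
    fr <- fr[!fr$status %in% c("dominated", "extended-dominated"), ]
    ok <- fr$strategy[1]
    for (k in seq_len(nrow(fr))[-1]) {
      if (!is.na(fr$icer[k]) && fr$icer[k] <= wtp) ok <- fr$strategy[k]
    }
    expect_equal(chosen, ok)
  }
})

test_that("nmb ties break by cost and then by strategy order", {
  tb <- tibble::tibble(strategy = c("BHA", "SB_THA", "DM_THA"),
                       cost = c(100, 100, 200), qaly = c(1, 1, 1.0001))
  expect_equal(wtp_decision(tb, 5e6), "DM_THA")  # higher nmb wins
  tb2 <- tibble::tibble(strategy = c("DM_THA", "SB_THA"),
                        cost = c(100, 100), qaly = c(1, 1))
  expect_equal(wtp_decision(tb2, 5e6), "SB_THA")  # tie: fixed order
})
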