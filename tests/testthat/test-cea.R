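test_that("strategy comparison classifies dominance and computes INMB", {
  cmp <- compare_strategies(list(cost = 154082, qalys = 1.32),
                            list(cost = 165035, qalys = 1.30),
                            wtp = 150000)
  expect_equal(cmp$dominance, "a_dominant")
  expect_true(is.na(cmp$icer))
  expect_equal(cmp$inmb, 150000 * 0.02 + 10953, tolerance = 1e-6)
  expect_equal(cmp$preferred, "crt")

  same <- compare_strategies(list(cost = 100, qalys = 1),
                             list(cost = 100, qalys = 1), wtp = 150000)
  expect_equal(same$inmb, 0)
  expect_true(is.na(same$icer))
  expect_equal(same$dominance, "none")

  # equal QALYs: ICER undefined but INMB still meaningful
  flat <- compare_strategies(list(cost = 120, qalys = 1),
                             list(cost = 100, qalys = 1), wtp = 50000)
  expect_true(is.na(flat$icer))
  expect_equal(flat$inmb, -20)

  # a trade-off yields a plain ICER
  trade <- compare_strategies(list(cost = 110000, qalys = 1.5),
                              list(cost = 100000, qalys = 1.4), wtp = 150000)
  expect_equal(trade$dominance, "none")
  expect_equal(trade$icer, 10000 / 0.1, tolerance = 1e-9)
})

test_that("INMB is linear in WTP and changes sign at the ICER", {
  a <- list(cost = 110000, qalys = 1.5)
  b <- list(cost = 100000, qalys = 1.4)
  icer <- compare_strategies(a, b, 1)$icer
  wtps <- c(0, 50000, icer, 150000, 300000)
  inmb <- vapply(wtps, function(l) compare_strategies(a, b, l)$inmb,
                 numeric(1))
  de <- a$qalys - b$qalys
  expect_equal(diff(inmb) / diff(wtps), rep(de, 4), tolerance = 1e-9)
  expect_equal(inmb[wtps == icer], 0, tolerance = 1e-9)
  expect_lt(inmb[1], 0)
  expect_gt(inmb[5], 0)
})

test_that("dominance implies positive INMB at every positive WTP", {
  a <- list(cost = 150000, qalys = 1.35)
  b <- list(cost = 160000, qalys = 1.30)
  for (l in c(1, 10000, 150000, 1e7)) {
    cmp <- compare_strategies(a, b, l)
    expect_equal(cmp$dominance, "a_dominant")
    expect_gt(cmp$inmb, 0)
  }
})

test_that("acceptability curves count NMB wins and always sum to one", {
  pairs <- tibble::tibble(
    cost_crt = rep(100, 10), qaly_crt = c(rep(2, 6), rep(0.5, 4)),
    cost_crts = rep(100, 10), qaly_crts = rep(1, 10)
  )
  cv <- ceac(pairs, wtp_grid = c(10000, 50000))
  expect_equal(cv$ceac_crt, c(0.6, 0.6))
  expect_equal(cv$ceac_crts, c(0.4, 0.4))
  # completeness on random PSA-like draws
  set.seed(21)
  rnd <- tibble::tibble(
    cost_crt = stats::rnorm(200, 160000, 20000),
    qaly_crt = stats::rnorm(200, 1.4, 0.2),
    cost_crts = stats::rnorm(200, 170000, 20000),
    qaly_crts = stats::rnorm(200, 1.3, 0.2)
  )
  cv2 <- ceac(rnd)
  expect_true(all(cv2$ceac_crt + cv2$ceac_crts == 1))
  expect_true(all(cv2$ceac_crt >= 0 & cv2$ceac_crt <= 1))
  # as WTP grows the curve approaches the P(more QALYs) limit
  lim <- ceac(rnd, wtp_grid = 1e12)$ceac_crt
  expect_equal(lim, mean(rnd$qaly_crt > rnd$qaly_crts))
  expect_error(ceac(rnd[0, ]), ">= 1 row")
  expect_error(ceac(rnd, wtp_grid = numeric(0)), "non-empty")
})

test_that("zero-variance inputs make the CEAC a step function at the ICER", {
  # CRT+S costs 50,000 more for 0.5 more QALYs: ICER = 100,000/QALY
  # (values chosen to be exactly representable so the tie is exact)
  pairs <- tibble::tibble(cost_crt = 100000, qaly_crt = 1.0,
                          cost_crts = 150000, qaly_crts = 1.5)
  cv <- ceac(pairs, wtp_grid = c(50000, 99999, 100000, 100001, 200000))
  expect_equal(cv$ceac_crt, c(1, 1, 0.5, 0, 0)) # tie split at the ICER
  expect_equal(cv$frontier_arm, c("crt", "crt", "crt", "crts", "crts"))
})

test_that("base case run returns tidy per-arm and incremental results", {
  cea <- run_base_case(base_params)
  td <- tidy(cea)
  expect_named(td, c("arm", "cost", "qalys"))
  expect_equal(td$arm, c("crt", "crts"))
  gl <- glance(cea)
  expect_equal(gl$delta_cost, td$cost[1] - td$cost[2], tolerance = 1e-9)
  expect_equal(gl$delta_qalys, td$qalys[1] - td$qalys[2], tolerance = 1e-9)
  expect_equal(gl$inmb, 150000 * gl$delta_qalys - gl$delta_cost,
               tolerance = 1e-9)
  # strategy evaluation agrees with the underlying trace arithmetic
  tr <- run_cohort(base_params, "crt")
  expect_equal(td$cost[1], expected_discounted_cost(tr, base_params),
               tolerance = 1e-9)
  expect_equal(td$qalys[1], expected_discounted_qalys(tr, base_params),
               tolerance = 1e-9)
})
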