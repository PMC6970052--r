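test_that("DSA registry brackets every base value and respects bounds", {
  reg <- dsa_registry(base_params)
  expect_true(all(reg$low <= reg$base & reg$base <= reg$high))
  bounded <- reg$type %in% c("probability", "utility")
  expect_true(all(reg$low[bounded] >= 0 & reg$high[bounded] <= 1))
  # supplied 95% CIs override the +/- 50% default
  ci <- tibble::tibble(id = "trm_3mo.crts", low = 0.05, high = 0.15)
  reg2 <- dsa_registry(base_params, ci = ci)
  r <- reg2[reg2$id == "trm_3mo.crts", ]
  expect_equal(c(r$low, r$high), c(0.05, 0.15))
  expect_error(dsa_registry(base_params,
                            ci = tibble::tibble(id = "nope", low = 0,
                                                high = 1)),
               "Unknown parameter id")
})

test_that("tornado bars bracket the base INMB and degenerate ranges collapse", {
  reg <- dsa_registry(base_params)
  picks <- reg[reg$id %in% c("c_initial.crts", "u_distant",
                             "p_distant.crts"), ]
  torn <- one_way_dsa(base_params, registry = picks)
  base_inmb <- attr(torn, "inmb_base")
  expect_equal(nrow(torn), 3)
  expect_true(all(torn$width > 0))
  expect_true(all(pmin(torn$inmb_low, torn$inmb_high) <= base_inmb + 1e-6 &
                    base_inmb <= pmax(torn$inmb_low, torn$inmb_high) + 1e-6))
  expect_true(all(diff(torn$width) <= 0)) # sorted widest first
  # a zero-width range reproduces the base INMB at both ends
  frozen <- picks[1, ]
  frozen$low <- frozen$base
  frozen$high <- frozen$base
  torn0 <- one_way_dsa(base_params, registry = frozen)
  expect_equal(torn0$inmb_low, base_inmb, tolerance = 1e-9)
  expect_equal(torn0$inmb_high, base_inmb, tolerance = 1e-9)
  # purity: the base parameter set is untouched
  expect_equal(get_param(base_params, "c_initial.crts"), 133290)
})

test_that("raising the distant-recurrence utility erodes the INMB of CRT monotonically", {
  # below the side-effect clamp (u <= 0.35) the effect is monotone; above
  # it, distant+side-effect months regain value and CRT (with its higher
  # side-effect rate) benefits, so the range stops at the kink
  grid <- seq(0.15, 0.35, length.out = 5)
  inmb <- vapply(grid, function(u) {
    esccea:::inmb_at(set_param(base_params, "u_distant", u),
                     base_settings, 150000)
  }, numeric(1))
  expect_true(all(diff(inmb) < 0))
})

test_that("two-way DSA grids record the preferred strategy per WTP", {
  # 1x1 grid at base values reproduces the base preference
  base_cmp <- glance(run_base_case(base_params))
  g1 <- two_way_dsa(base_params, "p_distant.crt", "p_distant.crts",
                    get_param(base_params, "p_distant.crt"),
                    get_param(base_params, "p_distant.crts"))
  expect_equal(nrow(g1), 1)
  expect_equal(g1$preferred, base_cmp$preferred)
  expect_equal(g1$inmb, base_cmp$inmb, tolerance = 1e-9)
  # identical arms: preference is driven purely by the cost difference
  p_same <- identical_arm_params(except = "c_initial")
  g2 <- two_way_dsa(p_same, "p_distant.crt", "p_distant.crts",
                    c(0.01, 0.02), c(0.01, 0.02),
                    wtp_list = c(100000, 150000))
  on_diag <- g2$x == g2$y
  expect_true(all(g2$preferred[on_diag] == "crt")) # CRT is cheaper
})

test_that("threshold search agrees with a dense grid scan and reports absent crossings", {
  th <- threshold_search(base_params, "c_initial.crts", tol = 1)
  expect_true(th$found)
  expect_true(th$monotone)
  expect_lt(abs(th$inmb_at_threshold), 1)
  # dense scan oracle: the bisection answer lies within one grid step
  grid <- seq(th$lower, th$upper, length.out = 201)
  inmb <- vapply(grid, function(v) {
    esccea:::inmb_at(set_param(base_params, "c_initial.crts", v),
                     base_settings, 150000)
  }, numeric(1))
  cross <- which(inmb[-1] * inmb[-201] <= 0)[1]
  step <- diff(grid)[1]
  expect_lt(abs(th$threshold - grid[cross]), 2 * step)
  # an interval where the INMB never crosses zero
  none <- threshold_search(base_params, "c_initial.crts",
                           lower = 1.4 * 133290, upper = 1.5 * 133290)
  expect_false(none$found)
  expect_true(is.na(none$threshold))
})
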