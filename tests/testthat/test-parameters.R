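test_that("period/monthly probability conversions reproduce the published values", {
  # two-year distant recurrence -> monthly, at the printed 4 d.p.
  expect_equal(round(prob_period_to_monthly(0.391, 24), 4), 0.0205)
  expect_equal(round(prob_period_to_monthly(0.291, 24), 4), 0.0142)
  # compounding the stored monthly values recovers the two-year inputs
  p <- base_params$scalars
  pd <- p[p$parameter == "p_distant", ]
  expect_equal(prob_monthly_to_period(pd$crt, 24), 0.291, tolerance = 1e-12)
  expect_equal(prob_monthly_to_period(pd$crts, 24), 0.391, tolerance = 1e-12)
})

test_that("probability conversions handle boundaries and invert each other", {
  for (m in c(1, 3, 12, 24)) {
    expect_equal(prob_period_to_monthly(0, m), 0)
    expect_equal(prob_period_to_monthly(1, m), 1)
  }
  expect_equal(prob_monthly_to_period(0.5, 1), 0.5)
  set.seed(101)
  p <- runif(50)
  m <- sample(1:60, 50, replace = TRUE)
  expect_equal(prob_monthly_to_period(prob_period_to_monthly(p, m), m), p,
               tolerance = 1e-12)
  # strictly increasing in p, strictly decreasing in m on (0, 1)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(prob_period_to_monthly(grid, 12)) > 0))
  expect_true(all(diff(prob_period_to_monthly(0.5, c(1, 2, 6, 12, 24))) < 0))
  expect_error(prob_period_to_monthly(1.2, 12), "probability")
  expect_error(prob_period_to_monthly(0.5, 0), "positive integer")
})

test_that("surgery decrement derives the CRT+S state utilities", {
  u <- derive_arm_utilities(c(healthy = 0.770, local = 0.460,
                              distant = 0.150))
  expect_equal(unname(u), c(0.727, 0.417, 0.107))
  # clamped at zero rather than going negative
  expect_equal(unname(derive_arm_utilities(0.02, 0.05)), 0)
})

test_that("effective utilities follow the treatment / arm-specific / equalized bands", {
  p <- base_params
  expect_equal(effective_utility("healthy", "crts", 6, p), 0.727)
  expect_equal(effective_utility("healthy", "crts", 13, p), 0.770)
  expect_equal(effective_utility("healthy", "crt", 6, p), 0.770)
  # treatment phase: arm-level treatment utility regardless of state
  expect_equal(effective_utility("healthy", "crts", 2, p), 0.300)
  expect_equal(effective_utility("healthy", "crt", 2, p), 0.770)
  # side-effect decrement clamps at zero for distant recurrence
  expect_equal(effective_utility("distant_se", "crt", 20, p), 0)
  expect_equal(effective_utility("distant_se", "crts", 20, p), 0)
  # death is worth nothing, any cycle
  expect_equal(effective_utility("dead", "crt", c(1, 50, 300), p),
               c(0, 0, 0))
  expect_error(effective_utility("cured", "crt", 5, p), "Unknown state")
})

test_that("arm utilities are ordered before equalization and identical after", {
  p <- base_params
  states <- setdiff(esc_states(), "dead")
  for (cy in 4:12) {
    u_crt <- effective_utility(states, "crt", cy, p)
    u_crts <- effective_utility(states, "crts", cy, p)
    expect_true(all(u_crts <= u_crt))
  }
  for (cy in c(13, 60, 300)) {
    expect_equal(effective_utility(states, "crt", cy, p),
                 effective_utility(states, "crts", cy, p))
  }
})

test_that("monthly discounting compounds the annual rate", {
  expect_equal(discount_factor(1, 0.03), 1)
  expect_equal(discount_factor(13, 0.03), 1 / 1.03)
  expect_equal(discount_factor(1:300, 0), rep(1, 300))
  d <- discount_factor(1:300, 0.03)
  expect_true(all(diff(d) < 0))
  expect_error(discount_factor(5, -0.01), "non-negative")
})

test_that("transition schedule applies year bands, trial death rates and the life table", {
  s <- base_settings
  sched_crt <- build_transition_schedule(base_params, "crt", s)
  sched_crts <- build_transition_schedule(base_params, "crts", s)
  yr3 <- sched_crt$year == 3
  expect_true(all(sched_crt$p_local[yr3] == 0.0237))
  expect_true(all(sched_crts$p_local[sched_crts$year == 3] == 0))
  expect_true(all(sched_crts$p_local[sched_crts$cycle %in% 4:24] == 0.0208))
  expect_true(all(sched_crt$p_local[sched_crt$year >= 5] == 0))
  # treatment cycles: monthly TRM only
  expect_equal(sched_crts$p_death[1:3],
               rep(prob_period_to_monthly(0.0926, 3), 3))
  expect_true(all(sched_crts$p_local[1:3] == 0))
  # life-table years: monthly conversion of annual q at the attained age
  lt <- tibble::tibble(age = 57:85, annual_q = 0.0117)
  p_flat <- esc_params(base_params$scalars, base_params$death_monthly, lt)
  sched <- build_transition_schedule(p_flat, "crt", s)
  yr6 <- sched$year == 6
  expect_equal(unique(sched$p_death[yr6]),
               1 - (1 - 0.0117)^(1 / 12), tolerance = 1e-12)
  expect_equal(round(unique(sched$p_death[yr6]), 6), 0.000980)
  # all schedule entries are probabilities
  for (cc in c("p_death", "p_local", "p_distant", "p_se")) {
    expect_true(all(sched_crt[[cc]] >= 0 & sched_crt[[cc]] <= 1))
  }
})

test_that("incomplete or invalid parameter sets fail loudly", {
  p <- base_params
  short <- p
  short$death_monthly <- short$death_monthly[1:40, ]
  expect_error(validate_params(short), "cycles 1-48")
  expect_error(set_param(p, "p_distant.crt", 1.2), "\\[0, 1\\]")
  expect_error(set_param(p, "death_scale.crt", 40), "leave \\[0, 1\\]")
  expect_error(set_param(p, "no_such_param", 1), "Unknown parameter")
  missing_row <- p
  missing_row$scalars <- missing_row$scalars[-1, ]
  expect_error(validate_params(missing_row), "missing: trm_3mo")
})

test_that("set_param is pure and keeps derived utilities in sync", {
  p <- base_params
  p2 <- set_param(p, "surgery_decrement", 0.1)
  expect_equal(get_param(p, "surgery_decrement"), 0.043) # original untouched
  sc2 <- p2$scalars
  expect_equal(sc2$crts[sc2$parameter == "u_healthy"], 0.670)
  expect_equal(sc2$crts[sc2$parameter == "u_distant"], 0.050)
  p3 <- set_param(p, "u_distant", 0.286)
  expect_equal(get_param(p3, "u_distant"), 0.286)
  expect_equal(p3$scalars$crts[p3$scalars$parameter == "u_distant"],
               0.286 - 0.043)
  # shared parameters update both arms at once
  p4 <- set_param(p, "c_continuing", 9000)
  expect_equal(p4$scalars$crts[p4$scalars$parameter == "c_continuing"], 9000)
})
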