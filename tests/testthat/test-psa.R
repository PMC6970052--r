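test_that("method-of-moments distributions reproduce their means", {
  dists <- build_distributions(base_params)
  expect_true(all(dists$family %in% c("beta", "gamma", "point")))
  # gamma cost: mean 7,893 with the +/- 50% sd rule
  g <- dists[dists$id == "c_continuing", ]
  expect_equal(g$family, "gamma")
  expect_equal(g$mean, 7893)
  expect_equal(g$sd, 7893 / 3.92, tolerance = 1e-12)
  expect_equal(g$par1 / g$par2, 7893, tolerance = 1e-9) # shape/rate = mean
  set.seed(31)
  draws <- stats::rgamma(10000, shape = g$par1, rate = g$par2)
  expect_lt(abs(mean(draws) - 7893), 3 * stats::sd(draws) / sqrt(10000))
  # beta probability: mean equals the base value
  b <- dists[dists$id == "p_side_effects.crt", ]
  expect_equal(b$family, "beta")
  expect_equal(b$par1 / (b$par1 + b$par2), 0.0081, tolerance = 1e-12)
  set.seed(32)
  bd <- stats::rbeta(10000, b$par1, b$par2)
  expect_lt(abs(mean(bd) - 0.0081), 3 * stats::sd(bd) / sqrt(10000))
  expect_true(all(bd >= 0 & bd <= 1))
})

test_that("degenerate bases become point masses", {
  p0 <- set_param(base_params, "p_side_effects.crts", 0)
  reg <- dsa_registry(p0)
  dists <- build_distributions(p0, reg)
  z <- dists[dists$id == "p_side_effects.crts", ]
  expect_equal(z$family, "point")
  expect_equal(z$mean, 0)
  # zero-width range -> point mass even for a positive base
  reg$low[reg$id == "u_distant"] <- reg$base[reg$id == "u_distant"]
  reg$high[reg$id == "u_distant"] <- reg$base[reg$id == "u_distant"]
  d2 <- build_distributions(p0, reg)
  expect_equal(d2$family[d2$id == "u_distant"], "point")
})

test_that("point-mass PSA reproduces the deterministic base case exactly", {
  reg <- dsa_registry(base_params)
  reg$low <- reg$base
  reg$high <- reg$base
  dists <- build_distributions(base_params, reg)
  expect_true(all(dists$family == "point"))
  psa <- run_psa(base_params, n_iterations = 5, seed = 3,
                 distributions = dists)
  cea <- tidy(run_base_case(base_params))
  expect_equal(psa$samples$cost_crt, rep(cea$cost[1], 5))
  expect_equal(psa$samples$qaly_crt, rep(cea$qalys[1], 5))
  expect_equal(psa$samples$cost_crts, rep(cea$cost[2], 5))
  expect_equal(psa$samples$qaly_crts, rep(cea$qalys[2], 5))
  d <- psa$dominance
  expect_true(d$crt_dominant %in% c(0, 1) && d$crts_dominant %in% c(0, 1))
})

test_that("PSA is deterministic given the master seed", {
  a <- run_psa(base_params, n_iterations = 12, seed = 77)
  b <- run_psa(base_params, n_iterations = 12, seed = 77)
  expect_identical(a$samples, b$samples)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  c_ <- run_psa(base_params, n_iterations = 12, seed = 78)
  expect_false(identical(a$samples, c_$samples))
})

test_that("dominance fractions partition the iterations", {
  psa <- run_psa(base_params, n_iterations = 60, seed = 5)
  d <- psa$dominance
  expect_equal(d$crt_dominant + d$crts_dominant + d$neither, 1)
  expect_true(all(unlist(d[, 1:5]) >= 0 & unlist(d[, 1:5]) <= 1))
  expect_equal(d$crt_cost_effective + d$crts_cost_effective, 1)
  # the CEAC at the analysis WTP agrees with the cost-effective fraction
  at_wtp <- psa$ceac[psa$ceac$wtp == 150000, ]
  expect_equal(at_wtp$ceac_crt, d$crt_cost_effective)
  # glance exposes the same numbers
  gl <- glance(psa)
  expect_equal(gl$crt_dominant, d$crt_dominant)
  expect_equal(gl$n_iterations, 60L)
})

test_that("invalid draws are rejected and redrawn deterministically", {
  # an absurd death-scale range forces some draws to breach probability 1
  reg <- dsa_registry(base_params)
  reg$high[reg$id == "death_scale.crt"] <- 80
  dists <- build_distributions(base_params, reg)
  a <- run_psa(base_params, n_iterations = 15, seed = 11,
               distributions = dists)
  b <- run_psa(base_params, n_iterations = 15, seed = 11,
               distributions = dists)
  expect_identical(a$samples, b$samples)
  expect_gte(a$n_rejected, 0)
  # every retained draw is a valid probability configuration
  expect_true(all(a$draws[, "death_scale.crt"] *
                    max(base_params$death_monthly$crt) <= 1))
})
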