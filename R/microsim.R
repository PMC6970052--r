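#' Individual-level microsimulation oracle
#'
#' Simulates `n` independent patient trajectories with the same per-cycle
#' event logic as the cohort model (death, then recurrence with distant
#' precedence, then permanent side-effect onset) and returns estimated
#' state occupancy with binomial standard errors, plus per-patient
#' discounted cost and QALY summaries. Because each simulated patient has
#' an exact death time, phase-of-care costs are accumulated patient by
#' patient, month by month — an independent route to the same expectations
#' the cohort algebra computes, used as a brute-force test oracle.
#'
#' Deterministic given `seed`.
#'
#' @inheritParams build_transition_schedule
#' @param n Number of simulated patients.
#' @param seed Integer RNG seed.
#' @return A list with:
#'   * `trace`: tibble `cycle`, state-fraction estimates and `se_<state>`
#'     columns;
#'   * `cost`, `qalys`: mean discounted totals with `cost_se`, `qalys_se`;
#'   * `death_cycle`: integer vector (NA for horizon survivors);
#'   * `n`, `seed`, `arm`.
#' @examples
#' ms <- microsim_cohort(base_case_params(), "crt", n = 500, seed = 1)
#' ms$cost
#' @export
microsim_cohort <- function(params, arm, settings = esc_settings(),
                            n = 10000L, seed = 1L) {
  arm <- match.arg(arm, arm_cols)
  if (n < 1) abort("`n` must be >= 1.")
  sched <- build_transition_schedule(params, arm, settings)
  U <- utility_matrix(params, arm, settings)
  H <- settings$horizon_months
  disc <- discount_factor(seq_len(H), settings$annual_discount_rate)

  pd <- sched$p_death; pl <- sched$p_local
  pr <- sched$p_distant; ps <- sched$p_se

  # state codes follow esc_states(): 1 healthy .. 6 distant_se, 7 dead
  set.seed(seed)
  state <- rep.int(1L, n)
  death_cycle <- rep.int(NA_integer_, n)
  qalys <- numeric(n)
  counts <- matrix(0L, nrow = H, ncol = 7L,
                   dimnames = list(NULL, esc_states()))

  for (t in seq_len(H)) {
    alive <- state != 7L
    if (any(alive)) {
      dies <- alive & (stats::runif(n) < pd[t])
      if (any(dies)) {
        state[dies] <- 7L
        death_cycle[dies] <- t
      }
      surv <- alive & !dies
      if (t > settings$treatment_phase_months && any(surv)) {
        u_rec <- stats::runif(n)
        u_loc <- stats::runif(n)
        u_se <- stats::runif(n)
        has_se <- state %in% c(2L, 4L, 6L)
        from_healthy <- surv & state %in% c(1L, 2L)
        from_local <- surv & state %in% c(3L, 4L)
        go_distant <- (from_healthy | from_local) & u_rec < pr[t]
        go_local <- from_healthy & !go_distant & u_loc < pl[t]
        state[go_distant] <- ifelse(has_se[go_distant], 6L, 5L)
        state[go_local] <- ifelse(has_se[go_local], 4L, 3L)
        onset <- surv & state %in% c(1L, 3L, 5L) & u_se < ps[t]
        state[onset] <- state[onset] + 1L
      }
    }
    counts[t, ] <- tabulate(state, nbins = 7L)
    qalys <- qalys + U[t, state] * (disc[t] / 12)
  }

  phat <- counts / n
  se <- sqrt(phat * (1 - phat) / n)
  colnames(se) <- paste0("se_", esc_states())
  trace <- as_tibble(cbind(cycle = seq_len(H), phat, se))

  cost_i <- microsim_costs(death_cycle, params, arm, settings, disc)

  list(
    trace = trace,
    cost = mean(cost_i), cost_se = sd(cost_i) / sqrt(n),
    qalys = mean(qalys), qalys_se = sd(qalys) / sqrt(n),
    death_cycle = death_cycle,
    n = n, seed = seed, arm = arm
  )
}

# Discounted lifetime cost for each simulated patient. A patient dying in
# cycle tau accrues monthly costs for months 1..tau; the last 12 months of
# life are end-of-life, months <= 12 that are not end-of-life are initial
# (arm-specific), the rest continuing. Horizon survivors get no end-of-life
# months. Computed once per distinct death time by an explicit month loop.
microsim_costs <- function(death_cycle, params, arm, settings, disc) {
  c_init <- get_param(params, paste0("c_initial.", arm))
  c_cont <- get_param(params, "c_continuing")
  c_eol <- get_param(params, "c_eol")
  H <- settings$horizon_months
  monthly <- c(INITIAL = c_init, CONTINUING = c_cont, END_OF_LIFE = c_eol) / 12

  cost_of_tau <- function(tau) {
    months <- seq_len(if (is.na(tau)) H else tau)
    labels <- vapply(months, phase_of_month, character(1), tau = tau,
                     horizon = H)
    sum(monthly[labels] * disc[months])
  }
  taus <- unique(death_cycle)
  lut <- vapply(taus, cost_of_tau, numeric(1))
  lut[match(death_cycle, taus)]
}
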