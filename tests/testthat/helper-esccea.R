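# Shared fixtures, built in code at test time.

base_params <- base_case_params()
base_settings <- esc_settings()

# A parameter set with no mortality, no recurrence and no side effects:
# the whole cohort stays healthy for the full horizon.
zero_risk_params <- function(u_healthy = 0.770, u_treatment = u_healthy) {
  p <- base_case_params(lifetable = make_lifetable(level = 0))
  p$death_monthly$crt <- 0
  p$death_monthly$crts <- 0
  for (id in c("trm_3mo.crt", "trm_3mo.crts", "p_local.crt", "p_local.crts",
               "p_distant.crt", "p_distant.crts",
               "p_side_effects.crt", "p_side_effects.crts",
               "surgery_decrement")) {
    p <- set_param(p, id, 0)
  }
  p <- set_param(p, "u_healthy", u_healthy)
  p <- set_param(p, "u_treatment.crt", u_treatment)
  set_param(p, "u_treatment.crts", u_treatment)
}

# Minimal hand-built trace: everyone dies at cycle `death_cycle`
# (NA = everyone survives the horizon), optionally undiscounted.
degenerate_trace <- function(death_cycle = NA, arm = "crt", horizon = 300L,
                             rate = 0) {
  occ <- matrix(0, nrow = horizon, ncol = 7L,
                dimnames = list(NULL, esc_states()))
  if (is.na(death_cycle)) {
    occ[, "healthy"] <- 1
  } else {
    if (death_cycle > 1) occ[seq_len(death_cycle - 1), "healthy"] <- 1
    occ[death_cycle:horizon, "dead"] <- 1
  }
  dead <- occ[, "dead"]
  out <- tibble::as_tibble(cbind(cycle = seq_len(horizon), occ))
  out$death_incidence <- dead - c(0, dead[-horizon])
  out$discount <- discount_factor(seq_len(horizon), rate)
  structure(out, class = c("esc_trace", class(out)), arm = arm,
            settings = esc_settings(annual_discount_rate = rate))
}

# A parameter set whose two arms are numerically identical except where
# stated; used to isolate single drivers of preference.
identical_arm_params <- function(except = character()) {
  p <- base_case_params(
    mortality = fixture_mortality_spec(0.40, 0.27, 0.40, 0.27)
  )
  per_arm <- c("trm_3mo", "p_local", "p_distant", "p_side_effects",
               "u_treatment", "death_scale")
  for (nm in setdiff(per_arm, except)) {
    p <- set_param(p, paste0(nm, ".crts"), get_param(p, paste0(nm, ".crt")))
  }
  if (!"surgery_decrement" %in% except) {
    p <- set_param(p, "surgery_decrement", 0)
  }
  if (!"c_initial" %in% except) {
    p <- set_param(p, "c_initial.crts", get_param(p, "c_initial.crt"))
  }
  p$local_band_end_year <- c(crt = 4L, crts = 4L)
  p$death_monthly$crts <- p$death_monthly$crt
  validate_params(p)
}
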