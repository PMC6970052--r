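#' Health states of the Markov model
#'
#' Seven states: healthy, local recurrence and distant recurrence — each
#' with and without chronic side effects — plus absorbing death.
#'
#' @return Character vector of the seven state labels, in canonical order.
#' @export
esc_states <- function() {
  c("healthy", "healthy_se", "local", "local_se",
    "distant", "distant_se", "dead")
}

#' Convert a period probability to a per-cycle (monthly) probability
#'
#' Inverts compounding over `m` cycles under a constant hazard:
#' `1 - (1 - p)^(1/m)`. Used to turn the trial-reported period
#' probabilities (e.g. two-year distant recurrence) into the monthly
#' probabilities the cycle engine consumes.
#'
#' @param p Probability over the whole period, in \[0, 1\]; vectorized.
#' @param m Period length in cycles (positive integer).
#' @return Monthly probability such that compounding over `m` cycles
#'   recovers `p`.
#' @examples
#' prob_period_to_monthly(0.391, 24) # ~0.0205
#' prob_period_to_monthly(0.291, 24) # ~0.0142
#' @seealso [prob_monthly_to_period()]
#' @export
prob_period_to_monthly <- function(p, m) {
  check_prob(p, "p")
  check_period(m)
  1 - (1 - p)^(1 / m)
}

#' Compound a per-cycle probability over a period
#'
#' `1 - (1 - p_monthly)^m`; the inverse of [prob_period_to_monthly()].
#'
#' @param p_monthly Per-cycle probability in \[0, 1\]; vectorized.
#' @param m Number of cycles (positive integer).
#' @return Probability of at least one event over `m` cycles.
#' @export
prob_monthly_to_period <- function(p_monthly, m) {
  check_prob(p_monthly, "p_monthly")
  check_period(m)
  1 - (1 - p_monthly)^m
}

check_prob <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(p)
}

check_period <- function(m) {
  if (any(!is.finite(m)) || any(m < 1) || any(m != as.integer(m))) {
    abort("`m` must be a positive integer number of cycles.")
  }
  invisible(m)
}

#' Derive surgery-arm state utilities from the chemoradiation-arm values
#'
#' The CRT+S arm carries a long-term utility decrement for having undergone
#' esophagectomy: each non-death state utility is the CRT value minus the
#' decrement, clamped to \[0, 1\].
#'
#' @param u_crt Named or unnamed vector of CRT state utilities in \[0, 1\].
#' @param surgery_decrement Long-term esophagectomy decrement (default
#'   0.043).
#' @return Vector of CRT+S utilities, same names as `u_crt`.
#' @examples
#' derive_arm_utilities(c(healthy = 0.770, local = 0.460, distant = 0.150))
#' @export
derive_arm_utilities <- function(u_crt, surgery_decrement = 0.043) {
  check_prob(u_crt, "u_crt")
  if (surgery_decrement < 0) abort("`surgery_decrement` must be >= 0.")
  pmin(pmax(u_crt - surgery_decrement, 0), 1)
}

# ---------------------------------------------------------------------------
# Parameter container

arm_cols <- c("crt", "crts")

#' Assemble a strategy parameter set
#'
#' Low-level constructor used by [base_case_params()]. Most users should start
#' from [base_case_params()] and modify values with [set_param()].
#'
#' @param scalars Tibble with columns `parameter`, `crt`, `crts`, `type`
#'   (`"probability"`, `"utility"`, `"cost"`, `"scale"`), `shared` (logical:
#'   one value applied to both arms) and `fixture` (logical: value is a
#'   synthetic stand-in rather than a published input).
#' @param death_monthly Tibble with columns `cycle` (1..48), `crt`, `crts`:
#'   arm-specific monthly death probabilities for post-diagnosis years 1-4.
#' @param lifetable Tibble with columns `age`, `annual_q`: background annual
#'   mortality applied from year 5 onward at the attained age.
#' @param local_band_end_year Named integer vector (`crt`, `crts`): last
#'   post-diagnosis year with non-zero monthly local-recurrence probability.
#' @param fixture_info Optional list recording how fixture inputs were
#'   generated (serialized into output metadata).
#' @return An object of class `"esc_params"`.
#' @export
esc_params <- function(scalars, death_monthly, lifetable,
                       local_band_end_year = c(crt = 4L, crts = 2L),
                       fixture_info = list()) {
  stopifnot(is.data.frame(scalars), is.data.frame(death_monthly),
            is.data.frame(lifetable))
  x <- structure(
    list(
      scalars = as_tibble(scalars),
      death_monthly = as_tibble(death_monthly),
      lifetable = as_tibble(lifetable),
      local_band_end_year = local_band_end_year,
      fixture_info = fixture_info
    ),
    class = "esc_params"
  )
  validate_params(x)
}

#' @export
print.esc_params <- function(x, ...) {
  cat("<esc_params> strategy parameters, arms CRT / CRT+S\n")
  print(x$scalars, n = Inf)
  cat(sprintf("death_monthly: %d cycles (years 1-4)%s\n",
              nrow(x$death_monthly),
              if (isTRUE(x$fixture_info$fixture)) " [FIXTURE]" else ""))
  cat(sprintf("lifetable: ages %d-%d (years 5+)\n",
              min(x$lifetable$age), max(x$lifetable$age)))
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks completeness and ranges: probabilities and utilities in \[0, 1\],
#' non-negative costs, a 48-cycle death vector per arm, and a life table
#' covering the ages reached over the horizon. Called by every model entry
#' point; errors are configuration errors, not silent fixes.
#'
#' @param params An [esc_params] object.
#' @param settings An [esc_settings] object (for horizon/age coverage).
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params, settings = esc_settings()) {
  sc <- params$scalars
  need <- c("trm_3mo", "p_local", "p_distant", "p_side_effects",
            "u_treatment", "u_healthy", "u_local", "u_distant",
            "se_decrement", "surgery_decrement",
            "c_initial", "c_continuing", "c_eol", "death_scale")
  missing <- setdiff(need, sc$parameter)
  if (length(missing) > 0) {
    abort(paste0("Incomplete parameter set; missing: ",
                 paste(missing, collapse = ", ")))
  }
  vals <- c(sc$crt, sc$crts)
  if (any(!is.finite(vals))) abort("Non-finite parameter value.")
  bounded <- sc$type %in% c("probability", "utility")
  if (any(sc$crt[bounded] < 0 | sc$crt[bounded] > 1 |
          sc$crts[bounded] < 0 | sc$crts[bounded] > 1)) {
    abort("Probabilities and utilities must lie in [0, 1].")
  }
  if (any(sc$crt[sc$type == "cost"] < 0 | sc$crts[sc$type == "cost"] < 0)) {
    abort("Costs must be non-negative.")
  }
  dm <- params$death_monthly
  if (nrow(dm) < 48 || !all(c("cycle", "crt", "crts") %in% names(dm))) {
    abort("`death_monthly` must supply cycles 1-48 for both arms.")
  }
  scale <- get_param_row(params, "death_scale")
  for (a in arm_cols) {
    q <- dm[[a]] * scale[[a]]
    if (any(q < 0 | q > 1)) {
      abort(sprintf(
        "Scaled monthly death probabilities for arm %s leave [0, 1].", a))
    }
  }
  lt <- params$lifetable
  if (!all(c("age", "annual_q") %in% names(lt))) {
    abort("`lifetable` needs columns age, annual_q.")
  }
  if (any(lt$annual_q < 0 | lt$annual_q >= 1)) {
    abort("Life-table annual probabilities must lie in [0, 1).")
  }
  ages_needed <- settings$start_age_years +
    seq(4L, (settings$horizon_months - 1L) %/% 12L)
  if (!all(ages_needed %in% lt$age)) {
    abort("Life table does not cover all attained ages over the horizon.")
  }
  invisible(params)
}

get_param_row <- function(params, parameter) {
  i <- match(parameter, params$scalars$parameter)
  if (is.na(i)) abort(sprintf("Unknown parameter `%s`.", parameter))
  params$scalars[i, ]
}

#' Read a scalar parameter by id
#'
#' Ids are `"<parameter>"` for shared parameters or
#' `"<parameter>.crt"` / `"<parameter>.crts"` for arm-specific ones, e.g.
#' `"c_initial.crts"` or `"u_distant"`.
#'
#' @param params An [esc_params] object.
#' @param id Parameter id string.
#' @return The scalar value.
#' @export
get_param <- function(params, id) {
  parsed <- parse_param_id(params, id)
  params$scalars[[parsed$arm]][parsed$row]
}

#' Return a copy of a parameter set with one scalar changed
#'
#' Pure update: the input is never modified. Updating a shared parameter
#' writes both arm columns; updating `surgery_decrement` or a base state
#' utility re-derives the CRT+S utilities (CRT value minus decrement,
#' clamped to \[0, 1\]). The result is validated, so out-of-range values
#' fail loudly rather than being renormalized.
#'
#' @inheritParams get_param
#' @param value New value.
#' @return A new [esc_params] object.
#' @export
set_param <- function(params, id, value) {
  parsed <- parse_param_id(params, id)
  sc <- params$scalars
  if (isTRUE(sc$shared[parsed$row]) || parsed$parameter == "surgery_decrement") {
    sc$crt[parsed$row] <- value
    sc$crts[parsed$row] <- value
  } else {
    sc[[parsed$arm]][parsed$row] <- value
  }
  params$scalars <- refresh_derived_utilities(sc)
  validate_params(params)
}

parse_param_id <- function(params, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  parameter <- parts[1]
  row <- match(parameter, params$scalars$parameter)
  if (is.na(row)) abort(sprintf("Unknown parameter id `%s`.", id))
  arm <- if (length(parts) >= 2) parts[2] else "crt"
  if (!arm %in% arm_cols) abort(sprintf("Unknown arm in id `%s`.", id))
  if (length(parts) == 1 && !isTRUE(params$scalars$shared[row]) &&
      !parameter %in% c("u_healthy", "u_local", "u_distant",
                        "surgery_decrement")) {
    abort(sprintf("Parameter `%s` is arm-specific; use `%s.crt` or `%s.crts`.",
                  parameter, parameter, parameter))
  }
  list(parameter = parameter, row = row, arm = arm)
}

# CRT+S state utilities are derived: CRT value minus the esophagectomy
# decrement, clamped. Kept in sync whenever a scalar changes.
refresh_derived_utilities <- function(scalars) {
  dec <- scalars$crt[match("surgery_decrement", scalars$parameter)]
  derived <- c("u_healthy", "u_local", "u_distant")
  i <- match(derived, scalars$parameter)
  scalars$crts[i] <- derive_arm_utilities(scalars$crt[i], dec)
  scalars
}

# ---------------------------------------------------------------------------
# Effective utilities

#' Effective utility of a state at a given cycle
#'
#' Implements the time structure of the QALY weights: during the treatment
#' phase (cycles 1-3) every alive state carries the arm's treatment-phase
#' utility; from cycle 4 to the equalization month the arm-specific state
#' utility applies; strictly after the equalization month the two arms share
#' `max(u_CRT, u_CRT+S)` per state. Side-effect states subtract the
#' side-effect decrement and are clamped at zero; death is 0.
#'
#' @param state Character vector of state labels (see [esc_states()]).
#' @param arm `"crt"` or `"crts"`.
#' @param cycle Integer cycle index (1-based); vectorized with `state`.
#' @param params An [esc_params] object.
#' @param settings An [esc_settings] object.
#' @return Numeric utility weights in \[0, 1\].
#' @examples
#' p <- base_case_params()
#' effective_utility("healthy", "crts", 6, p)   # 0.727
#' effective_utility("healthy", "crts", 13, p)  # 0.770 (equalized)
#' @export
effective_utility <- function(state, arm, cycle, params,
                              settings = esc_settings()) {
  arm <- match.arg(arm, arm_cols)
  if (any(cycle < 1)) abort("`cycle` must be >= 1.")
  if (!all(state %in% esc_states())) {
    abort(sprintf("Unknown state(s): %s",
                  paste(setdiff(state, esc_states()), collapse = ", ")))
  }
  n <- max(length(state), length(cycle))
  state <- rep_len(state, n)
  cycle <- rep_len(cycle, n)
  U <- utility_matrix(params, arm, settings)
  U[cbind(pmin(cycle, settings$horizon_months),
          match(state, esc_states()))]
}

# horizon x 7 matrix of effective utilities for one arm
utility_matrix <- function(params, arm, settings = esc_settings()) {
  sc <- params$scalars
  val <- function(p, a) sc[[a]][match(p, sc$parameter)]
  se_dec <- val("se_decrement", "crt")
  base <- function(a) c(val("u_healthy", a), val("u_local", a),
                        val("u_distant", a))
  u_arm <- base(arm)
  u_max <- pmax(base("crt"), base("crts"))

  H <- settings$horizon_months
  tp <- settings$treatment_phase_months
  eq <- settings$equalization_month
  U <- matrix(0, nrow = H, ncol = 7L,
              dimnames = list(NULL, esc_states()))
  state_u <- matrix(rep(u_arm, each = H), nrow = H)
  eq_rows <- seq_len(H) > eq
  state_u[eq_rows, ] <- matrix(rep(u_max, each = sum(eq_rows)),
                               nrow = sum(eq_rows))
  U[, c("healthy", "local", "distant")] <- state_u
  U[, c("healthy_se", "local_se", "distant_se")] <- pmax(state_u - se_dec, 0)
  # treatment phase: a single treatment utility for any alive state
  U[seq_len(tp), seq_len(6L)] <- val("u_treatment", arm)
  U[, "dead"] <- 0
  U
}

# ---------------------------------------------------------------------------
# Transition schedule

#' Cycle-indexed transition probabilities for one arm
#'
#' Expands a parameter set into per-cycle monthly probabilities of death,
#' local recurrence, distant recurrence and side-effect onset:
#' * cycles 1-3 (treatment phase): death is the monthly conversion of the
#'   3-month treatment-related mortality; no other transitions;
#' * years 1-4 post-diagnosis: death from the arm-specific trial-calibrated
#'   vector (times `death_scale`); local recurrence follows the year bands
#'   (CRT through year 4, CRT+S through year 2, then zero);
#' * year 5 onward: death is the monthly conversion of the life-table annual
#'   probability at the attained age; local recurrence zero.
#' Distant-recurrence and side-effect probabilities are constant over the
#' post-treatment horizon.
#'
#' @inheritParams effective_utility
#' @return A tibble with columns `cycle`, `year`, `phase`
#'   (`"treatment"`/`"markov"`), `p_death`, `p_local`, `p_distant`, `p_se`.
#' @export
build_transition_schedule <- function(params, arm,
                                      settings = esc_settings()) {
  arm <- match.arg(arm, arm_cols)
  sv <- schedule_vectors(params, arm, settings, validate = TRUE)
  cycle <- seq_len(settings$horizon_months)
  year <- (cycle - 1L) %/% 12L + 1L
  tibble(
    cycle = cycle, year = year,
    phase = ifelse(cycle <= settings$treatment_phase_months,
                   "treatment", "markov"),
    p_death = sv$p_death, p_local = sv$p_local,
    p_distant = sv$p_distant, p_se = sv$p_se
  )
}

# plain-vector schedule; hot path for run_cohort and the PSA
schedule_vectors <- function(params, arm, settings, validate = TRUE) {
  if (validate) validate_params(params, settings)
  sc <- params$scalars
  idx <- match(c("trm_3mo", "death_scale", "p_local", "p_distant",
                 "p_side_effects"), sc$parameter)
  v <- sc[[arm]][idx]

  H <- settings$horizon_months
  tp <- settings$treatment_phase_months
  cycle <- seq_len(H)
  year <- (cycle - 1L) %/% 12L + 1L

  p_death <- numeric(H)
  p_death[cycle <= tp] <- prob_period_to_monthly(v[1], tp)
  trial <- cycle > tp & year <= 4L
  p_death[trial] <- params$death_monthly[[arm]][cycle[trial]] * v[2]
  lt <- cycle > tp & year > 4L
  age <- settings$start_age_years + (year - 1L)
  q_annual <- params$lifetable$annual_q[match(age[lt], params$lifetable$age)]
  p_death[lt] <- prob_period_to_monthly(q_annual, 12L)

  list(
    p_death = p_death,
    p_local = ifelse(cycle > tp & year <= params$local_band_end_year[[arm]],
                     v[3], 0),
    p_distant = ifelse(cycle > tp, v[4], 0),
    p_se = ifelse(cycle > tp, v[5], 0)
  )
}
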