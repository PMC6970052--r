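#' Phase-of-care label of a person-month
#'
#' Assigns each alive month to exactly one costing phase given the death
#' cycle `tau`: the last twelve months of life are `END_OF_LIFE`; months
#' within the first twelve that are not end-of-life are `INITIAL`;
#' everything else is `CONTINUING`. When death occurs within the first
#' year, months count as end-of-life rather than initial. Horizon
#' survivors (`tau = NA` or `Inf`) receive no end-of-life months.
#'
#' @param t Month (cycle) index, 1-based.
#' @param tau Death cycle, or `NA`/`Inf` for a patient alive at the
#'   horizon.
#' @param horizon Model horizon in months (bound for survivors).
#' @return One of `"INITIAL"`, `"CONTINUING"`, `"END_OF_LIFE"`.
#' @examples
#' phase_of_month(5, 8)    # END_OF_LIFE: death in the first year
#' phase_of_month(5, 60)   # INITIAL
#' phase_of_month(30, 60)  # CONTINUING
#' @export
phase_of_month <- function(t, tau, horizon = 300L) {
  finite_tau <- !is.na(tau) && is.finite(tau)
  bound <- if (finite_tau) tau else horizon
  if (t < 1 || t > bound) {
    abort("`t` must lie in 1..tau (or 1..horizon for survivors).")
  }
  if (finite_tau && t > tau - 12) return("END_OF_LIFE")
  if (t <= 12) return("INITIAL")
  "CONTINUING"
}

#' Expected discounted lifetime cost of a cohort trace
#'
#' Phase-of-care accounting: the cohort is decomposed by death cycle using
#' the per-cycle death incidence (plus the mass surviving to the horizon);
#' for each death time, monthly costs (annual phase cost / 12, with the
#' initial phase arm-specific) are summed over months 1..tau labelled by
#' [phase_of_month()] and discounted; the death-time-weighted expectation
#' is returned. Computed in closed form from cumulative discount sums.
#'
#' @param trace An `esc_trace` from [run_cohort()].
#' @param params An [esc_params] object.
#' @param settings An [esc_settings] object; defaults to the settings the
#'   trace was produced under.
#' @return Expected discounted cost (scalar, dollars).
#' @export
expected_discounted_cost <- function(trace, params,
                                     settings = trace_settings(trace)) {
  arm <- attr(trace, "arm")
  c_init <- get_param(params, paste0("c_initial.", arm))
  c_cont <- get_param(params, "c_continuing")
  c_eol <- get_param(params, "c_eol")
  if (any(c(c_init, c_cont, c_eol) < 0)) abort("Costs must be non-negative.")
  cost_kernel(trace$death_incidence, trace$discount,
              c_init, c_cont, c_eol)
}

# death-time decomposition in closed form from cumulative discount sums
cost_kernel <- function(death_incidence, disc, c_init, c_cont, c_eol) {
  H <- length(disc)
  cumd <- c(0, cumsum(disc)) # cumd[k + 1] = sum of disc over months 1..k
  pv_at <- function(k) cumd[pmax(k, 0) + 1]

  tau <- seq_len(H)
  init_end <- pmin(12, pmax(0, tau - 12))
  pv_death <- c_init / 12 * pv_at(init_end) +
    c_cont / 12 * (pv_at(pmax(tau - 12, init_end)) - pv_at(init_end)) +
    c_eol / 12 * (pv_at(tau) - pv_at(pmax(tau - 12, 0)))
  pv_survive <- c_init / 12 * pv_at(12) +
    c_cont / 12 * (pv_at(H) - pv_at(12))

  w <- death_incidence
  sum(w * pv_death) + (1 - sum(w)) * pv_survive
}

#' Expected discounted QALYs of a cohort trace
#'
#' Sum over cycles and states of occupancy times the effective utility
#' (treatment-phase weights in cycles 1-3, arm-specific state utilities
#' until the equalization month, the across-arm maximum after it, with the
#' side-effect decrement applied and clamped at zero) times the discount
#' factor, at 1/12 year per cycle.
#'
#' @inheritParams expected_discounted_cost
#' @return Expected discounted QALYs (scalar).
#' @export
expected_discounted_qalys <- function(trace, params,
                                      settings = trace_settings(trace)) {
  arm <- attr(trace, "arm")
  U <- utility_matrix(params, arm, settings)
  occ <- as.matrix(trace[, esc_states()])
  sum(rowSums(occ * U) * trace$discount) / 12
}

trace_settings <- function(trace) {
  attr(trace, "settings") %||% esc_settings()
}

`%||%` <- function(x, y) if (is.null(x)) y else x
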