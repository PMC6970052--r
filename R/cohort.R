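#' One Markov step of the post-treatment model
#'
#' Advances a 7-state occupancy row by one monthly cycle. Events are
#' applied in a fixed order as products of conditional probabilities, so
#' the output always sums to the input mass:
#' 1. death with probability `p_death` from every alive state;
#' 2. among survivors: from healthy, distant recurrence with `p_distant`,
#'    else local recurrence with `p_local` (distant takes precedence);
#'    from local recurrence, distant recurrence with `p_distant`; distant
#'    recurrence is absorbing apart from death;
#' 3. side-effect onset with probability `p_se` from any alive state
#'    without side effects; side effects are permanent.
#'
#' @param occupancy Numeric vector of length 7 in the order of
#'   [esc_states()]; should sum to 1.
#' @param p_death,p_local,p_distant,p_se Monthly probabilities for the
#'   cycle being applied.
#' @return The next occupancy vector (same order, same total mass).
#' @examples
#' occ <- c(1, 0, 0, 0, 0, 0, 0)
#' step_markov(occ, p_death = 0.1, p_local = 0, p_distant = 0, p_se = 0)
#' @export
step_markov <- function(occupancy, p_death, p_local, p_distant, p_se) {
  if (length(occupancy) != 7L) abort("`occupancy` must have length 7.")
  check_prob(c(p_death, p_local, p_distant, p_se), "probability")
  out <- step_markov_impl(occupancy, p_death, p_local, p_distant, p_se)
  if (any(out < 0)) abort("Internal error: negative occupancy.")
  out
}

# unchecked kernel shared with run_cohort (inputs validated upstream)
step_markov_impl <- function(occupancy, p_death, p_local, p_distant, p_se) {
  H <- occupancy[1]; Hs <- occupancy[2]
  L <- occupancy[3]; Ls <- occupancy[4]
  D <- occupancy[5]; Ds <- occupancy[6]
  dead <- occupancy[7]

  s <- 1 - p_death
  # destinations after death + recurrence, before side-effect onset
  to_H  <- H  * s * (1 - p_distant) * (1 - p_local)
  to_Hs <- Hs * s * (1 - p_distant) * (1 - p_local)
  to_L  <- H  * s * (1 - p_distant) * p_local + L * s * (1 - p_distant)
  to_Ls <- Hs * s * (1 - p_distant) * p_local + Ls * s * (1 - p_distant)
  to_D  <- (H + L) * s * p_distant + D * s
  to_Ds <- (Hs + Ls) * s * p_distant + Ds * s

  c(
    to_H * (1 - p_se),
    to_Hs + to_H * p_se,
    to_L * (1 - p_se),
    to_Ls + to_L * p_se,
    to_D * (1 - p_se),
    to_Ds + to_D * p_se,
    dead + (H + Hs + L + Ls + D + Ds) * p_death
  )
}

#' Treatment-phase survival
#'
#' Propagates the cohort through the up-front treatment phase, where the
#' only event is treatment-related death: the 3-month treatment-related
#' mortality is converted to a monthly probability and applied in each
#' treatment cycle (replacing background death). Survivors at the end of
#' the phase continue as healthy, post-treatment.
#'
#' @inheritParams build_transition_schedule
#' @return A list with `alive` (per-cycle alive fraction over the phase)
#'   and `occupancy` (the 7-state row at the end of the last phase cycle).
#' @examples
#' run_treatment_phase(base_case_params(), "crts")$alive[3] # 1 - 0.0926
#' @export
run_treatment_phase <- function(params, arm, settings = esc_settings()) {
  arm <- match.arg(arm, arm_cols)
  trm <- get_param(params, paste0("trm_3mo.", arm))
  tp <- settings$treatment_phase_months
  q <- prob_period_to_monthly(trm, tp)
  alive <- (1 - q)^seq_len(tp)
  occupancy <- c(alive[tp], 0, 0, 0, 0, 0, 1 - alive[tp])
  names(occupancy) <- esc_states()
  list(alive = alive, occupancy = occupancy)
}

#' Run the cohort model for one arm
#'
#' Chains the treatment phase and the monthly Markov model over the full
#' horizon, recording end-of-cycle state occupancy, per-cycle death
#' incidence and the discount factor. During the treatment phase the alive
#' mass is carried in the healthy column (utilities there are governed by
#' the treatment-phase weight, not the state).
#'
#' @inheritParams build_transition_schedule
#' @return A tibble of class `"esc_trace"` with columns `cycle`, the seven
#'   state fractions, `death_incidence` and `discount`; attributes `arm`
#'   and `settings`.
#' @examples
#' tr <- run_cohort(base_case_params(), "crt")
#' all.equal(rowSums(tr[, esc_states()]), rep(1, 300))
#' @export
run_cohort <- function(params, arm, settings = esc_settings()) {
  core <- cohort_core(params, arm, settings, validate = TRUE)
  out <- as_tibble(cbind(cycle = seq_len(nrow(core$occ)), core$occ))
  out$death_incidence <- core$death_incidence
  out$discount <- core$discount
  structure(out, class = c("esc_trace", class(out)),
            arm = arm, settings = settings)
}

# matrix-only engine shared by run_cohort and the DSA/PSA fast path
cohort_core <- function(params, arm, settings, validate = TRUE) {
  arm <- match.arg(arm, arm_cols)
  sv <- schedule_vectors(params, arm, settings, validate = validate)
  H <- settings$horizon_months
  tp <- settings$treatment_phase_months

  occ <- matrix(0, nrow = H, ncol = 7L,
                dimnames = list(NULL, esc_states()))
  q_trm <- sv$p_death[1]
  alive <- (1 - q_trm)^seq_len(tp)
  occ[seq_len(tp), 1L] <- alive
  occ[seq_len(tp), 7L] <- 1 - alive

  pd <- sv$p_death; pl <- sv$p_local; pr <- sv$p_distant; ps <- sv$p_se
  h <- alive[tp]; hs <- 0; l <- 0; ls <- 0; di <- 0; dis <- 0
  dead <- 1 - alive[tp]
  for (t in seq.int(tp + 1L, H)) {
    s <- 1 - pd[t]; r <- pr[t]; lo <- pl[t]; se <- ps[t]
    dead <- dead + (h + hs + l + ls + di + dis) * pd[t]
    to_h <- h * s * (1 - r) * (1 - lo)
    to_hs <- hs * s * (1 - r) * (1 - lo)
    to_l <- h * s * (1 - r) * lo + l * s * (1 - r)
    to_ls <- hs * s * (1 - r) * lo + ls * s * (1 - r)
    to_d <- (h + l) * s * r + di * s
    to_ds <- (hs + ls) * s * r + dis * s
    h <- to_h * (1 - se)
    hs <- to_hs + to_h * se
    l <- to_l * (1 - se)
    ls <- to_ls + to_l * se
    di <- to_d * (1 - se)
    dis <- to_ds + to_d * se
    occ[t, 1L] <- h; occ[t, 2L] <- hs; occ[t, 3L] <- l
    occ[t, 4L] <- ls; occ[t, 5L] <- di; occ[t, 6L] <- dis
    occ[t, 7L] <- dead
  }
  dead_col <- occ[, 7L]
  list(
    occ = occ,
    death_incidence = dead_col - c(0, dead_col[-H]),
    discount = discount_factor(seq_len(H), settings$annual_discount_rate)
  )
}

#' @export
print.esc_trace <- function(x, ...) {
  cat(sprintf("<esc_trace> arm %s, %d monthly cycles\n",
              toupper(attr(x, "arm")), nrow(x)))
  NextMethod()
}

#' Export a cohort trace to CSV
#'
#' One row per cycle: the seven state fractions, death incidence and the
#' discount factor, with metadata comment lines (arm, settings) on top.
#'
#' @param trace An `esc_trace` from [run_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write_csv_with_meta(
    as_tibble(trace),
    path,
    meta = c(arm = attr(trace, "arm"))
  )
}
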