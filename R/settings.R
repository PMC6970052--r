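#' Economic and structural model settings
#'
#' Bundles the run-level constants of the model: discount rate, horizon,
#' cycle structure, willingness to pay, and cohort starting age. Defaults
#' reproduce the base analysis: a 57-year-old cohort followed for 25 years
#' in monthly cycles, a 3-month treatment phase, costs and QALYs discounted
#' at 3% per year, and a willingness to pay of $150,000 per QALY.
#'
#' @param annual_discount_rate Annual discount rate applied to both costs and
#'   QALYs. Non-negative; default 0.03.
#' @param horizon_months Model horizon in monthly cycles; default 300
#'   (25 years).
#' @param treatment_phase_months Length of the up-front treatment phase in
#'   cycles; default 3.
#' @param wtp Willingness-to-pay threshold in dollars per QALY; default
#'   150000.
#' @param start_age_years Cohort age at diagnosis; default 57. Background
#'   mortality from the life table is looked up at the attained age.
#' @param equalization_month Cycle after which the two arms share identical
#'   state utilities (the max of the two arm-specific values); default 12.
#'
#' @return A list with class `"esc_settings"`.
#' @examples
#' esc_settings()
#' esc_settings(annual_discount_rate = 0, wtp = 100000)
#' @export
esc_settings <- function(annual_discount_rate = 0.03,
                         horizon_months = 300L,
                         treatment_phase_months = 3L,
                         wtp = 150000,
                         start_age_years = 57L,
                         equalization_month = 12L) {
  if (annual_discount_rate < 0) {
    abort("`annual_discount_rate` must be non-negative.")
  }
  horizon_months <- as.integer(horizon_months)
  treatment_phase_months <- as.integer(treatment_phase_months)
  if (horizon_months < 1L || treatment_phase_months < 1L ||
      treatment_phase_months >= horizon_months) {
    abort("Need 1 <= treatment_phase_months < horizon_months.")
  }
  structure(
    list(
      annual_discount_rate = annual_discount_rate,
      horizon_months = horizon_months,
      cycle_length_months = 1L,
      treatment_phase_months = treatment_phase_months,
      wtp = wtp,
      start_age_years = as.integer(start_age_years),
      equalization_month = as.integer(equalization_month)
    ),
    class = "esc_settings"
  )
}

#' @export
print.esc_settings <- function(x, ...) {
  cat("<esc_settings>\n")
  cat(sprintf("  discount rate : %.3f / yr\n", x$annual_discount_rate))
  cat(sprintf("  horizon       : %d monthly cycles (%.1f yr)\n",
              x$horizon_months, x$horizon_months / 12))
  cat(sprintf("  treatment     : cycles 1-%d\n", x$treatment_phase_months))
  cat(sprintf("  WTP           : $%s / QALY\n",
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  start age     : %d yr; utilities equalized after month %d\n",
              x$start_age_years, x$equalization_month))
  invisible(x)
}

#' Monthly discount factor
#'
#' Present-value weight of cycle `cycle` under annual rate `annual_rate`,
#' with monthly compounding: `(1 + annual_rate)^(-(cycle - 1)/12)`. The
#' first cycle is undiscounted.
#'
#' @param cycle Cycle index (1-based); vectorized.
#' @param annual_rate Non-negative annual discount rate.
#' @return Numeric vector of factors in (0, 1].
#' @examples
#' discount_factor(1, 0.03)   # 1
#' discount_factor(13, 0.03)  # 1 / 1.03
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(annual_rate < 0)) abort("`annual_rate` must be non-negative.")
  if (any(cycle < 1)) abort("`cycle` must be >= 1.")
  (1 + annual_rate)^(-(cycle - 1) / 12)
}
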