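#' Discounted cost and QALYs for one strategy
#'
#' Runs the cohort model for one arm and attributes costs and QALYs.
#'
#' @inheritParams build_transition_schedule
#' @return A one-row tibble: `arm`, `cost`, `qalys` (both discounted).
#' @export
evaluate_strategy <- function(params, arm, settings = esc_settings()) {
  v <- eval_arm(params, arm, settings)
  tibble(arm = arm, cost = v[["cost"]], qalys = v[["qalys"]])
}

# fast path shared by base case, DSA and PSA: no tibble round trips
eval_arm <- function(params, arm, settings, validate = TRUE) {
  core <- cohort_core(params, arm, settings, validate = validate)
  sc <- params$scalars
  cost <- cost_kernel(
    core$death_incidence, core$discount,
    sc[[arm]][match("c_initial", sc$parameter)],
    sc$crt[match("c_continuing", sc$parameter)],
    sc$crt[match("c_eol", sc$parameter)]
  )
  U <- utility_matrix(params, arm, settings)
  c(cost = cost,
    qalys = sum(rowSums(core$occ * U) * core$discount) / 12)
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes incremental cost, incremental QALYs, the ICER where it is
#' meaningful, a dominance classification, and the incremental net
#' monetary benefit `INMB(a vs b) = wtp * (E_a - E_b) - (C_a - C_b)`.
#' Strategy `a` dominates when it costs less and yields more QALYs (and
#' vice versa); under dominance, or when the QALY difference is zero, the
#' ICER is flagged undefined (`NA`) while the INMB remains valid.
#'
#' @param result_a,result_b Lists or one-row data frames with elements
#'   `cost` and `qalys` (see [evaluate_strategy()]).
#' @param wtp Willingness to pay, dollars per QALY.
#' @param labels Length-2 character vector naming the strategies.
#' @return A one-row tibble: `delta_cost`, `delta_qalys`, `icer`,
#'   `dominance` (`"a_dominant"`, `"b_dominant"`, `"none"`), `inmb`,
#'   `wtp`, `preferred` (label of the higher-NMB strategy).
#' @examples
#' compare_strategies(list(cost = 154082, qalys = 1.32),
#'                    list(cost = 165035, qalys = 1.30), wtp = 150000)
#' @export
compare_strategies <- function(result_a, result_b, wtp,
                               labels = c("crt", "crts")) {
  ca <- result_a$cost; ea <- result_a$qalys
  cb <- result_b$cost; eb <- result_b$qalys
  if (any(!is.finite(c(ca, ea, cb, eb)))) {
    abort("Strategy results must be finite.")
  }
  dc <- ca - cb
  de <- ea - eb
  inmb <- wtp * de - dc
  dominance <- if (ca <= cb && ea >= eb && (ca < cb || ea > eb)) {
    "a_dominant"
  } else if (cb <= ca && eb >= ea && (cb < ca || eb > ea)) {
    "b_dominant"
  } else {
    "none"
  }
  icer <- if (dominance != "none" || de == 0) NA_real_ else dc / de
  preferred <- if (inmb > 0) labels[1] else if (inmb < 0) labels[2] else NA
  tibble(delta_cost = dc, delta_qalys = de, icer = icer,
         dominance = dominance, inmb = inmb, wtp = wtp,
         preferred = preferred)
}

#' Base-case cost-effectiveness analysis
#'
#' Evaluates both strategies and compares CRT against CRT+S at the given
#' willingness to pay.
#'
#' @param params An [esc_params] object.
#' @param settings An [esc_settings] object.
#' @param wtp Willingness to pay; defaults to the value in `settings`.
#' @return An object of class `"esc_cea"`: list with `strategies` (tibble,
#'   one row per arm) and `incremental` (CRT vs CRT+S, see
#'   [compare_strategies()]).
#' @examples
#' \donttest{
#' run_base_case(base_case_params())
#' }
#' @export
run_base_case <- function(params, settings = esc_settings(),
                          wtp = settings$wtp) {
  strategies <- bind_rows(
    evaluate_strategy(params, "crt", settings),
    evaluate_strategy(params, "crts", settings)
  )
  incremental <- compare_strategies(
    strategies[strategies$arm == "crt", ],
    strategies[strategies$arm == "crts", ],
    wtp = wtp
  )
  structure(list(strategies = strategies, incremental = incremental,
                 settings = settings),
            class = "esc_cea")
}

#' @export
print.esc_cea <- function(x, ...) {
  cat("<esc_cea> base-case cost-effectiveness, CRT vs CRT+S\n")
  s <- x$strategies
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s $%s for %.3f QALYs\n", toupper(s$arm[i]),
                format(round(s$cost[i]), big.mark = ","), s$qalys[i]))
  }
  inc <- x$incremental
  cat(sprintf("  dominance: %s; INMB(CRT) at $%s/QALY: $%s",
              inc$dominance, format(inc$wtp, big.mark = ","),
              format(round(inc$inmb), big.mark = ",")))
  if (!is.na(inc$icer)) {
    cat(sprintf("; ICER $%s/QALY", format(round(inc$icer), big.mark = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curves and frontier
#'
#' From per-iteration PSA (cost, QALY) pairs, computes for each
#' willingness-to-pay value the fraction of iterations in which each
#' strategy has the strictly highest net monetary benefit (exact ties
#' split equally) and marks the frontier: the strategy with the highest
#' mean net monetary benefit at that willingness to pay.
#'
#' @param psa_pairs Data frame with columns `cost_crt`, `qaly_crt`,
#'   `cost_crts`, `qaly_crts` (one row per PSA iteration).
#' @param wtp_grid Numeric vector of willingness-to-pay values; default
#'   $0-$300,000 in $10,000 steps.
#' @return Tibble: `wtp`, `ceac_crt`, `ceac_crts`, `frontier_arm`.
#' @export
ceac <- function(psa_pairs, wtp_grid = seq(0, 300000, by = 10000)) {
  need <- c("cost_crt", "qaly_crt", "cost_crts", "qaly_crts")
  if (!is.data.frame(psa_pairs) || nrow(psa_pairs) < 1 ||
      !all(need %in% names(psa_pairs))) {
    abort("`psa_pairs` must have >= 1 row with cost/QALY columns per arm.")
  }
  if (length(wtp_grid) < 1) abort("`wtp_grid` must be non-empty.")
  purrr::map_dfr(wtp_grid, function(lambda) {
    nmb_crt <- lambda * psa_pairs$qaly_crt - psa_pairs$cost_crt
    nmb_crts <- lambda * psa_pairs$qaly_crts - psa_pairs$cost_crts
    p_crt <- mean((nmb_crt > nmb_crts) + 0.5 * (nmb_crt == nmb_crts))
    tibble(
      wtp = lambda,
      ceac_crt = p_crt,
      ceac_crts = 1 - p_crt,
      frontier_arm = if (mean(nmb_crt) >= mean(nmb_crts)) "crt" else "crts"
    )
  })
}
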