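#' Tidy a base-case CEA result
#'
#' @param x An `esc_cea` object from [run_base_case()].
#' @param ... Unused.
#' @return Per-strategy tibble: `arm`, `cost`, `qalys`.
#' @export
tidy.esc_cea <- function(x, ...) {
  x$strategies
}

#' One-row summary of a base-case CEA result
#'
#' @inheritParams tidy.esc_cea
#' @return One-row tibble with incremental cost, incremental QALYs, ICER,
#'   dominance class, INMB, WTP and the preferred strategy.
#' @export
glance.esc_cea <- function(x, ...) {
  x$incremental
}

#' Tidy PSA samples
#'
#' @param x An `esc_psa` object from [run_psa()].
#' @param ... Unused.
#' @return The per-iteration samples tibble.
#' @export
tidy.esc_psa <- function(x, ...) {
  x$samples
}

#' One-row summary of a PSA
#'
#' @inheritParams tidy.esc_psa
#' @return One-row tibble: dominance and cost-effectiveness fractions,
#'   rejection count, iteration count and seed.
#' @export
glance.esc_psa <- function(x, ...) {
  bind_cols(x$dominance,
            tibble(n_rejected = x$n_rejected,
                   n_iterations = x$n_iterations, seed = x$seed))
}

#' Tidy a parameter set into long format
#'
#' @param x An `esc_params` object.
#' @param ... Unused.
#' @return Long tibble: `parameter`, `arm`, `value`, `type`, `shared`,
#'   `fixture`.
#' @export
tidy.esc_params <- function(x, ...) {
  tidyr::pivot_longer(x$scalars, cols = dplyr::all_of(arm_cols),
                      names_to = "arm", values_to = "value")
}

#' Tidy a tornado table
#'
#' @param x An `esc_tornado` object from [one_way_dsa()].
#' @param ... Unused.
#' @return Long tibble: `id`, `bound` (`"low"`/`"high"`), `value`, `inmb`.
#' @export
tidy.esc_tornado <- function(x, ...) {
  bind_rows(
    tibble(id = x$id, bound = "low", value = x$low, inmb = x$inmb_low),
    tibble(id = x$id, bound = "high", value = x$high, inmb = x$inmb_high)
  )
}
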