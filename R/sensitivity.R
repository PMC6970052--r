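#' Default deterministic sensitivity-analysis registry
#'
#' One row per varied parameter: all base probabilities and utilities, the
#' side-effect and esophagectomy decrements, the phase costs,
#' treatment-related mortality, and the (fixture) death-rate scale factors.
#' Bounds default to the base value +/- 50%; probabilities and utilities
#' are clipped to \[0, 1\]. Known 95% confidence intervals can be supplied
#' and take precedence over the +/- 50% rule.
#'
#' @param params An [esc_params] object.
#' @param ci Optional data frame `id`, `low`, `high` of 95% CI bounds.
#' @return Tibble: `id`, `type`, `base`, `low`, `high`.
#' @export
dsa_registry <- function(params, ci = NULL) {
  sc <- params$scalars
  per_arm <- c("trm_3mo", "p_local", "p_distant", "p_side_effects",
               "u_treatment", "c_initial", "death_scale")
  linked <- c("u_healthy", "u_local", "u_distant", "surgery_decrement")
  shared <- c("se_decrement", "c_continuing", "c_eol")
  ids <- c(
    as.vector(outer(per_arm, arm_cols, paste, sep = ".")),
    linked, shared
  )
  reg <- purrr::map_dfr(ids, function(id) {
    base <- get_param(params, id)
    type <- sc$type[match(strsplit(id, ".", fixed = TRUE)[[1]][1],
                          sc$parameter)]
    low <- base * 0.5
    high <- base * 1.5
    if (type %in% c("probability", "utility")) {
      low <- max(0, low); high <- min(1, high)
    }
    tibble(id = id, type = type, base = base, low = low, high = high)
  })
  if (!is.null(ci)) {
    stopifnot(all(c("id", "low", "high") %in% names(ci)))
    i <- match(ci$id, reg$id)
    if (anyNA(i)) abort("Unknown parameter id in `ci`.")
    reg$low[i] <- ci$low
    reg$high[i] <- ci$high
  }
  if (any(reg$low > reg$base | reg$base > reg$high)) {
    abort("Registry bounds must satisfy low <= base <= high.")
  }
  reg
}

inmb_at <- function(params, settings, wtp) {
  a <- eval_arm(params, "crt", settings)
  b <- eval_arm(params, "crts", settings)
  wtp * (a[["qalys"]] - b[["qalys"]]) - (a[["cost"]] - b[["cost"]])
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full model with each registry parameter at its low and high
#' bound, everything else at base, recording the incremental net monetary
#' benefit of CRT over CRT+S at both ends. Rows are sorted by descending
#' bar width `|inmb_high - inmb_low|`. The input parameter set is never
#' modified.
#'
#' @param params An [esc_params] object.
#' @param settings An [esc_settings] object.
#' @param registry A [dsa_registry()] tibble (possibly subset).
#' @param wtp Willingness to pay; defaults to `settings$wtp`.
#' @return Tibble of class `"esc_tornado"`: `id`, `low`, `high`,
#'   `inmb_low`, `inmb_high`, `width`; attribute `inmb_base`.
#' @export
one_way_dsa <- function(params, settings = esc_settings(),
                        registry = dsa_registry(params),
                        wtp = settings$wtp) {
  base_inmb <- inmb_at(params, settings, wtp)
  if (nrow(registry) == 0) {
    out <- tibble(id = character(), low = numeric(), high = numeric(),
                  inmb_low = numeric(), inmb_high = numeric(),
                  width = numeric())
    return(structure(out, class = c("esc_tornado", class(out)),
                     inmb_base = base_inmb, wtp = wtp))
  }
  out <- purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    tibble(
      id = r$id, low = r$low, high = r$high,
      inmb_low = inmb_at(set_param(params, r$id, r$low), settings, wtp),
      inmb_high = inmb_at(set_param(params, r$id, r$high), settings, wtp)
    )
  })
  out$width <- abs(out$inmb_high - out$inmb_low)
  out <- arrange(out, desc(.data$width))
  structure(out, class = c("esc_tornado", class(out)),
            inmb_base = base_inmb, wtp = wtp)
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates the preferred strategy (highest net monetary benefit) on a
#' grid of two parameters, at one or more willingness-to-pay values.
#'
#' @param params An [esc_params] object.
#' @param x_id,y_id Parameter ids (see [get_param()]).
#' @param x_values,y_values Numeric grids for the two parameters.
#' @param settings An [esc_settings] object.
#' @param wtp_list Willingness-to-pay values to evaluate.
#' @return Tibble of class `"esc_twoway"`: `x`, `y`, `wtp`, `inmb`
#'   (CRT vs CRT+S), `preferred`.
#' @export
two_way_dsa <- function(params, x_id, y_id, x_values, y_values,
                        settings = esc_settings(),
                        wtp_list = settings$wtp) {
  grid <- tidyr::expand_grid(x = x_values, y = y_values)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    p <- set_param(set_param(params, x_id, grid$x[i]), y_id, grid$y[i])
    a <- eval_arm(p, "crt", settings)
    b <- eval_arm(p, "crts", settings)
    purrr::map_dfr(wtp_list, function(lambda) {
      inmb <- lambda * (a[["qalys"]] - b[["qalys"]]) -
        (a[["cost"]] - b[["cost"]])
      tibble(x = grid$x[i], y = grid$y[i], wtp = lambda, inmb = inmb,
             preferred = if (inmb >= 0) "crt" else "crts")
    })
  })
  structure(out, class = c("esc_twoway", class(out)),
            x_id = x_id, y_id = y_id)
}

#' Threshold analysis: parameter value at which INMB crosses zero
#'
#' Checks for a sign change of the CRT-vs-CRT+S incremental net monetary
#' benefit across `[lower, upper]`, verifies approximate monotonicity on a
#' coarse grid, then bisects to the crossing value. If the INMB has the
#' same sign at both ends, a "no threshold in range" result is returned
#' rather than an error.
#'
#' @param params An [esc_params] object.
#' @param id Parameter id to vary.
#' @param lower,upper Search interval; defaults to the [dsa_registry()]
#'   bounds for `id`.
#' @param settings An [esc_settings] object.
#' @param wtp Willingness to pay.
#' @param tol Absolute INMB tolerance at the crossing (default $1).
#' @param coarse_points Grid size for the monotonicity pre-check.
#' @return A one-row tibble: `id`, `found`, `threshold` (NA when not
#'   found), `inmb_at_threshold`, `lower`, `upper`, `monotone`.
#' @export
threshold_search <- function(params, id, lower = NULL, upper = NULL,
                             settings = esc_settings(), wtp = settings$wtp,
                             tol = 1, coarse_points = 9L) {
  if (is.null(lower) || is.null(upper)) {
    reg <- dsa_registry(params)
    r <- reg[reg$id == id, ]
    if (nrow(r) != 1) abort(sprintf("No registry bounds for `%s`.", id))
    lower <- lower %||% r$low
    upper <- upper %||% r$high
  }
  f <- function(v) inmb_at(set_param(params, id, v), settings, wtp)
  grid <- seq(lower, upper, length.out = coarse_points)
  fg <- vapply(grid, f, numeric(1))
  monotone <- all(diff(fg) >= 0) || all(diff(fg) <= 0)
  if (!monotone) {
    warn(sprintf("INMB is not monotone in `%s` on the coarse grid.", id))
  }
  no_threshold <- function() {
    tibble(id = id, found = FALSE, threshold = NA_real_,
           inmb_at_threshold = NA_real_, lower = lower, upper = upper,
           monotone = monotone)
  }
  sign_change <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (fg[1] == 0) {
    return(tibble(id = id, found = TRUE, threshold = grid[1],
                  inmb_at_threshold = 0, lower = lower, upper = upper,
                  monotone = monotone))
  }
  if (length(sign_change) == 0) return(no_threshold())
  lo <- grid[sign_change[1]]
  hi <- grid[sign_change[1] + 1]
  flo <- fg[sign_change[1]]
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-9 * max(abs(upper), 1)) {
      return(tibble(id = id, found = TRUE, threshold = mid,
                    inmb_at_threshold = fm, lower = lower, upper = upper,
                    monotone = monotone))
    }
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
}
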