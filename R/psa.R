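#' Sampling distributions for probabilistic sensitivity analysis
#'
#' Method-of-moments distributions per parameter type: beta for
#' probabilities and utilities, gamma for costs and for the positive
#' death-rate scale factors. The mean is the base-case value; the standard
#' deviation is the registry range width divided by 3.92 (the width of a
#' 95% normal interval), which for an unclipped +/- 50% range equals
#' 0.2551 times the base value. Parameters with zero mean or zero sd
#' become point masses. Infeasible beta moments (sd too large for the
#' mean) are clipped to 99% of the feasible maximum with a warning.
#'
#' @param params An [esc_params] object.
#' @param registry A [dsa_registry()] tibble supplying ranges (and hence
#'   sds); subset it to restrict which parameters vary.
#' @return Tibble: `id`, `family` (`"beta"`, `"gamma"`, `"point"`),
#'   `mean`, `sd`, `par1`, `par2` (shape1/shape2 for beta, shape/rate for
#'   gamma).
#' @export
build_distributions <- function(params, registry = dsa_registry(params)) {
  purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    m <- r$base
    s <- (r$high - r$low) / 3.92
    family <- switch(r$type,
                     probability = , utility = "beta",
                     cost = , scale = "gamma",
                     abort(sprintf("No distribution family for type `%s`.",
                                   r$type)))
    if (s == 0 || m == 0) {
      return(tibble(id = r$id, family = "point", mean = m, sd = 0,
                    par1 = NA_real_, par2 = NA_real_))
    }
    if (family == "beta") {
      s_max <- sqrt(m * (1 - m))
      if (s >= s_max) {
        warn(sprintf("sd for `%s` infeasible for a beta mean of %.3f; clipped.",
                     r$id, m))
        s <- 0.99 * s_max
      }
      nu <- m * (1 - m) / s^2 - 1
      par1 <- m * nu
      par2 <- (1 - m) * nu
    } else {
      par1 <- m^2 / s^2   # shape
      par2 <- m / s^2     # rate
    }
    tibble(id = r$id, family = family, mean = m, sd = s,
           par1 = par1, par2 = par2)
  })
}

draw_distributions <- function(distributions) {
  vapply(seq_len(nrow(distributions)), function(i) {
    d <- distributions[i, ]
    switch(d$family,
           point = d$mean,
           beta = rbeta(1, d$par1, d$par2),
           gamma = rgamma(1, shape = d$par1, rate = d$par2))
  }, numeric(1))
}

# apply a full vector of draws in one pass, validating once
apply_draws <- function(params, ids, values) {
  sc <- params$scalars
  for (k in seq_along(ids)) {
    parts <- strsplit(ids[k], ".", fixed = TRUE)[[1]]
    row <- match(parts[1], sc$parameter)
    if (is.na(row)) abort(sprintf("Unknown parameter id `%s`.", ids[k]))
    if (length(parts) == 1) {
      sc$crt[row] <- values[k]
      sc$crts[row] <- values[k]
    } else {
      sc[[parts[2]]][row] <- values[k]
    }
  }
  params$scalars <- refresh_derived_utilities(sc)
  validate_params(params)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo parameter uncertainty: per iteration, one value is drawn
#' per distribution (shared parameters once, applied to both arms), both
#' cohorts are run, and the discounted (cost, QALY) pair per arm is
#' recorded. Draws producing an invalid parameter set (for example a
#' scaled death probability above 1) are rejected and redrawn, with the
#' count reported. One master seed spawns an independent substream per
#' iteration, so results do not depend on evaluation order and are
#' bit-reproducible.
#'
#' @param params An [esc_params] object (base case).
#' @param settings An [esc_settings] object.
#' @param n_iterations Number of Monte-Carlo repetitions (10,000 in the
#'   full analysis).
#' @param seed Master RNG seed.
#' @param distributions A [build_distributions()] tibble.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curves.
#' @return An object of class `"esc_psa"`: list with `samples` (tibble:
#'   `iteration`, `cost_crt`, `qaly_crt`, `cost_crts`, `qaly_crts`,
#'   incremental columns), `draws` (tibble of parameter draws), `ceac`
#'   (see [ceac()]), `dominance` (tibble of fractions), `n_rejected`,
#'   `n_iterations`, `seed`.
#' @examples
#' \donttest{
#' p <- base_case_params()
#' run_psa(p, n_iterations = 20, seed = 1)
#' }
#' @export
run_psa <- function(params, settings = esc_settings(),
                    n_iterations = 10000L, seed = 1L,
                    distributions = build_distributions(params),
                    wtp_grid = seq(0, 300000, by = 10000)) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  validate_params(params, settings)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)

  ids <- distributions$id
  n_rejected <- 0L
  draws <- matrix(NA_real_, nrow = n_iterations, ncol = length(ids),
                  dimnames = list(NULL, ids))
  res <- matrix(NA_real_, nrow = n_iterations, ncol = 4L,
                dimnames = list(NULL, c("cost_crt", "qaly_crt",
                                        "cost_crts", "qaly_crts")))
  for (i in seq_len(n_iterations)) {
    set.seed(iter_seeds[i])
    repeat {
      v <- draw_distributions(distributions)
      p_i <- tryCatch(apply_draws(params, ids, v), error = function(e) NULL)
      if (!is.null(p_i)) break
      n_rejected <- n_rejected + 1L
    }
    draws[i, ] <- v
    a <- eval_arm(p_i, "crt", settings, validate = FALSE)
    b <- eval_arm(p_i, "crts", settings, validate = FALSE)
    res[i, ] <- c(a, b)
  }
  if (n_rejected > 0) {
    message(sprintf("PSA: %d invalid draw(s) rejected and redrawn.",
                    n_rejected))
  }

  samples <- as_tibble(res)
  samples <- mutate(samples,
                    iteration = seq_len(n_iterations),
                    delta_cost = .data$cost_crt - .data$cost_crts,
                    delta_qalys = .data$qaly_crt - .data$qaly_crts,
                    .before = 1)
  crt_dom <- mean(samples$cost_crt < samples$cost_crts &
                    samples$qaly_crt > samples$qaly_crts)
  crts_dom <- mean(samples$cost_crts < samples$cost_crt &
                     samples$qaly_crts > samples$qaly_crt)
  nmb_gap <- settings$wtp * samples$delta_qalys - samples$delta_cost
  dominance <- tibble(
    crt_dominant = crt_dom,
    crts_dominant = crts_dom,
    neither = 1 - crt_dom - crts_dom,
    crt_cost_effective = mean((nmb_gap > 0) + 0.5 * (nmb_gap == 0)),
    crts_cost_effective = mean((nmb_gap < 0) + 0.5 * (nmb_gap == 0)),
    wtp = settings$wtp
  )
  structure(
    list(samples = samples, draws = as_tibble(draws),
         ceac = ceac(samples, wtp_grid), dominance = dominance,
         n_rejected = n_rejected, n_iterations = n_iterations,
         seed = seed, settings = settings),
    class = "esc_psa"
  )
}

#' @export
print.esc_psa <- function(x, ...) {
  cat(sprintf("<esc_psa> %d Monte-Carlo iterations (seed %d)\n",
              x$n_iterations, x$seed))
  d <- x$dominance
  cat(sprintf("  CRT dominant %.1f%%, cost-effective at $%s/QALY %.1f%%\n",
              100 * d$crt_dominant, format(d$wtp, big.mark = ","),
              100 * d$crt_cost_effective))
  cat(sprintf("  CRT+S dominant %.1f%%, cost-effective %.1f%%\n",
              100 * d$crts_dominant, 100 * d$crts_cost_effective))
  invisible(x)
}
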