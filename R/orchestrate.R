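#' Write a parameter set to YAML (with optional CSV side files)
#'
#' Serializes the scalar parameters (one block per parameter with both
#' arm values), the years 1-4 monthly death-rate vectors and the life
#' table. The two tables are inlined unless CSV file names are given, in
#' which case they are written next to the YAML and referenced by name.
#'
#' @param params An [esc_params] object.
#' @param path Output YAML path.
#' @param death_csv,lifetable_csv Optional file names (relative to the
#'   YAML) for the death-rate and life-table CSVs.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path,
                              death_csv = NULL, lifetable_csv = NULL) {
  sc <- params$scalars
  obj <- list(
    parameters = setNames(lapply(seq_len(nrow(sc)), function(i) {
      list(crt = sc$crt[i], crts = sc$crts[i], type = sc$type[i],
           shared = sc$shared[i], fixture = sc$fixture[i])
    }), sc$parameter),
    local_band_end_year = as.list(params$local_band_end_year),
    fixture_info = params$fixture_info
  )
  dir <- dirname(path)
  if (is.null(death_csv)) {
    obj$death_monthly <- lapply(
      seq_len(nrow(params$death_monthly)),
      function(i) as.list(params$death_monthly[i, ]))
  } else {
    write.csv(params$death_monthly, file.path(dir, death_csv),
              row.names = FALSE, quote = FALSE)
    obj$death_monthly_csv <- death_csv
  }
  if (is.null(lifetable_csv)) {
    obj$lifetable <- lapply(seq_len(nrow(params$lifetable)),
                            function(i) as.list(params$lifetable[i, ]))
  } else {
    write.csv(params$lifetable, file.path(dir, lifetable_csv),
              row.names = FALSE, quote = FALSE)
    obj$lifetable_csv <- lifetable_csv
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a parameter set from YAML
#'
#' Inverse of [write_params_yaml()]; CSV references are resolved relative
#' to the YAML file. The result is validated on construction.
#'
#' @param path YAML file path.
#' @return An [esc_params] object.
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) abort(sprintf("Parameter file not found: %s", path))
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(sprintf(
                    "Invalid YAML in %s: %s", path, conditionMessage(e))))
  if (is.null(obj$parameters)) abort("Parameter file has no `parameters` block.")
  dir <- dirname(path)
  sc <- purrr::map_dfr(names(obj$parameters), function(nm) {
    p <- obj$parameters[[nm]]
    tibble(parameter = nm, crt = as.numeric(p$crt), crts = as.numeric(p$crts),
           type = p$type, shared = isTRUE(p$shared),
           fixture = isTRUE(p$fixture))
  })
  read_block <- function(inline, csv_ref) {
    if (!is.null(inline)) {
      purrr::map_dfr(inline, as_tibble)
    } else {
      f <- file.path(dir, csv_ref)
      if (!file.exists(f)) abort(sprintf("Referenced CSV not found: %s", f))
      as_tibble(utils::read.csv(f, comment.char = "#"))
    }
  }
  esc_params(
    scalars = sc,
    death_monthly = read_block(obj[["death_monthly"]],
                               obj[["death_monthly_csv"]]),
    lifetable = read_block(obj[["lifetable"]], obj[["lifetable_csv"]]),
    local_band_end_year = unlist(obj$local_band_end_year),
    fixture_info = obj$fixture_info %||% list()
  )
}

# FNV-1a over a string; used to stamp outputs with a config digest.
# The output directory is not part of the digest: runs differing only in
# where they write are the same analysis.
config_digest <- function(config) {
  txt <- yaml::as.yaml(config[setdiff(names(config), "out_dir")])
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_csv_with_meta <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

round_cols <- function(df, currency = character(), qaly = character(),
                       prob = character()) {
  for (c in intersect(currency, names(df))) df[[c]] <- round(df[[c]])
  for (c in intersect(qaly, names(df))) df[[c]] <- round(df[[c]], 4)
  for (c in intersect(prob, names(df))) df[[c]] <- round(df[[c]], 6)
  df
}

#' Run a configured analysis end to end
#'
#' Single entry point wiring configuration, fixtures, the cohort engine,
#' comparative metrics and the sensitivity machinery, writing CSV outputs
#' stamped with the seed, a config digest and fixture provenance.
#'
#' The configuration is a list (or a YAML file path) with fields:
#' * `analysis`: one of `"base"`, `"dsa"`, `"twoway"`, `"threshold"`,
#'   `"psa"`, `"fixtures"`;
#' * `params`: optional path to a [write_params_yaml()] file (default:
#'   the packaged base case from [base_case_params()]);
#' * `seed`, `wtp`, `n_iterations`;
#' * `out_dir`: output directory (created if needed);
#' * analysis-specific: `threshold_id`; `twoway` (list with `x_id`,
#'   `y_id`, `x_values`, `y_values`, `wtp_list`).
#'
#' CSV bodies are rounded for exchange — whole dollars, QALYs to 4
#' decimals, probabilities to 6 — while all computation keeps full
#' precision. Two runs with the same configuration and seed produce
#' byte-identical files.
#'
#' @param config List or path to a YAML config file.
#' @return The analysis result object, invisibly.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  analysis <- config$analysis %||% "base"
  if (!analysis %in% c("base", "dsa", "twoway", "threshold", "psa",
                       "fixtures")) {
    abort(sprintf("Unknown analysis selector `%s`.", analysis))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  settings <- esc_settings(
    annual_discount_rate = config$annual_discount_rate %||% 0.03,
    wtp = config$wtp %||% 150000
  )
  params <- if (!is.null(config$params)) {
    read_params_yaml(config$params)
  } else {
    base_case_params(settings = settings)
  }
  validate_params(params, settings)
  meta <- c(
    config_digest = config_digest(config),
    seed = seed,
    fixture = if (isTRUE(params$fixture_info$fixture)) {
      "death_monthly and lifetable are synthetic fixtures"
    } else {
      "none"
    }
  )
  path <- function(f) file.path(out_dir, f)

  result <- switch(
    analysis,
    base = {
      cea <- run_base_case(params, settings)
      settings0 <- esc_settings(annual_discount_rate = 0,
                                wtp = settings$wtp)
      undisc <- bind_rows(evaluate_strategy(params, "crt", settings0),
                          evaluate_strategy(params, "crts", settings0))
      res <- left_join(tidy(cea),
                       rename(undisc, cost_undiscounted = "cost",
                              qalys_undiscounted = "qalys"),
                       by = "arm")
      write_csv_with_meta(
        round_cols(res, currency = c("cost", "cost_undiscounted"),
                   qaly = c("qalys", "qalys_undiscounted")),
        path("results.csv"), meta)
      write_csv_with_meta(
        round_cols(glance(cea), currency = c("delta_cost", "icer", "inmb",
                                             "wtp"),
                   qaly = "delta_qalys"),
        path("incremental.csv"), meta)
      cea
    },
    dsa = {
      tornado <- one_way_dsa(params, settings)
      write_csv_with_meta(
        round_cols(as_tibble(tornado),
                   currency = c("inmb_low", "inmb_high", "width")),
        path("tornado.csv"), meta)
      tornado
    },
    twoway = {
      tw <- config$twoway %||% list()
      x_id <- tw$x_id %||% "p_distant.crt"
      y_id <- tw$y_id %||% "p_distant.crts"
      x_values <- tw$x_values %||%
        seq(0.5, 1.5, length.out = 11) * get_param(params, x_id)
      y_values <- tw$y_values %||%
        seq(0.5, 1.5, length.out = 11) * get_param(params, y_id)
      grid <- two_way_dsa(params, x_id, y_id, x_values, y_values,
                          settings,
                          wtp_list = tw$wtp_list %||% c(100000, 150000))
      write_csv_with_meta(
        round_cols(as_tibble(grid), currency = c("inmb", "wtp"),
                   prob = c("x", "y")),
        path("twoway.csv"), meta)
      grid
    },
    threshold = {
      id <- config$threshold_id %||% "c_initial.crts"
      th <- threshold_search(params, id, settings = settings)
      write_csv_with_meta(th, path("threshold.csv"), meta)
      th
    },
    psa = {
      psa <- run_psa(params, settings,
                     n_iterations = as.integer(config$n_iterations %||%
                                                 10000L),
                     seed = seed)
      write_csv_with_meta(
        round_cols(psa$samples,
                   currency = c("cost_crt", "cost_crts", "delta_cost"),
                   qaly = c("qaly_crt", "qaly_crts", "delta_qalys")),
        path("psa_samples.csv"), meta)
      write_csv_with_meta(
        round_cols(psa$ceac, currency = "wtp",
                   prob = c("ceac_crt", "ceac_crts")),
        path("ceac.csv"), meta)
      write_csv_with_meta(round_cols(glance(psa),
                                     prob = c("crt_dominant", "crts_dominant",
                                              "neither",
                                              "crt_cost_effective",
                                              "crts_cost_effective")),
                          path("psa_summary.csv"), meta)
      psa
    },
    fixtures = {
      write_params_yaml(params, path("params.yaml"),
                        death_csv = "deathrates.csv",
                        lifetable_csv = "lifetable.csv")
      # re-write the referenced CSVs with provenance stamps on top
      write_csv_with_meta(params$lifetable, path("lifetable.csv"), meta)
      write_csv_with_meta(params$death_monthly, path("deathrates.csv"),
                          meta)
      params
    }
  )
  invisible(result)
}
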