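pkg_version <- function() {
  as.character(utils::packageVersion("pcacea"))
}

output_header <- function(params, seed = NA) {
  c(sprintf("pcacea %s", pkg_version()),
    sprintf("seed=%s", as.character(seed)),
    sprintf("params_md5=%s", param_hash(params)))
}

write_report_table <- function(tab, path, params, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", output_header(params, seed)), con)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Resolve a run configuration
#'
#' A configuration is a named list (or path to a YAML file holding one) with
#' optional entries: `params` (path to a parameter YAML; default the built-in
#' fixture), `survival_data` (path to a `time_days`/`event` table; if given,
#' the five families are fitted and the AIC winner's shape/scale replace the
#' configured curve), `life_table` (path to an `age`/`qx` table; if given, a
#' logistic mortality curve is fitted and replaces the configured one),
#' `out_dir` (default `"."`), `seed` (default 1), `iterations` (PSA
#' iterations, default 5000), `horizon_years` (override), `wtp_grid`
#' (`c(from, to, by)` for the CEAC grid).
#'
#' @param config Named list or YAML file path.
#' @return A list with the resolved `params` and options; errors before any
#'   computation if a referenced file is missing or an override is malformed.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (key in c("params", "survival_data", "life_table")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("referenced file not found: `", key, "` = ", config[[key]], call. = FALSE)
    }
  }
  if (!is.null(config$horizon_years) &&
      (!is.numeric(config$horizon_years) || config$horizon_years <= 0)) {
    stop("`horizon_years` override must be a positive number", call. = FALSE)
  }
  params <- if (is.null(config$params)) gen_fixture() else read_parameters(config$params)
  fits <- NULL
  if (!is.null(config$survival_data)) {
    data <- read_survival_data(config$survival_data)
    fits <- fit_all_families(data)
    best <- select_best(fits)
    params <- param_set(params, "survival.family", best$family)
    params <- param_set(params, "survival.lambda", best$scale)
    params <- param_set(params, "survival.gamma", best$shape)
  }
  if (!is.null(config$life_table)) {
    lt <- read_life_table(config$life_table)
    lm <- fit_logistic_mortality(lt)
    params <- param_set(params, "mortality.L", lm$L)
    params <- param_set(params, "mortality.k", lm$k)
    params <- param_set(params, "mortality.a0", lm$a0)
  }
  if (!is.null(config$horizon_years)) {
    params <- param_set(params, "settings.horizon_years", config$horizon_years)
  }
  list(
    params = validate_parameters(params),
    fits = fits,
    out_dir = if (is.null(config$out_dir)) "." else config$out_dir,
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    iterations = if (is.null(config$iterations)) 5000L else as.integer(config$iterations),
    wtp_grid = if (is.null(config$wtp_grid)) seq(0, 300000, by = 1000) else
      seq(config$wtp_grid[1], config$wtp_grid[2], by = config$wtp_grid[3])
  )
}

#' Run the base-case analysis and write its report files
#'
#' Orchestrates (optional) survival fitting, the two cohort traces, and the
#' discounted cost/QALY comparison. Writes `trace_degarelix.tsv`,
#' `trace_leuprorelin.tsv`, `result.tsv` (a base-case results table) and
#' `result.txt` (a key-value record), each stamped with the tool version,
#' seed and a hash of the resolved parameter set.
#'
#' @param config Run configuration (see [resolve_config()]).
#' @return The `economic_result`, invisibly.
#' @export
run_base_case <- function(config = list()) {
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- cfg$params
  message("resolved ", length(param_paths(params)), " parameters (md5 ",
          param_hash(params), ")")
  res <- run_cea(params)
  traces <- attr(res, "traces")
  for (arm in names(traces)) {
    write_trace(traces[[arm]], file.path(cfg$out_dir, paste0("trace_", arm, ".tsv")),
                header_lines = output_header(params, cfg$seed))
  }
  if (!is.null(cfg$fits)) {
    write_report_table(fit_report(cfg$fits),
                       file.path(cfg$out_dir, "survival_fits.tsv"),
                       params, cfg$seed)
  }
  write_report_table(result_table(res), file.path(cfg$out_dir, "result.tsv"),
                     params, cfg$seed)
  kv <- c(
    sprintf("cost_degarelix=%.2f", res$arm_a$cost),
    sprintf("cost_leuprorelin=%.2f", res$arm_b$cost),
    sprintf("qalys_degarelix=%.3f", res$arm_a$qalys),
    sprintf("qalys_leuprorelin=%.3f", res$arm_b$qalys),
    sprintf("delta_cost=%.2f", res$delta_cost),
    sprintf("delta_qalys=%.3f", res$delta_qalys),
    sprintf("icer=%s", if (res$icer_label == "defined") sprintf("%.0f", res$icer) else res$icer_label),
    sprintf("inb=%.0f", res$inb),
    sprintf("wtp=%.0f", res$wtp)
  )
  writeLines(c(paste0("# ", output_header(params, cfg$seed)), kv),
             file.path(cfg$out_dir, "result.txt"))
  invisible(res)
}

#' Run a sensitivity or simulation suite and write its report files
#'
#' Dispatches to the sensitivity-analysis battery or the synthetic-data
#' generators:
#' * `"owsa"` writes `tornado.tsv` (sorted by descending ICER range);
#' * `"psa"` writes `ce_plane.tsv` and `ceac.tsv` (honours `seed` and
#'   `iterations`);
#' * `"scenarios"` writes `scenarios.tsv` with the three standard scenarios
#'   (maintenance-price threshold at 1x GDP, 10-year horizon, double-dose
#'   comparator) plus any configured `scenarios` edits;
#' * `"simulate"` writes `synthetic_survival.tsv` and
#'   `synthetic_life_table.tsv` from the generators.
#'
#' @param config Run configuration (see [resolve_config()]).
#' @param which One of `"owsa"`, `"psa"`, `"scenarios"`, `"simulate"`.
#' @return The suite's main object, invisibly.
#' @export
run_suite <- function(config = list(), which = c("owsa", "psa", "scenarios", "simulate")) {
  which <- match.arg(which)
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- cfg$params
  out <- switch(which,
    owsa = {
      tor <- one_way(params)
      write_report_table(tor, file.path(cfg$out_dir, "tornado.tsv"), params, cfg$seed)
      tor
    },
    psa = {
      ps <- psa(params, n_iter = cfg$iterations, seed = cfg$seed,
                wtp_grid = cfg$wtp_grid)
      write_report_table(ps$samples, file.path(cfg$out_dir, "ce_plane.tsv"),
                         params, cfg$seed)
      write_report_table(ps$ceac, file.path(cfg$out_dir, "ceac.tsv"),
                         params, cfg$seed)
      ps
    },
    scenarios = {
      gdp <- params$economics$gdp_per_capita
      thr <- threshold_price(params, "prices.degarelix_maintenance", gdp)
      scens <- list(
        maintenance_price_at_1x_gdp = list(prices.degarelix_maintenance = thr$price),
        horizon_10_years = list(settings.horizon_years = 10),
        double_dose_comparator = list(
          prices.leuprorelin_per_cycle = 2 * params$prices$leuprorelin_per_cycle)
      )
      rows <- lapply(names(scens), function(nm) {
        r <- scenario_run(params, scens[[nm]])
        cbind(scenario = nm, result_table(r)[1, c("total_cost", "qalys",
                                                  "incremental_qalys", "icer", "inb")])
      })
      tab <- do.call(rbind, rows)
      write_report_table(tab, file.path(cfg$out_dir, "scenarios.tsv"), params, cfg$seed)
      tab
    },
    simulate = {
      sv <- params$survival
      d <- gen_survival(1000, family = sv$family, lambda = sv$lambda,
                        gamma = sv$gamma, hr = sv$hr_psa_recurrence,
                        seed = cfg$seed)
      tab <- rbind(cbind(arm = "reference", d$reference),
                   cbind(arm = "treated", d$treated))
      write_report_table(tab, file.path(cfg$out_dir, "synthetic_survival.tsv"),
                         params, cfg$seed)
      lt <- gen_life_table(params$mortality$L, params$mortality$k, params$mortality$a0)
      write_report_table(as.data.frame(lt),
                         file.path(cfg$out_dir, "synthetic_life_table.tsv"),
                         params, cfg$seed)
      d
    }
  )
  invisible(out)
}
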