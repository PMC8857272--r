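# cli_reporting: configuration-driven pipeline runner. A YAML config drives
# cohort generation (or CSV ingestion), optional parameter fitting, a list of
# scenarios, and CSV reports with full provenance (seed + config hash in
# every output header).

#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML with the blocks:
#' \preformatted{
#' seed: 1                      # mandatory
#' output: out/                 # output directory
#' cohort:
#'   source: profile            # "profile" or "csv"
#'   n_patients: 500
#'   noise_sd: 5                # observation noise when generating
#'   csv_dir: path/             # when source: csv
#' params:
#'   source: default            # "default", "json" or "fit"
#'   json: params.json          # when source: json
#' scenarios:                   # at least one
#'   - kind: no_treatment
#'   - kind: as_observed
#'   - kind: capped_delay
#'     options: {max_delay: 14}
#' delay_loss:
#'   grid: [0, 14, 28, 56]      # optional delay-loss curve
#' report:
#'   bin_width: 30.4375
#'   pi_level: 0.95
#'   clip: false
#' }
#'
#' @param path Path to a YAML file, or a pre-parsed list.
#' @return A validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) .stopf("config file not found: %s", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else .stopf("`path` must be a file path or a list")
  if (is.null(cfg$seed)) .stopf("config must set `seed`")
  .assert_number(cfg$seed, "seed")
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    .stopf("config must list at least one scenario")
  cfg$output <- cfg$output %||% "namdsim-out"
  cohort <- utils::modifyList(
    list(source = "profile", n_patients = 500L, noise_sd = 5),
    cfg$cohort %||% list())
  if (!cohort$source %in% c("profile", "csv"))
    .stopf("cohort$source must be 'profile' or 'csv'")
  if (cohort$source == "csv" && is.null(cohort$csv_dir))
    .stopf("cohort source 'csv' requires cohort$csv_dir")
  cfg$cohort <- cohort
  par_cfg <- utils::modifyList(list(source = "default"),
                               cfg$params %||% list())
  if (!par_cfg$source %in% c("default", "json", "fit"))
    .stopf("params$source must be 'default', 'json' or 'fit'")
  if (par_cfg$source == "json" && is.null(par_cfg$json))
    .stopf("params source 'json' requires params$json")
  cfg$params <- par_cfg
  cfg$report <- utils::modifyList(
    list(bin_width = DAYS_PER_MONTH, pi_level = 0.95, clip = FALSE),
    cfg$report %||% list())
  for (sc in cfg$scenarios) {
    if (is.null(sc$kind) || !sc$kind %in% .SCENARIO_KINDS)
      .stopf("unknown or missing scenario kind: %s",
             sc$kind %||% "<missing>")
  }
  cfg
}

#' Run the full simulation/reporting pipeline
#'
#' Generates or ingests a cohort, resolves model parameters (defaults, a JSON
#' file, or a least-squares fit to the cohort observations), runs every
#' configured scenario, and writes the report bundle: per-scenario mean-curve
#' CSVs, a scenario-comparison table (mean gain at Months 3/6/12/18 with
#' intervals), an optional delay-loss CSV, pandemic loss tables when a
#' `covid_thinned` scenario is configured, a fit JSON when fitting, and a log
#' with the seed and a config echo. Every CSV carries the config hash and
#' seed in a `#` header comment. Outputs are staged in a temporary directory
#' and moved into place only on success, so a failing run leaves no partial
#' bundle.
#'
#' @param config A YAML path or config list (see [read_run_config()]).
#' @param out_dir Optional override of the configured output directory.
#' @return Invisibly, a list with `outputs` (written file paths), `results`
#'   (scenario result objects), `params`, and `cohort`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$output
  chash <- rlang::hash(cfg)
  hdr <- c(sprintf("namdsim config_hash=%s seed=%d", chash,
                   as.integer(cfg$seed)))
  stage <- file.path(tempfile("namdsim-stage"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  outputs <- character()
  logline <- character()
  log <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logline <<- c(logline, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  log("pipeline start: seed %d, config hash %s", as.integer(cfg$seed), chash)

  # cohort
  cohort <- if (cfg$cohort$source == "csv") {
    log("reading cohort from %s", cfg$cohort$csv_dir)
    read_cohort_csv(cfg$cohort$csv_dir)
  } else {
    log("generating cohort: n = %d", as.integer(cfg$cohort$n_patients))
    gen_params <- if (cfg$params$source == "fit") default_params() else NULL
    generate_cohort(n = as.integer(cfg$cohort$n_patients),
                    seed = as.integer(cfg$seed),
                    params = gen_params,
                    noise_sd = cfg$cohort$noise_sd)
  }

  # parameters
  params <- switch(cfg$params$source,
    default = default_params(),
    json = read_params_json(cfg$params$json),
    fit = {
      if (is.null(cohort$observations))
        .stopf("params source 'fit' requires cohort observations")
      log("fitting parameters to %d observations",
          nrow(cohort$observations))
      fit <- fit_parameters(cohort$patients, cohort$schedules,
                            cohort$observations,
                            config = list(seed = as.integer(cfg$seed)))
      write_fit_json(fit, file.path(stage, "fit.json"))
      outputs <- c(outputs, "fit.json")
      fit$params
    })

  # scenarios
  results <- list()
  comparison <- list()
  months_at <- c(3, 6, 12, 18)
  for (k in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[[k]]
    spec <- scenario_spec(sc$kind,
                          window_end = sc$window_end %||%
                            (18 * DAYS_PER_MONTH),
                          options = sc$options %||% list())
    log("running scenario '%s'", sc$kind)
    res <- run_scenario(cohort, spec, params, seed = as.integer(cfg$seed),
                        bin_width = cfg$report$bin_width)
    results[[sc$kind]] <- res
    if (inherits(res, "covid_result")) {
      .write_csv_exact(res$per_patient, file.path(stage, "covid_per_patient.csv"),
                       hdr)
      .write_csv_exact(res$strata, file.path(stage, "covid_strata.csv"), hdr)
      outputs <- c(outputs, "covid_per_patient.csv", "covid_strata.csv")
      log("covid scenario: mean loss %.3f letters", res$mean_loss)
      next
    }
    fn <- sprintf("scenario_%s.csv", sc$kind)
    mc <- res$mean_curve
    if (cfg$report$clip) {
      # clip only exported values, never the model state
      mc$mean_gain <- pmin(pmax(mc$mean_gain, -100), 100)
    }
    .write_csv_exact(mc, file.path(stage, fn), hdr)
    outputs <- c(outputs, fn)
    row <- data.frame(scenario = sc$kind)
    for (m in months_at) {
      i <- which.min(abs(mc$time_days - m * DAYS_PER_MONTH))
      row[[sprintf("gain_m%02d", m)]] <- mc$mean_gain[i]
      row[[sprintf("lo_m%02d", m)]] <- mc$pi_low[i]
      row[[sprintf("hi_m%02d", m)]] <- mc$pi_high[i]
    }
    comparison[[sc$kind]] <- row
  }
  if (length(comparison)) {
    .write_csv_exact(do.call(rbind, comparison),
                     file.path(stage, "comparison.csv"), hdr)
    outputs <- c(outputs, "comparison.csv")
  }

  # optional delay-loss curve
  if (!is.null(cfg$delay_loss$grid)) {
    log("computing delay-loss curve over %d grid points",
        length(cfg$delay_loss$grid))
    dl <- delay_loss_curve(cohort, params,
                           as.numeric(cfg$delay_loss$grid))
    .write_csv_exact(dl, file.path(stage, "delay_loss.csv"), hdr)
    outputs <- c(outputs, "delay_loss.csv")
  }

  writeLines(c(paste0("# ", hdr),
               sprintf("seed: %d", as.integer(cfg$seed)),
               "config:", yaml::as.yaml(cfg), "", logline),
             file.path(stage, "log.txt"))
  outputs <- c(outputs, "log.txt")

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in outputs)
    file.copy(file.path(stage, f), file.path(out_dir, f), overwrite = TRUE)
  log("wrote %d files to %s", length(outputs), out_dir)
  invisible(list(outputs = file.path(out_dir, outputs), results = results,
                 params = params, cohort = cohort))
}
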