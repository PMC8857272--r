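# scenarios: declarative counterfactual transformations of injection
# schedules and the scenario runner. In every cohort-based scenario the
# number of patients, their baseline covariates and their observation
# windows are kept fixed; only the injection timing changes.

.SCENARIO_KINDS <- c("as_observed", "no_treatment", "fixed_3l_q8w",
                     "zero_delay", "capped_delay", "loading_redistributed",
                     "no_loading_redistributed", "covid_thinned",
                     "harbor_style")

#' Declare a counterfactual treatment scenario
#'
#' @param kind One of `"as_observed"`, `"no_treatment"`, `"fixed_3l_q8w"`,
#'   `"zero_delay"`, `"capped_delay"`, `"loading_redistributed"`,
#'   `"no_loading_redistributed"`, `"covid_thinned"`, `"harbor_style"`.
#' @param window_end Scenario window in days (default Month 18).
#' @param options Kind-specific settings: `max_delay` (capped_delay, default
#'   14), `dose` (fixed_3l_q8w), `loading_sigma`/`maint_sigma`
#'   (loading_redistributed, defaults 4/7), `n`/`series`/`start_date`/
#'   `end_date` (covid_thinned), `n` (harbor_style, default 275).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind, window_end = 18 * DAYS_PER_MONTH,
                          options = list()) {
  kind <- match.arg(kind, .SCENARIO_KINDS)
  .assert_number(window_end, "window_end", lower = 0,
                 allow_equal_lower = FALSE)
  structure(list(kind = kind, window_end = window_end, options = options),
            class = "scenario_spec")
}

# transform one patient's schedule according to the spec
.transform_schedule <- function(schedule, patient, spec) {
  opt <- spec$options
  switch(spec$kind,
    as_observed = schedule,
    no_treatment = injection_schedule(),
    fixed_3l_q8w = make_3l_q8w_schedule(spec$window_end,
                                        opt$dose %||% 0.5),
    zero_delay = if (nrow(schedule))
      shift_delay(schedule, patient$delay_days, 0) else schedule,
    capped_delay = if (nrow(schedule))
      shift_delay(schedule, patient$delay_days, opt$max_delay %||% 14)
      else schedule,
    loading_redistributed = if (nrow(schedule))
      redistribute_with_loading(schedule, spec$window_end,
                                opt$loading_sigma %||% 4,
                                opt$maint_sigma %||% 7) else schedule,
    no_loading_redistributed = if (nrow(schedule))
      redistribute_without_loading(schedule, spec$window_end)
      else schedule,
    .stopf("scenario kind '%s' is not schedule-transforming", spec$kind))
}

#' Run a treatment scenario over a cohort
#'
#' Transforms each patient's injection schedule according to the scenario,
#' simulates every patient to `min(obs_end, window_end)`, and aggregates the
#' mean VA-gain curve. Cohort identity (n, baselines, observation windows) is
#' never altered, except by `harbor_style` and `covid_thinned`, which define
#' their own populations (`covid_thinned` is dispatched to
#' [run_covid_scenario()] and returns its richer result object).
#'
#' @param cohort A `va_cohort` (or list with `patients` and `schedules`).
#' @param spec A [scenario_spec()].
#' @param params A `va_params` object.
#' @param seed Integer seed for the stochastic scenarios (jittered
#'   redistribution, harbor draws, covid thinning).
#' @param h Integrator sub-step (days).
#' @param bin_width Curve bin width in days.
#' @return An object of class `scenario_result`: list with `spec`,
#'   `mean_curve`, `end_va` (data frame `patient_id`, `time_days`,
#'   `va_letters` at each patient's scenario end), `seed`, `n`.
#' @export
run_scenario <- function(cohort, spec, params = default_params(), seed = 1,
                         h = 0.25, bin_width = DAYS_PER_MONTH) {
  if (!inherits(spec, "scenario_spec")) .stopf("`spec` must be a scenario_spec")
  validate_params(params)
  set.seed(seed)
  if (spec$kind == "covid_thinned") {
    opt <- spec$options
    return(run_covid_scenario(
      params = params,
      profile = opt$profile %||% cohort_profile(),
      series = opt$series %||% make_covid_rate_series(),
      n = opt$n %||% 4500,
      start_date = as.Date(opt$start_date %||% "2019-09-01"),
      end_date = as.Date(opt$end_date %||% "2021-03-01"),
      seed = seed, h = h))
  }
  if (spec$kind == "harbor_style") {
    cohort <- .harbor_cohort(spec$options$n %||% 275L)
    spec2 <- scenario_spec("as_observed",
                           window_end = min(spec$window_end,
                                            12 * DAYS_PER_MONTH))
    spec2$options <- spec$options
    spec <- spec2
  }
  patients <- cohort$patients
  validate_patients(patients)
  n <- nrow(patients)
  traj <- vector("list", n)
  end_va <- numeric(n)
  end_t <- numeric(n)
  for (i in seq_len(n)) {
    pat <- patients[i, ]
    sch <- .transform_schedule(.schedule_of(cohort$schedules,
                                            pat$patient_id), pat, spec)
    tend <- min(pat$obs_end_days, spec$window_end)
    et <- sort(unique(c(seq(0, tend, by = bin_width), tend)))
    tr <- simulate_trajectory(pat, sch, params, et, h = h)
    traj[[i]] <- tr
    end_va[i] <- tr$va_letters[nrow(tr)]
    end_t[i] <- tend
  }
  sim <- do.call(rbind, traj)
  mc <- mean_curve_with_pi(sim, patients, bin_width)
  structure(list(spec = spec, mean_curve = mc,
                 end_va = data.frame(patient_id = patients$patient_id,
                                     time_days = end_t,
                                     va_letters = end_va,
                                     stringsAsFactors = FALSE),
                 seed = seed, n = n),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' over %d patients (seed %d)\n",
              x$spec$kind, x$n, x$seed))
  cat(sprintf("  mean end-of-window VA: %.2f letters\n",
              mean(x$end_va$va_letters)))
  invisible(x)
}

# validation-arm population: age and baseline VA drawn from normal
# distributions with the published trial demographics, treatment-naive,
# 3 q4w loading + q8w maintenance to Month 12 at 0.5 mg
.harbor_cohort <- function(n = 275L) {
  age <- pmax(stats::rnorm(n, 78.8, 8.4), 50)
  va <- pmin(pmax(stats::rnorm(n, 54.2, 13.3), 0), 100)
  patients <- data.frame(patient_id = sprintf("H%05d", seq_len(n)),
                         age = age, baseline_va = va,
                         pretreatment = "naive", delay_days = 0,
                         obs_end_days = 12 * DAYS_PER_MONTH,
                         stringsAsFactors = FALSE)
  sch <- make_3l_q8w_schedule(12 * DAYS_PER_MONTH, dose = 0.5)
  schedules <- do.call(rbind, lapply(patients$patient_id, function(id)
    cbind(patient_id = id, sch, stringsAsFactors = FALSE)))
  list(patients = patients, schedules = schedules)
}

#' Mean VA loss at Month 18 as a function of treatment delay
#'
#' For each delay `d` on the grid, every patient's schedule is shifted so the
#' first injection falls at day `d` (inter-injection gaps preserved), the
#' cohort is simulated to Month 18 (or the individual observation end, if
#' earlier), and the loss relative to the zero-delay arm is reported as a
#' positive number with a 95% interval for the mean. Patients without any
#' injection are excluded (no delay is defined for them).
#'
#' @param cohort A `va_cohort`.
#' @param params A `va_params` object.
#' @param delay_grid Non-negative delays in days.
#' @param window_end Evaluation window (days, default Month 18).
#' @param h Integrator sub-step (days).
#' @return Data frame `delay_days`, `mean_loss`, `pi_low`, `pi_high`, `n`.
#' @export
delay_loss_curve <- function(cohort, params, delay_grid,
                             window_end = 18 * DAYS_PER_MONTH, h = 0.25) {
  if (any(delay_grid < 0)) .stopf("delays must be >= 0")
  validate_params(params)
  patients <- cohort$patients
  has_inj <- patients$patient_id %in% cohort$schedules$patient_id
  patients <- patients[has_inj, , drop = FALSE]
  n <- nrow(patients)
  if (!n) .stopf("no treated patients in the cohort")
  end_va_at <- function(d) {
    vapply(seq_len(n), function(i) {
      pat <- patients[i, ]
      sch <- .schedule_of(cohort$schedules, pat$patient_id)
      sch$time_days <- sch$time_days + (d - sch$time_days[1L])
      tend <- min(pat$obs_end_days, window_end)
      simulate_trajectory(pat, sch, params, c(0, tend),
                          h = h)$va_letters[2L]
    }, numeric(1L))
  }
  ref <- end_va_at(0)
  z <- stats::qnorm(0.975)
  rows <- lapply(delay_grid, function(d) {
    loss <- ref - end_va_at(d)
    half <- z * stats::sd(loss) / sqrt(n)
    data.frame(delay_days = d, mean_loss = mean(loss),
               pi_low = mean(loss) - half, pi_high = mean(loss) + half,
               n = n)
  })
  do.call(rbind, rows)
}
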