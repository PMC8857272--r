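# Pandemic missed-injection machinery: a weekly injection-rate series turns
# into a per-injection probability of actually being performed,
# P(inj | t) = min(N_performed(week t) / N_reference, 1),
# and each scheduled injection is kept or dropped by an independent
# Bernoulli draw at that probability.

#' Build a synthetic weekly injection-rate series
#'
#' A weekly series at parity (performed = reference) except during
#' user-defined "wave" intervals where the performed fraction dips. The
#' default emulates the qualitative pandemic pattern: a shallower but longer
#' first wave and a deeper, shorter second wave.
#'
#' @param start,end Coverage dates (anything `as.Date` accepts).
#' @param waves List of waves, each a list with `start` (date), `weeks`
#'   (duration) and `level` (performed fraction in \[0, 1\]). Waves must not
#'   overlap.
#' @param reference Pre-pandemic weekly injection count (any positive scale;
#'   only the ratio matters).
#' @return Data frame `week_start` (Date), `performed`, `reference`.
#' @examples
#' s <- make_covid_rate_series()
#' range(s$performed / s$reference)
#' @export
make_covid_rate_series <- function(start = "2019-09-01",
                                   end = "2021-03-01",
                                   waves = list(
                                     list(start = "2020-03-09", weeks = 12,
                                          level = 0.75),
                                     list(start = "2020-12-07", weeks = 6,
                                          level = 0.50)),
                                   reference = 10000) {
  start <- as.Date(start); end <- as.Date(end)
  .assert_number(reference, "reference", lower = 0, allow_equal_lower = FALSE)
  week_start <- seq(start, end + 6, by = "7 days")
  performed <- rep(reference, length(week_start))
  ivals <- lapply(waves, function(w) {
    if (w$level < 0 || w$level > 1) .stopf("wave levels must lie in [0, 1]")
    ws <- as.Date(w$start)
    c(as.numeric(ws), as.numeric(ws + 7 * w$weeks))
  })
  if (length(ivals) > 1L) {
    m <- do.call(rbind, ivals)
    o <- order(m[, 1L])
    if (any(m[o, 1L][-1L] < m[o, 2L][-nrow(m)]))
      .stopf("wave intervals overlap")
  }
  for (k in seq_along(waves)) {
    inside <- as.numeric(week_start) >= ivals[[k]][1L] &
      as.numeric(week_start) < ivals[[k]][2L]
    performed[inside] <- waves[[k]]$level * reference
  }
  data.frame(week_start = week_start, performed = performed,
             reference = reference)
}

#' Probability that an injection is performed in a given week
#'
#' `P(inj | t) = min(performed_in_week(t) / reference, 1)`.
#'
#' @param series A rate series (see [make_covid_rate_series()]), with
#'   columns `week_start`, `performed`, `reference`.
#' @param t Calendar date(s) (anything `as.Date` accepts).
#' @return Numeric vector of probabilities; errors if `t` falls outside the
#'   series coverage.
#' @export
covid_injection_probability <- function(series, t) {
  t <- as.Date(t)
  ws <- as.Date(series$week_start)
  i <- findInterval(as.numeric(t), as.numeric(ws))
  if (any(i == 0L) || any(as.numeric(t) >= as.numeric(ws[length(ws)]) + 7))
    .stopf("date outside the rate-series coverage (%s to %s)",
           min(ws), max(ws) + 6)
  pmin(series$performed[i] / series$reference[i], 1)
}

#' Thin an injection schedule by pandemic-week probabilities
#'
#' Each scheduled injection is independently kept with the probability of its
#' calendar week; missed injections are removed (not rescheduled) by default.
#' `mode = "postpone"` instead delays each missed injection by
#' `postpone_days` (a sensitivity-analysis variant). Uses the current RNG
#' state.
#'
#' @param schedule An injection schedule (times in days from baseline).
#' @param baseline_date The patient's baseline calendar date.
#' @param series A rate series covering all injection dates.
#' @param mode `"drop"` (default) or `"postpone"`.
#' @param postpone_days Shift applied to missed injections when
#'   `mode = "postpone"`.
#' @return The thinned schedule, with an attribute `missed_times` holding
#'   the original times (days) of the injections that were missed.
#' @export
apply_covid_thinning <- function(schedule, baseline_date, series,
                                 mode = c("drop", "postpone"),
                                 postpone_days = 28) {
  mode <- match.arg(mode)
  validate_schedule(schedule)
  if (!nrow(schedule)) {
    attr(schedule, "missed_times") <- numeric()
    return(schedule)
  }
  dates <- as.Date(baseline_date) + schedule$time_days
  p <- covid_injection_probability(series, dates)
  keep <- stats::runif(nrow(schedule)) < p
  missed <- schedule$time_days[!keep]
  if (mode == "drop") {
    out <- schedule[keep, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    tt <- schedule$time_days
    tt[!keep] <- tt[!keep] + postpone_days
    out <- injection_schedule(.sanitize_times(tt), schedule$dose_mg)
  }
  attr(out, "missed_times") <- missed
  out
}

#' Simulate the population impact of pandemic missed injections
#'
#' Builds a treatment-naive population with baseline VA and age drawn from
#' the cohort profile, baseline dates uniform over `[start_date, end_date]`,
#' real-world injection patterns from the cohort generator, and compares each
#' patient's VA at `end_date` under the full versus the thinned schedule.
#' Loss is reported positive (full minus thinned). Patients are stratified by
#' the number of missed injections and by whether a missed injection fell
#' within `early_window` days of the (scheduled) treatment start.
#'
#' @param params A `va_params` object.
#' @param profile A [cohort_profile()] for baselines and injection patterns.
#' @param series A rate series (see [make_covid_rate_series()]).
#' @param n Population size (default 4500, a 1% desk-scale stand-in for a
#'   national population of 450,000; configurable).
#' @param start_date,end_date Baseline-assignment window / simulation end.
#' @param seed Integer seed.
#' @param early_window Days after treatment start defining an "early" miss
#'   (default 30).
#' @param mode Passed to [apply_covid_thinning()].
#' @param h Integrator sub-step (days).
#' @return An object of class `covid_result`: list with `per_patient` (data
#'   frame: id, baseline date, window, scheduled/missed counts, early-miss
#'   flag, end VA under both arms, `loss`), `strata` (mean loss by missed
#'   count and early-miss flag), `mean_loss` (all patients),
#'   `mean_loss_missed` (patients with >= 1 miss), `seed`.
#' @export
run_covid_scenario <- function(params = default_params(),
                               profile = cohort_profile(),
                               series = make_covid_rate_series(),
                               n = 4500, seed = 1,
                               start_date = as.Date("2019-09-01"),
                               end_date = as.Date("2021-03-01"),
                               early_window = 30,
                               mode = c("drop", "postpone"), h = 0.25) {
  mode <- match.arg(mode)
  validate_params(params)
  set.seed(seed)
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  span <- as.numeric(end_date - start_date)
  tn_va <- .truncnorm_match(profile$baseline_va$mean, profile$baseline_va$sd,
                            profile$baseline_va$lower,
                            profile$baseline_va$upper)
  tn_age <- .truncnorm_match(profile$age$mean, profile$age$sd,
                             profile$age$lower, profile$age$upper)
  dd <- calibrate_delay_distribution(profile$delay)
  va0 <- .truncnorm_sample(tn_va, n)
  age <- .truncnorm_sample(tn_age, n)
  delay <- sample_delays(dd, n)
  bl_offset <- stats::runif(n, 0, span)
  window <- span - bl_offset

  per <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- list(patient_id = sprintf("C%05d", i), age = age[i],
                baseline_va = va0[i], pretreatment = "naive",
                delay_days = delay[i], obs_end_days = max(window[i], 1e-3))
    sch <- sample_injection_pattern(pat, profile)
    bl_date <- start_date + bl_offset[i]
    thin <- apply_covid_thinning(sch, bl_date, series, mode = mode)
    missed <- attr(thin, "missed_times")
    tend <- pat$obs_end_days
    va_full <- simulate_trajectory(pat, sch, params, c(0, tend),
                                   h = h)$va_letters[2L]
    va_thin <- if (length(missed) || mode == "postpone")
      simulate_trajectory(pat, thin, params, c(0, tend),
                          h = h)$va_letters[2L] else va_full
    t_start <- if (nrow(sch)) sch$time_days[1L] else NA_real_
    per[[i]] <- data.frame(
      patient_id = pat$patient_id,
      baseline_date = bl_date, window_days = window[i],
      n_scheduled = nrow(sch), n_missed = length(missed),
      early_miss = length(missed) > 0 &&
        any(missed - t_start <= early_window),
      va_full = va_full, va_thinned = va_thin,
      loss = va_full - va_thin, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  strat <- do.call(rbind, lapply(1:2, function(k) {
    do.call(rbind, lapply(c(FALSE, TRUE), function(e) {
      sel <- per$n_missed == k & per$early_miss == e
      data.frame(n_missed = k, early_miss = e, n = sum(sel),
                 mean_loss = if (any(sel)) mean(per$loss[sel]) else NA_real_)
    }))
  }))
  structure(list(per_patient = per, strata = strat,
                 mean_loss = mean(per$loss),
                 mean_loss_missed = if (any(per$n_missed > 0))
                   mean(per$loss[per$n_missed > 0]) else NA_real_,
                 series = series, seed = seed, n = n),
            class = "covid_result")
}

#' @export
print.covid_result <- function(x, ...) {
  cat(sprintf("Pandemic missed-injection scenario: %d patients (seed %d)\n",
              x$n, x$seed))
  cat(sprintf("  mean VA loss: %.2f letters (all), %.2f (>=1 missed; %.1f%% affected)\n",
              x$mean_loss, x$mean_loss_missed,
              100 * mean(x$per_patient$n_missed > 0)))
  print(x$strata, row.names = FALSE)
  invisible(x)
}
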