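# model_core: deterministic simulation of one patient's VA trajectory under
# an arbitrary intravitreal injection schedule.
#
# The state equation is linear in VA,
#   dg/dt = k_in * (1 + Emax(t) * C(t) / (ec50 + C(t))) - k_out * g,
# with piecewise-smooth forcing (C jumps at injection times, is smooth in
# between). The default integrator exploits this: an exponential
# time-differencing step that treats the linear decay exactly and the smooth
# Hill forcing by its midpoint value, with every injection time a mandatory
# grid node. For an empty schedule the scheme reproduces the closed-form
# solution to machine precision. An adaptive `deSolve::lsoda` path is kept as
# an independent cross-check (`method = "lsoda"`).

#' Construct an injection schedule
#'
#' An injection schedule is a data frame with columns `time_days` (days from
#' baseline, strictly increasing, >= 0) and `dose_mg` (> 0). It may have zero
#' rows (no-treatment).
#'
#' @param time_days Numeric vector of injection times (days from baseline).
#' @param dose_mg Numeric vector (or scalar, recycled) of doses in mg.
#' @return A validated schedule data frame.
#' @examples
#' injection_schedule(c(0, 28, 56), 0.5)
#' @export
injection_schedule <- function(time_days = numeric(), dose_mg = numeric()) {
  if (length(dose_mg) == 1L && length(time_days) > 1L)
    dose_mg <- rep(dose_mg, length(time_days))
  s <- data.frame(time_days = as.numeric(time_days),
                  dose_mg = as.numeric(dose_mg))
  validate_schedule(s)
  s
}

#' @rdname injection_schedule
#' @param schedule A schedule data frame to validate.
#' @export
validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule) ||
      !all(c("time_days", "dose_mg") %in% names(schedule)))
    .stopf("a schedule must be a data frame with columns time_days, dose_mg")
  t <- schedule$time_days
  if (length(t)) {
    if (anyNA(t) || any(!is.finite(t)) || any(t < 0))
      .stopf("schedule times must be finite and >= 0")
    if (any(diff(t) <= 0))
      .stopf("schedule times must be strictly increasing")
    if (anyNA(schedule$dose_mg) || any(schedule$dose_mg <= 0))
      .stopf("schedule doses must be > 0")
  }
  invisible(schedule)
}

#' Vitreous drug amount under bolus injections with first-order elimination
#'
#' Each injection adds its dose instantaneously; the total drug amount decays
#' with rate `k_drug` (superposition of exponentials):
#' `C(t) = sum over events with time <= t of dose * exp(-k_drug * (t - time))`.
#' Before the first injection the concentration is 0. Units are dose units
#' (mg); no vitreous volume is applied (see [va_params()]).
#'
#' @param schedule An injection schedule (see [injection_schedule()]).
#' @param t Numeric vector of query times (days, >= 0).
#' @param k_drug Elimination rate constant (1/day).
#' @return Numeric vector of drug amounts at `t`.
#' @examples
#' s <- injection_schedule(0, 0.5)
#' vitreous_concentration(s, log(2) / (log(2) / 9), log(2) / 9) # one half-life
#' @export
vitreous_concentration <- function(schedule, t, k_drug) {
  validate_schedule(schedule)
  .assert_number(k_drug, "k_drug", lower = 0, allow_equal_lower = FALSE)
  if (anyNA(t) || any(t < 0)) .stopf("query times must be >= 0")
  .conc(schedule$time_days, schedule$dose_mg, t, k_drug)
}

# vectorised concentration kernel (no validation)
.conc <- function(ev_times, ev_doses, t, k_drug) {
  if (!length(ev_times)) return(rep(0, length(t)))
  dt <- outer(t, ev_times, "-")
  w <- exp(-k_drug * pmax(dt, 0))
  w[dt < 0] <- 0
  as.vector(w %*% ev_doses)
}

#' Maximal drug effect as a function of time, age and pre-treatment status
#'
#' `Emax(t) = Emax_ss(age) + alpha * d_emax0 * exp(-k_emax * t)` with
#' `log(Emax_ss) = log(emax0_ss) + beta * log(age / 77)`. The clock `t` is
#' time after baseline (diagnosis), not after the first injection: the
#' transient extra effect is a property of early disease, which is how a
#' treatment delay erodes achievable benefit.
#'
#' @param t Time after baseline (days, >= 0); vectorised.
#' @param params A `va_params` object.
#' @param age Patient age in years (> 0).
#' @param alpha Pre-treatment scaling (see [alpha_for()]).
#' @return Numeric vector of Emax values.
#' @export
emax_at <- function(t, params, age, alpha) {
  validate_params(params)
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0)
    .stopf("`age` must be a single positive number")
  if (anyNA(t) || any(t < 0)) .stopf("`t` must be >= 0")
  ess <- exp(log(params$emax0_ss) + params$beta * log(age / 77))
  ess + alpha * params$d_emax0 * exp(-params$k_emax * t)
}

#' Closed-form untreated VA trajectory
#'
#' The exact solution of the no-treatment model,
#' `g(t) = g_ss + (g0 - g_ss) * exp(-k_out * t)`.
#'
#' @param g0 Baseline VA (letters).
#' @param params A `va_params` object.
#' @param t Time (days, >= 0); vectorised.
#' @return VA in letters at `t`.
#' @examples
#' no_treatment_solution(70, va_params(g_ss = 40, k_out = 0.01), 100)
#' @export
no_treatment_solution <- function(g0, params, t) {
  validate_params(params)
  if (anyNA(t) || any(t < 0)) .stopf("`t` must be >= 0")
  params$g_ss + (g0 - params$g_ss) * exp(-params$k_out * t)
}

# ---- patient representation -------------------------------------------------

#' Construct a patient baseline record
#'
#' @param patient_id Identifier (character or coercible).
#' @param age Age in years (> 0).
#' @param baseline_va Baseline VA in letters, in \[0, 100\].
#' @param pretreatment One of `"naive"`, `"pretreated"`,
#'   `"possibly_pretreated"`.
#' @param delay_days Days from baseline (diagnosis) to first injection (>= 0).
#' @param obs_end_days Days from baseline to the end of observation (> 0).
#' @return A one-row data frame (the package's patient schema).
#' @export
patient_baseline <- function(patient_id, age, baseline_va,
                             pretreatment = "naive",
                             delay_days = 0, obs_end_days = 730.5) {
  p <- data.frame(patient_id = as.character(patient_id), age = age,
                  baseline_va = baseline_va, pretreatment = pretreatment,
                  delay_days = delay_days, obs_end_days = obs_end_days,
                  stringsAsFactors = FALSE)
  validate_patients(p)
  p
}

#' @rdname patient_baseline
#' @param patients A patient data frame to validate (may have several rows).
#' @export
validate_patients <- function(patients) {
  need <- c("patient_id", "age", "baseline_va", "pretreatment",
            "delay_days", "obs_end_days")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    .stopf("patient table is missing columns: %s", paste(miss, collapse = ", "))
  with(patients, {
    if (any(!is.finite(age)) || any(age <= 0)) .stopf("ages must be > 0")
    if (any(!is.finite(baseline_va)) || any(baseline_va < 0) ||
        any(baseline_va > 100))
      .stopf("baseline VA must lie in [0, 100] letters")
    if (any(!is.finite(delay_days)) || any(delay_days < 0))
      .stopf("delays must be >= 0")
    ok_obs <- is.na(obs_end_days) | (is.finite(obs_end_days) & obs_end_days > 0)
    if (!all(ok_obs)) .stopf("obs_end_days must be > 0")
    bad <- setdiff(unique(pretreatment),
                   c("naive", "pretreated", "possibly_pretreated"))
    if (length(bad))
      .stopf("unknown pre-treatment status: %s", paste(bad, collapse = ", "))
  })
  if (anyDuplicated(patients$patient_id))
    .stopf("duplicated patient_id values")
  invisible(patients)
}

.as_patient <- function(patient) {
  if (is.data.frame(patient)) {
    if (nrow(patient) != 1L) .stopf("`patient` must be a single record")
    patient <- as.list(patient)
  }
  patient
}

# ---- integration ------------------------------------------------------------

# Precompute everything about a (schedule, eval grid) pair that does not
# depend on the disease parameters. k_drug is fixed in this model, so the
# concentration at the step midpoints can be cached too; parameter estimation
# re-uses these templates across hundreds of objective evaluations.
.sim_template <- function(schedule, eval_times, h, k_drug) {
  tmax <- max(eval_times)
  if (tmax == 0) {
    return(list(nodes = 0, mid = numeric(), dt = numeric(),
                c_mid = numeric(), idx = rep(1L, length(eval_times)),
                eval_times = eval_times))
  }
  ev <- schedule[schedule$time_days < tmax, , drop = FALSE]
  nodes <- sort(unique(c(0, eval_times, ev$time_days,
                         seq(0, tmax, by = h), tmax)))
  mid <- (nodes[-1L] + nodes[-length(nodes)]) / 2
  list(nodes = nodes,
       mid = mid,
       dt = diff(nodes),
       c_mid = .conc(ev$time_days, ev$dose_mg, mid, k_drug),
       idx = match(eval_times, nodes),
       eval_times = eval_times)
}

# Run the exponential-time-differencing integrator on a template.
.sim_run <- function(tpl, params, g0, age, alpha) {
  k <- params$k_out
  kin <- params$g_ss * k
  if (length(tpl$mid) == 0L) return(rep(g0, length(tpl$idx)))
  kt <- k * tpl$nodes
  if (max(kt) > 600)
    .stopf("k_out * horizon too large for the analytic integrator; use method = \"lsoda\"")
  ess <- exp(log(params$emax0_ss) + params$beta * log(age / 77))
  em <- ess + alpha * params$d_emax0 * exp(-params$k_emax * tpl$mid)
  f <- em * tpl$c_mid / (params$ec50 + tpl$c_mid)
  a <- kin * (1 + f)
  ekt <- exp(kt)
  inc <- (a / k) * diff(ekt)
  g <- (g0 + c(0, cumsum(inc))) / ekt
  g[tpl$idx]
}

.sim_lsoda <- function(schedule, params, g0, age, alpha, eval_times,
                       rtol, atol) {
  tmax <- max(eval_times)
  ev <- schedule[schedule$time_days < tmax, , drop = FALSE]
  bp <- sort(unique(c(0, ev$time_days[ev$time_days > 0], tmax)))
  out_t <- sort(unique(c(eval_times, bp)))
  rhs <- function(t, y, parms) {
    cc <- .conc(ev$time_days, ev$dose_mg, t, params$k_drug)
    ess <- exp(log(params$emax0_ss) + params$beta * log(age / 77))
    em <- ess + alpha * params$d_emax0 * exp(-params$k_emax * t)
    list(params$g_ss * params$k_out *
           (1 + em * cc / (params$ec50 + cc)) - params$k_out * y)
  }
  va <- numeric(length(out_t))
  va[out_t == 0] <- g0
  y <- g0
  # integrate segment by segment so the forcing discontinuities at injection
  # times are never stepped over
  for (i in seq_len(length(bp) - 1L)) {
    seg <- out_t[out_t >= bp[i] & out_t <= bp[i + 1L]]
    seg <- sort(unique(c(bp[i], seg, bp[i + 1L])))
    sol <- deSolve::lsoda(y = c(g = y), times = seg, func = rhs,
                          rtol = rtol, atol = atol)
    va[match(seg, out_t)] <- sol[, "g"]
    y <- unname(sol[nrow(sol), "g"])
  }
  va[match(eval_times, out_t)]
}

#' Simulate one patient's VA trajectory under an injection schedule
#'
#' Integrates the indirect-response model from `g(0) = baseline_va` with the
#' drug forcing given by the schedule. Injection times are always integration
#' breakpoints, so the discontinuous concentration is never stepped over.
#'
#' The default `method = "analytic"` is an exponential time-differencing
#' scheme (exact treatment of the linear decay, midpoint rule for the smooth
#' Hill forcing within each sub-step of at most `h` days). With an empty
#' schedule it reproduces [no_treatment_solution()] to machine precision.
#' `method = "lsoda"` uses the adaptive solver from \pkg{deSolve} and serves
#' as an independent numerical cross-check.
#'
#' @param patient A single patient record (see [patient_baseline()]).
#' @param schedule An injection schedule (possibly empty).
#' @param params A `va_params` object.
#' @param eval_times Sorted, non-negative times (days) at which to report VA;
#'   must not exceed the patient's `obs_end_days` (when present).
#' @param method `"analytic"` (default) or `"lsoda"`.
#' @param h Maximum sub-step (days) for the analytic method.
#' @param clip If `TRUE`, clip reported VA to \[0, 100\] letters (the model
#'   itself is never clamped; default `FALSE`).
#' @param rtol,atol Tolerances for `method = "lsoda"`.
#' @return A data frame with columns `patient_id`, `time_days`, `va_letters`.
#' @examples
#' pat <- patient_baseline("P1", age = 77, baseline_va = 52)
#' sch <- make_3l_q8w_schedule()
#' tr <- simulate_trajectory(pat, sch, default_params(), seq(0, 540, by = 30))
#' head(tr)
#' @export
simulate_trajectory <- function(patient, schedule, params, eval_times,
                                method = c("analytic", "lsoda"),
                                h = 0.25, clip = FALSE,
                                rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  validate_params(params)
  validate_schedule(schedule)
  patient <- .as_patient(patient)
  if (anyNA(eval_times) || is.unsorted(eval_times) || any(eval_times < 0))
    .stopf("`eval_times` must be sorted, finite and >= 0")
  if (!is.null(patient$obs_end_days) && !is.na(patient$obs_end_days) &&
      max(eval_times) > patient$obs_end_days + 1e-9)
    .stopf("eval_times exceed obs_end_days for patient %s", patient$patient_id)
  g0 <- patient$baseline_va
  alpha <- alpha_for(params, patient$pretreatment %||% "naive")
  va <- tryCatch({
    if (method == "analytic") {
      tpl <- .sim_template(schedule, eval_times, h, params$k_drug)
      .sim_run(tpl, params, g0, patient$age, alpha)
    } else {
      .sim_lsoda(schedule, params, g0, patient$age, alpha, eval_times,
                 rtol, atol)
    }
  }, error = function(e) {
    .stopf("trajectory simulation failed for patient %s: %s",
           patient$patient_id %||% "<unnamed>", conditionMessage(e))
  })
  if (any(!is.finite(va)))
    .stopf("non-finite VA produced for patient %s",
           patient$patient_id %||% "<unnamed>")
  if (clip) va <- pmin(pmax(va, 0), 100)
  data.frame(patient_id = as.character(patient$patient_id %||% NA_character_),
             time_days = eval_times, va_letters = va,
             stringsAsFactors = FALSE)
}
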