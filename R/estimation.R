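# estimation: ordinary least-squares calibration of the model against cohort
# VA observations, plus the validation statistics (mean gain curves with 95%
# prediction intervals for the mean, adjusted R-squared, and the adjusted-R2
# vs sample-size sweep).

# ---- residuals --------------------------------------------------------------

# Build one simulation template per patient, keyed to that patient's
# observation times. Templates cache the grid and the (parameter-independent,
# since k_drug is fixed) concentration profile, so repeated objective
# evaluations only redo the cheap Emax/Hill/cumsum part.
.make_fit_templates <- function(patients, schedules, observations,
                                h, k_drug) {
  obs <- observations[order(observations$patient_id,
                            observations$time_days), , drop = FALSE]
  orphans <- setdiff(unique(obs$patient_id), patients$patient_id)
  if (length(orphans))
    .stopf("observations reference unknown patients: %s",
           paste(orphans, collapse = ", "))
  ids <- unique(obs$patient_id)
  idx <- split(seq_len(nrow(obs)), factor(obs$patient_id, levels = ids))
  prow <- match(ids, patients$patient_id)
  tpls <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- idx[[k]]
    times <- obs$time_days[rows]
    ut <- unique(times)
    sch <- .schedule_of(schedules, ids[k])
    tpl <- .sim_template(sch, ut, h, k_drug)
    tpls[[k]] <- list(tpl = tpl, obs_rows = rows,
                      map = match(times, ut),
                      va_obs = obs$va_letters[rows],
                      g0 = patients$baseline_va[prow[k]],
                      age = patients$age[prow[k]],
                      pre = patients$pretreatment[prow[k]])
  }
  list(templates = tpls, obs = obs)
}

.residuals_from_templates <- function(tpls, params) {
  unlist(lapply(tpls, function(x) {
    va <- .sim_run(x$tpl, params, x$g0, x$age,
                   alpha_for(params, x$pre))
    x$va_obs - va[x$map]
  }), use.names = FALSE)
}

#' Residual vector of the model against VA observations
#'
#' One residual per observation (observed minus model-predicted VA), in a
#' deterministic order (sorted by patient id, then time).
#'
#' @param params A `va_params` object.
#' @param patients Patient data frame (see [patient_baseline()]).
#' @param schedules Schedule data frame with `patient_id`, `time_days`,
#'   `dose_mg` (a patient absent from the table has no injections).
#' @param observations Data frame `patient_id`, `time_days`, `va_letters`.
#' @param h Integrator sub-step (days).
#' @return Numeric vector of residuals in letters.
#' @export
residual_vector <- function(params, patients, schedules, observations,
                            h = 0.25) {
  validate_params(params)
  validate_patients(patients)
  ft <- .make_fit_templates(patients, schedules, observations, h,
                            params$k_drug)
  .residuals_from_templates(ft$templates, params)
}

# ---- parameter transforms ---------------------------------------------------

.LOG_SCALE <- c("g_ss", "k_out", "ec50", "emax0_ss", "k_emax")
.LOGIT_SCALE <- c("alpha_pretreated")

.theta_pack <- function(params, estimate) {
  vapply(estimate, function(nm) {
    v <- params[[nm]]
    if (nm %in% .LOG_SCALE) log(v)
    else if (nm %in% .LOGIT_SCALE) stats::qlogis(min(max(v, 1e-6), 1 - 1e-6))
    else v
  }, numeric(1L))
}

.theta_unpack <- function(theta, base, estimate, tie_possibly = TRUE) {
  p <- unclass(base)
  for (i in seq_along(estimate)) {
    nm <- estimate[i]
    p[[nm]] <- unname(if (nm %in% .LOG_SCALE) exp(theta[i])
    else if (nm %in% .LOGIT_SCALE) stats::plogis(theta[i])
    else theta[i])
  }
  if (tie_possibly) p$alpha_possibly <- p$alpha_pretreated
  class(p) <- "va_params"
  p
}

# ---- fitting ----------------------------------------------------------------

#' Fit model parameters by nonlinear least squares
#'
#' Minimises the (unweighted) sum of squared VA residuals over a configurable
#' subset of parameters. Positive parameters are optimised on the log scale
#' (which guarantees the returned set satisfies all [va_params()]
#' invariants), `alpha_pretreated` on the logit scale. Each start consists of
#' a derivative-free Nelder-Mead pass followed by a Levenberg-Marquardt
#' least-squares refinement ([minpack.lm::nls.lm()]); starts beyond the first
#' jitter the initial values with a fixed seed, so the whole fit is
#' deterministic given data, init and config. `k_drug` is always held fixed;
#' `ec50` is fixed by default (weakly identified jointly with the Emax
#' parameters under a single dose level) and can be added to `estimate`.
#'
#' @param patients,schedules,observations Cohort tables as in
#'   [residual_vector()].
#' @param init A `va_params` object used as starting values (and as the
#'   source of all fixed parameters).
#' @param config Optional list overriding any of: `estimate` (character
#'   vector of parameter names; default all but `ec50`, `k_drug` and the
#'   fixed `alpha_naive`), `n_starts` (5), `jitter_sd` (0.15, on the
#'   transformed scale), `seed` (1), `nm_maxit` (100), `lm_maxit` (100),
#'   `h` (0.5), `tie_possibly` (TRUE: `alpha_possibly` tracks
#'   `alpha_pretreated`).
#' @return An object of class `va_fit`: list with `params` (full
#'   `va_params`), `sse`, `sse_init`, `n_obs`, `n_params_estimated`,
#'   `estimated`, `converged`, `identifiable`, `condition_number`, `starts`
#'   (per-start summary), `config`.
#' @export
fit_parameters <- function(patients, schedules, observations,
                           init = default_params(), config = list()) {
  validate_params(init)
  validate_patients(patients)
  cfg <- utils::modifyList(
    list(estimate = c("g_ss", "k_out", "emax0_ss", "d_emax0", "k_emax",
                      "beta", "alpha_pretreated"),
         n_starts = 5L, jitter_sd = 0.15, seed = 1L,
         nm_maxit = 100L, lm_maxit = 100L, h = 0.5, tie_possibly = TRUE),
    config)
  if ("k_drug" %in% cfg$estimate)
    .stopf("k_drug is fixed and cannot be estimated")
  n_obs <- nrow(observations)
  if (n_obs < length(cfg$estimate))
    .stopf("need at least one observation per estimated parameter")
  ft <- .make_fit_templates(patients, schedules, observations, cfg$h,
                            init$k_drug)
  resid_fn <- function(theta) {
    p <- .theta_unpack(theta, init, cfg$estimate, cfg$tie_possibly)
    r <- .residuals_from_templates(ft$templates, p)
    if (any(!is.finite(r))) r[] <- 1e6
    r
  }
  sse_fn <- function(theta) sum(resid_fn(theta)^2)

  theta0 <- .theta_pack(init, cfg$estimate)
  sse_init <- sse_fn(theta0)
  set.seed(cfg$seed)
  jitters <- lapply(seq_len(cfg$n_starts), function(s) {
    if (s == 1L) rep(0, length(theta0))
    else stats::rnorm(length(theta0), 0, cfg$jitter_sd)
  })
  best <- list(sse = Inf, theta = theta0, converged = FALSE, hessian = NULL)
  starts <- vector("list", cfg$n_starts)
  for (s in seq_len(cfg$n_starts)) {
    th <- theta0 + jitters[[s]]
    if (cfg$nm_maxit > 0 && length(th) > 1L) {
      nm <- stats::optim(th, sse_fn, method = "Nelder-Mead",
                         control = list(maxit = cfg$nm_maxit))
      th <- nm$par
    }
    lm <- minpack.lm::nls.lm(par = th, fn = resid_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = cfg$lm_maxit))
    sse_s <- sum(lm$fvec^2)
    conv_s <- lm$info %in% 1:4
    starts[[s]] <- data.frame(start = s, sse = sse_s, converged = conv_s,
                              info = lm$info)
    if (sse_s < best$sse)
      best <- list(sse = sse_s, theta = lm$par, converged = conv_s,
                   hessian = lm$hessian)
  }
  starts <- do.call(rbind, starts)

  # objective monotonicity: never return something worse than the init
  if (best$sse > sse_init) {
    best$theta <- theta0
    best$sse <- sse_init
    best$converged <- FALSE
  }
  params_hat <- .theta_unpack(best$theta, init, cfg$estimate,
                              cfg$tie_possibly)
  cond <- NA_real_
  identifiable <- NA
  if (!is.null(best$hessian)) {
    ev <- suppressWarnings(eigen(best$hessian, symmetric = TRUE,
                                 only.values = TRUE)$values)
    ev <- ev[is.finite(ev)]
    if (length(ev) && min(ev) > 0) {
      cond <- max(ev) / min(ev)
      identifiable <- cond < 1e10
    } else {
      cond <- Inf
      identifiable <- FALSE
    }
    if (!identifiable)
      warning("near-singular information: some parameters are not ",
              "identifiable from these data (condition number ",
              format(cond, digits = 3), ")", call. = FALSE)
  }
  structure(list(params = params_hat, sse = best$sse, sse_init = sse_init,
                 n_obs = n_obs,
                 n_params_estimated = length(cfg$estimate),
                 estimated = cfg$estimate, converged = best$converged,
                 identifiable = identifiable, condition_number = cond,
                 starts = starts, config = cfg),
            class = "va_fit")
}

#' @export
print.va_fit <- function(x, ...) {
  cat(sprintf("VA model fit: sse = %.4g over %d observations (%d parameters)\n",
              x$sse, x$n_obs, x$n_params_estimated))
  cat(sprintf("  converged: %s; identifiable: %s\n",
              x$converged, x$identifiable))
  print(x$params)
  invisible(x)
}

#' Serialise a fit result to JSON (and back)
#'
#' @param fit A `va_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(params = unclass(fit$params), sse = fit$sse,
              sse_init = fit$sse_init, n_obs = fit$n_obs,
              n_params_estimated = fit$n_params_estimated,
              estimated = fit$estimated, converged = fit$converged,
              identifiable = fit$identifiable,
              condition_number = fit$condition_number,
              config = fit$config[c("n_starts", "jitter_sd", "seed", "h")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- mean curves ------------------------------------------------------------

#' Mean VA gain curve with 95% prediction interval for the mean
#'
#' Bins observations (or simulated trajectory points) into time bins of
#' `bin_width` days (assignment to the nearest bin centre), computes the mean
#' change from baseline over the patients contributing to each bin, and a
#' normal-approximation interval for the mean, `mean +/- z * sd / sqrt(n)`.
#' Observations after a patient's `obs_end_days` are excluded (censoring),
#' so the per-bin patient count shrinks as patients drop out. Empty bins are
#' dropped.
#'
#' @param observations Data frame `patient_id`, `time_days`, `va_letters`.
#' @param patients Patient table supplying each patient's baseline VA (the
#'   reference for "change from baseline") and `obs_end_days`.
#' @param bin_width Bin width in days (default one month).
#' @param level Interval level (default 0.95).
#' @return A data frame of class `mean_curve`: `time_days` (bin centres),
#'   `mean_gain`, `pi_low`, `pi_high`, `n_at_time`.
#' @export
mean_curve_with_pi <- function(observations, patients,
                               bin_width = DAYS_PER_MONTH, level = 0.95) {
  validate_patients(patients)
  pr <- match(observations$patient_id, patients$patient_id)
  if (anyNA(pr)) .stopf("observations reference unknown patients")
  keep <- observations$time_days <=
    patients$obs_end_days[pr] + bin_width / 2
  keep[is.na(keep)] <- TRUE
  obs <- observations[keep, , drop = FALSE]
  pr <- pr[keep]
  gain <- obs$va_letters - patients$baseline_va[pr]
  bin <- round(obs$time_days / bin_width)
  z <- stats::qnorm(1 - (1 - level) / 2)
  agg <- lapply(split(gain, bin), function(g) {
    n <- length(g)
    s <- if (n > 1L) stats::sd(g) else 0
    c(mean = mean(g), half = z * s / sqrt(n), n = n)
  })
  bins <- as.numeric(names(agg))
  m <- do.call(rbind, agg)
  out <- data.frame(time_days = bins * bin_width,
                    mean_gain = m[, "mean"],
                    pi_low = m[, "mean"] - m[, "half"],
                    pi_high = m[, "mean"] + m[, "half"],
                    n_at_time = as.integer(m[, "n"]))
  out <- out[order(out$time_days), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mean_curve", "data.frame")
  out
}

#' Adjusted R-squared between an observed and a predicted mean curve
#'
#' Computes `R2 = 1 - SS_res / SS_tot` across the common time bins of the
#' two curves and adjusts for the number of model parameters:
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` with `n` the number of bins.
#'
#' @param observed,predicted `mean_curve` data frames on identical bins.
#' @param n_params Number of estimated model parameters `p` (default 7, the
#'   size of the default estimation subset).
#' @return Adjusted R-squared (can be negative for a poor fit).
#' @export
adjusted_r2 <- function(observed, predicted, n_params = 7) {
  if (!all(c("time_days", "mean_gain") %in% names(observed)) ||
      !all(c("time_days", "mean_gain") %in% names(predicted)))
    .stopf("inputs must be mean_curve data frames")
  m <- merge(observed[, c("time_days", "mean_gain")],
             predicted[, c("time_days", "mean_gain")],
             by = "time_days", suffixes = c("_obs", "_pred"))
  n <- nrow(m)
  if (n < n_params + 2)
    .stopf("need at least n_params + 2 = %d common bins, have %d",
           n_params + 2, n)
  ss_res <- sum((m$mean_gain_obs - m$mean_gain_pred)^2)
  ss_tot <- sum((m$mean_gain_obs - mean(m$mean_gain_obs))^2)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Adjusted R-squared as a function of sample size
#'
#' Draws subsamples of patients without replacement, and for each draw
#' computes the adjusted R-squared between the subsample's observed (noisy)
#' mean gain curve and the model-predicted (noise-free) mean gain curve of
#' the same patients. Mirrors the empirical finding that population-level
#' mean VA is well predicted at large n while individual prediction is not
#' possible.
#'
#' @param cohort A `va_cohort` with observations.
#' @param params `va_params` used for the model predictions.
#' @param sample_sizes Integer vector of subsample sizes (each <= cohort
#'   size).
#' @param draws_per_size Number of draws per size (default 30).
#' @param seed Integer seed.
#' @param bin_width Bin width in days.
#' @param n_params Adjustment degrees of freedom (see [adjusted_r2()]).
#' @param h Integrator sub-step (days).
#' @return Data frame `n`, `mean_r2`, `lo`, `hi` (empirical 2.5/97.5
#'   percentiles across draws).
#' @export
r2_vs_sample_size <- function(cohort, params, sample_sizes,
                              draws_per_size = 30, seed = 1,
                              bin_width = DAYS_PER_MONTH, n_params = 7,
                              h = 0.5) {
  patients <- cohort$patients
  if (any(sample_sizes > nrow(patients)))
    .stopf("sample sizes exceed the cohort size (%d)", nrow(patients))
  if (is.null(cohort$observations))
    .stopf("cohort has no observations")
  # model predictions at every observation point, computed once
  ft <- .make_fit_templates(patients, cohort$schedules,
                            cohort$observations, h, params$k_drug)
  pred <- ft$obs
  pred$va_letters <- ft$obs$va_letters -
    .residuals_from_templates(ft$templates, params)
  set.seed(seed)
  rows <- lapply(sample_sizes, function(n) {
    r2 <- vapply(seq_len(draws_per_size), function(d) {
      ids <- sample(patients$patient_id, n)
      sub_obs <- ft$obs[ft$obs$patient_id %in% ids, , drop = FALSE]
      sub_pred <- pred[pred$patient_id %in% ids, , drop = FALSE]
      oc <- mean_curve_with_pi(sub_obs, patients, bin_width)
      pc <- mean_curve_with_pi(sub_pred, patients, bin_width)
      adjusted_r2(oc, pc, n_params)
    }, numeric(1L))
    data.frame(n = n, mean_r2 = mean(r2),
               lo = unname(stats::quantile(r2, 0.025)),
               hi = unname(stats::quantile(r2, 0.975)))
  })
  do.call(rbind, rows)
}
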