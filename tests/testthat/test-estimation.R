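test_that("residuals are observed minus model, in deterministic order", {
  p <- default_params()
  coh <- small_cohort(n = 15, seed = 3, params = p, noise_sd = 0)
  r <- residual_vector(p, coh$patients, coh$schedules, coh$observations)
  expect_lt(max(abs(r)), 1e-6)   # self-consistency at the generating truth
  # a single baseline observation: residual = observed - g0
  pat <- ref_patient(va = 48)
  obs <- data.frame(patient_id = "P1", time_days = 0, va_letters = 51)
  r1 <- residual_vector(p, pat,
                        data.frame(patient_id = character(),
                                   time_days = numeric(),
                                   dose_mg = numeric()), obs)
  expect_equal(r1, 3)
  # orphan observations are reported by id
  obs_bad <- rbind(obs, data.frame(patient_id = "GHOST", time_days = 10,
                                   va_letters = 50))
  expect_error(residual_vector(p, pat, coh$schedules[0, ], obs_bad), "GHOST")
})

test_that("residual spread matches the observation noise", {
  p <- default_params()
  coh <- small_cohort(n = 60, seed = 9, params = p, noise_sd = 5)
  r <- residual_vector(p, coh$patients, coh$schedules, coh$observations)
  expect_gt(length(r), 800)
  expect_equal(sd(r), 5, tolerance = 0.06)
})

test_that("mean curve aggregates gains with a CLT interval and censoring", {
  # identical constant patients: zero gain, zero width
  pats <- do.call(rbind, lapply(1:5, function(i)
    ref_patient(sprintf("P%d", i), va = 60)))
  obs <- expand.grid(patient_id = pats$patient_id,
                     time_days = c(0, 30.4375, 60.875),
                     stringsAsFactors = FALSE)
  obs$va_letters <- 60
  mc <- mean_curve_with_pi(obs, pats)
  expect_equal(mc$mean_gain, rep(0, 3))
  expect_equal(mc$pi_high - mc$pi_low, rep(0, 3))
  expect_equal(mc$n_at_time, rep(5L, 3))

  # one bin of 10,000 standard-normal gains: half-width ~ 1.96 / 100
  set.seed(21)
  pats2 <- do.call(rbind, lapply(1:10000, function(i)
    ref_patient(sprintf("Q%05d", i), va = 50)))
  obs2 <- data.frame(patient_id = pats2$patient_id, time_days = 30.4375,
                     va_letters = 50 + rnorm(10000))
  mc2 <- mean_curve_with_pi(obs2, pats2)
  expect_equal(mc2$pi_high - mc2$pi_low, 2 * 1.96 / 100, tolerance = 0.03)

  # observations beyond a patient's window are censored out
  pats3 <- rbind(ref_patient("A", va = 50, obs_end = 400),
                 ref_patient("B", va = 50, obs_end = 100))
  obs3 <- expand.grid(patient_id = c("A", "B"),
                      time_days = c(0, 91.3125, 365.25),
                      stringsAsFactors = FALSE)
  obs3$va_letters <- 50
  mc3 <- mean_curve_with_pi(obs3, pats3)
  expect_equal(mc3$n_at_time, c(2L, 2L, 1L))
})

test_that("adjusted R-squared follows the textbook formula", {
  mk <- function(y) structure(data.frame(time_days = seq_along(y) * 30,
                                         mean_gain = y),
                              class = c("mean_curve", "data.frame"))
  set.seed(7)
  obs <- rnorm(24, 2, 3)
  pred <- obs + rnorm(24, 0, 1)
  got <- adjusted_r2(mk(obs), mk(pred), n_params = 7)
  # independently coded reference
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(got, 1 - (1 - r2) * (24 - 1) / (24 - 7 - 1))
  # a perfect prediction scores exactly 1
  expect_equal(adjusted_r2(mk(obs), mk(obs)), 1)
  # the null model (constant mean) scores <= 0 after adjustment
  expect_lte(adjusted_r2(mk(obs), mk(rep(mean(obs), 24))), 0)
  # too few bins for the adjustment
  expect_error(adjusted_r2(mk(obs[1:5]), mk(pred[1:5]), n_params = 7),
               "bins")
})

test_that("noise-free data at the truth is a fixed point of the fit", {
  truth <- default_params()
  coh <- small_cohort(n = 25, seed = 13, params = truth, noise_sd = 0)
  fit <- fit_parameters(coh$patients, coh$schedules, coh$observations,
                        init = truth,
                        config = list(n_starts = 1L, nm_maxit = 0L,
                                      lm_maxit = 20L))
  expect_lt(fit$sse, 1e-4)
  for (nm in fit$estimated)
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("the fit never returns a worse objective than its start", {
  truth <- default_params()
  coh <- small_cohort(n = 20, seed = 17, params = truth, noise_sd = 5)
  init <- va_params(g_ss = 55, k_out = 0.008, emax0_ss = 0.6, d_emax0 = 0.4,
                    k_emax = 0.05, beta = 0, alpha_pretreated = 0.6)
  fit <- suppressWarnings(
    fit_parameters(coh$patients, coh$schedules, coh$observations, init,
                   config = list(n_starts = 2L, nm_maxit = 30L,
                                 lm_maxit = 25L)))
  expect_lte(fit$sse, fit$sse_init)
  validate_params(fit$params)   # log/logit scales keep invariants intact
})

test_that("a cohort without injections leaves drug parameters unidentified", {
  truth <- default_params()
  coh <- small_cohort(n = 30, seed = 19, params = truth, noise_sd = 2)
  sch0 <- coh$schedules[0, ]   # strip every injection
  obs <- coh$observations
  expect_warning(
    fit <- fit_parameters(coh$patients, sch0, obs, truth,
                          config = list(n_starts = 1L, nm_maxit = 0L,
                                        lm_maxit = 15L)),
    "identifiable")
  expect_false(fit$identifiable)
})

test_that("adjusted R2 grows with sample size and degenerates at full n", {
  truth <- default_params()
  coh <- small_cohort(n = 120, seed = 23, params = truth, noise_sd = 5)
  tab <- r2_vs_sample_size(coh, truth, sample_sizes = c(20, 120),
                           draws_per_size = 8, seed = 2)
  expect_equal(nrow(tab), 2L)
  expect_gt(tab$mean_r2[2], tab$mean_r2[1])
  # drawing the whole cohort without replacement has a single outcome
  expect_equal(tab$lo[2], tab$hi[2])
  expect_error(r2_vs_sample_size(coh, truth, 500), "exceed")
})
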