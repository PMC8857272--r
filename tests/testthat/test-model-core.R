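test_that("vitreous concentration follows bolus + first-order elimination", {
  kd <- log(2) / 9
  expect_equal(vitreous_concentration(injection_schedule(), c(0, 10, 100), kd),
               c(0, 0, 0))
  # one half-life halves the bolus
  s1 <- injection_schedule(0, 0.5)
  expect_equal(vitreous_concentration(s1, 9, kd), 0.25)
  # superposition just after the second event
  s2 <- injection_schedule(c(0, 28), 0.5)
  expect_equal(vitreous_concentration(s2, 28, kd),
               0.5 + 0.5 * exp(-28 * kd))
  # zero before the first injection
  s3 <- injection_schedule(c(20, 40), 0.5)
  expect_equal(vitreous_concentration(s3, c(0, 19.9), kd), c(0, 0))
  expect_error(vitreous_concentration(s1, -1, kd), ">= 0")
  expect_error(injection_schedule(c(10, 5), 0.5), "increasing")
})

test_that("concentration matches an ODE oracle with bolus jump events", {
  kd <- log(2) / 9
  s <- injection_schedule(c(0, 28), 0.5)
  tt <- seq(0, 90, by = 0.5)
  # independent oracle: integrate dC/dt = -kd * C with additive dose events
  sol <- deSolve::lsoda(
    y = c(C = 0), times = tt, func = function(t, y, p) list(-kd * y),
    events = list(data = data.frame(var = "C", time = c(0, 28),
                                    value = 0.5, method = "add")),
    rtol = 1e-10, atol = 1e-12)
  # at the bolus instants the two conventions differ (pre- vs post-jump
  # value); compare everywhere else
  keep <- !tt %in% c(0, 28)
  expect_equal(vitreous_concentration(s, tt, kd)[keep],
               unname(sol[keep, "C"]), tolerance = 1e-7)
})

test_that("PK superposition: two-event concentration is the sum of singles", {
  set.seed(5)
  for (i in 1:20) {
    kd <- runif(1, 0.02, 0.2)
    t1 <- runif(1, 0, 50); t2 <- t1 + runif(1, 1, 100)
    d1 <- runif(1, 0.1, 2); d2 <- runif(1, 0.1, 2)
    tt <- sort(runif(20, 0, 300))
    both <- vitreous_concentration(injection_schedule(c(t1, t2), c(d1, d2)),
                                   tt, kd)
    one <- vitreous_concentration(injection_schedule(t1, d1), tt, kd)
    two <- vitreous_concentration(injection_schedule(t2, d2), tt, kd)
    expect_equal(both, one + two, tolerance = 1e-12)
  }
})

test_that("Emax combines its steady state, age scaling and transient decay", {
  p <- default_params()
  # at baseline and reference age, Emax = emax0_ss + d_emax0
  expect_equal(emax_at(0, p, age = 77, alpha = 1),
               p$emax0_ss + p$d_emax0)
  # the transient vanishes at large t, for any alpha
  expect_equal(emax_at(1e7, p, age = 77, alpha = 0.4), p$emax0_ss)
  # at the reference age the age term vanishes exactly
  expect_equal(emax_at(1e7, p, age = 77, alpha = 1), p$emax0_ss)
  # age scaling on the log scale
  expect_equal(emax_at(1e7, p, age = 87, alpha = 1),
               exp(log(p$emax0_ss) + p$beta * log(87 / 77)))
  expect_error(emax_at(0, p, age = -1, alpha = 1), "age")
})

test_that("the no-treatment closed form behaves as the exact solution", {
  p <- va_params(g_ss = 40, k_out = 0.01)
  expect_equal(no_treatment_solution(40, p, c(0, 50, 700)), rep(40, 3))
  expect_equal(no_treatment_solution(66, p, 0), 66)
  expect_equal(no_treatment_solution(70, p, 100), 40 + 30 * exp(-1),
               tolerance = 1e-12)
})

test_that("empty-schedule simulation reproduces the closed form", {
  set.seed(11)
  tt <- seq(0, 720, by = 7.3)
  for (i in 1:25) {
    p <- random_params()
    g0 <- runif(1, 5, 95)
    pat <- ref_patient(va = g0)
    tr <- simulate_trajectory(pat, injection_schedule(), p, tt)
    expect_lt(max(abs(tr$va_letters - no_treatment_solution(g0, p, tt))),
              1e-6)
  }
})

test_that("trajectory starts exactly at the baseline VA", {
  p <- va_params(k_out = 0.01)
  tr <- simulate_trajectory(ref_patient(va = 63.5), make_3l_q8w_schedule(),
                            p, c(0, 30, 60))
  expect_identical(tr$va_letters[1], 63.5)
})

test_that("analytic integrator agrees with the adaptive lsoda cross-check", {
  p <- default_params()
  pat <- ref_patient(va = 52, age = 81, pre = "pretreated", delay = 20)
  sch <- injection_schedule(c(20, 48, 90, 200, 300), 0.5)
  tt <- seq(0, 540, by = 30)
  a <- simulate_trajectory(pat, sch, p, tt)
  b <- simulate_trajectory(pat, sch, p, tt, method = "lsoda",
                           rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(a$va_letters - b$va_letters)), 1e-3)
})

test_that("halving the integration step barely changes month-18 VA", {
  p <- default_params()
  pat <- ref_patient()
  sch <- make_3l_q8w_schedule()
  v1 <- simulate_trajectory(pat, sch, p, c(0, 547.875), h = 0.25)$va_letters[2]
  v2 <- simulate_trajectory(pat, sch, p, c(0, 547.875), h = 0.125)$va_letters[2]
  expect_lt(abs(v1 - v2), 0.01)
})

test_that("adding an injection never decreases VA at any later time", {
  p <- default_params()
  pat <- ref_patient()
  tt <- seq(0, 720, by = 10)
  bases <- list(injection_schedule(),
                injection_schedule(30, 0.5),
                make_3l_q8w_schedule())
  for (base in bases) {
    for (t_extra in c(5, 90, 400)) {
      if (nrow(base) && min(abs(base$time_days - t_extra)) < 1e-9) next
      more <- injection_schedule(sort(c(base$time_days, t_extra)),
                                 c(base$dose_mg, 0.5)[order(c(base$time_days,
                                                              t_extra))])
      v0 <- simulate_trajectory(pat, base, p, tt)$va_letters
      v1 <- simulate_trajectory(pat, more, p, tt)$va_letters
      expect_true(all(v1 - v0 >= -1e-9))
    }
  }
})

test_that("earlier injections never hurt the 18-month outcome", {
  # the transient Emax component decays with time from diagnosis, so within
  # the active-disease window a single injection helps more the earlier it
  # is given
  p <- default_params()
  pat <- ref_patient()
  shifts <- seq(0, 84, by = 7)
  end_va <- vapply(shifts, function(s)
    simulate_trajectory(pat, injection_schedule(s, 0.5), p,
                        c(0, 547.875))$va_letters[2], numeric(1))
  expect_true(all(diff(end_va) <= 1e-9))
})

test_that("reported VA can be clipped without touching the model state", {
  p <- va_params(g_ss = 90, emax0_ss = 1.5, d_emax0 = 0.5)
  pat <- ref_patient(va = 95)
  sch <- injection_schedule(seq(0, 500, by = 28), 0.5)
  raw <- simulate_trajectory(pat, sch, p, seq(0, 540, by = 30))
  clipped <- simulate_trajectory(pat, sch, p, seq(0, 540, by = 30),
                                 clip = TRUE)
  expect_gt(max(raw$va_letters), 100)
  expect_lte(max(clipped$va_letters), 100)
})

test_that("simulation input contracts are enforced", {
  p <- default_params()
  expect_error(simulate_trajectory(ref_patient(obs_end = 100),
                                   injection_schedule(), p, c(0, 200)),
               "obs_end")
  expect_error(simulate_trajectory(ref_patient(), injection_schedule(), p,
                                   c(10, 5)), "sorted")
  bad <- va_params(); bad$k_out <- NaN
  expect_error(simulate_trajectory(ref_patient(), injection_schedule(), bad,
                                   c(0, 10)), "k_out")
})
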