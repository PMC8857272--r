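test_that("delay calibration hits the published moments and tails", {
  dd <- calibrate_delay_distribution()
  a <- dd$achieved
  expect_lt(abs(a$mean - 20.3), 0.5)
  expect_lt(abs(a$sd - 19.4), 1)
  expect_lt(abs(a$p_lt14 - 0.437), 0.02)
  expect_lt(abs(a$p_gt28 - 0.291), 0.02)
  # draws live on the right support
  set.seed(1)
  d <- sample_delays(dd, 1e4)
  expect_true(all(d >= 0))
})

test_that("a degenerate delay request collapses to a point mass at zero", {
  dd <- calibrate_delay_distribution(list(mean = 0, sd = 0,
                                          p_lt14 = 1, p_gt28 = 0))
  expect_identical(dd$type, "point")
  expect_equal(sample_delays(dd, 5), rep(0, 5))
  expect_equal(dd$achieved$p_lt14, 1)
  expect_equal(dd$achieved$p_gt28, 0)
})

test_that("baseline draws respect supports and the mixture", {
  pats <- sample_baselines(cohort_profile(), n = 2000, seed = 8)
  expect_true(all(pats$baseline_va >= 0 & pats$baseline_va <= 100))
  expect_true(all(pats$age >= 50))
  expect_true(all(pats$delay_days >= 0))
  expect_setequal(unique(pats$pretreatment),
                  c("naive", "pretreated", "possibly_pretreated"))
  # a pure-naive mixture yields only naive patients
  prof <- cohort_profile(pretreatment_mix = c(naive = 1, pretreated = 0,
                                              possibly_pretreated = 0))
  expect_true(all(sample_baselines(prof, n = 200, seed = 1)$pretreatment ==
                    "naive"))
})

test_that("dropout matches the retention targets and supports completers", {
  prof <- cohort_profile()
  set.seed(12)
  obs_end <- sample_dropout(prof, 6000)
  frac_at <- function(m) mean(obs_end >= m * DAYS_PER_MONTH)
  expect_equal(frac_at(6), prof$retention$fraction[1], tolerance = 0.02)
  expect_equal(frac_at(12), prof$retention$fraction[2], tolerance = 0.02)
  expect_equal(frac_at(18), prof$retention$fraction[3], tolerance = 0.02)
  expect_true(frac_at(6) >= frac_at(12) && frac_at(12) >= frac_at(18))
  # 100% retention: everyone completes 24 months
  prof2 <- cohort_profile(retention = list(months = c(6, 12, 18),
                                           fraction = c(1, 1, 1)))
  expect_true(all(sample_dropout(prof2, 500) == 24 * DAYS_PER_MONTH))
})

test_that("injection patterns start at the delay and stay in the window", {
  prof <- cohort_profile()
  pats <- sample_baselines(prof, n = 2000, seed = 4)
  set.seed(5)
  for (i in seq_len(500)) {
    s <- sample_injection_pattern(pats[i, ], prof)
    if (!nrow(s)) next
    expect_true(all(diff(s$time_days) > 0))
    expect_gte(s$time_days[1], pats$delay_days[i])
    expect_lte(max(s$time_days), pats$obs_end_days[i])
  }
  # no time to treat: empty schedule
  late <- ref_patient(delay = 200, obs_end = 100)
  expect_equal(nrow(sample_injection_pattern(late, prof)), 0L)
})

test_that("first-year injection counts match the profile moments", {
  coh <- generate_cohort(n = 1500, seed = 6)
  y1 <- vapply(split(coh$schedules$time_days, coh$schedules$patient_id),
               function(t) sum(t <= 365), numeric(1))
  cnt <- setNames(rep(0, nrow(coh$patients)), coh$patients$patient_id)
  cnt[names(y1)] <- y1
  sel <- coh$patients$obs_end_days >= 365
  expect_equal(mean(cnt[sel]), 4.47, tolerance = 0.2 / 4.47)
  expect_equal(sd(cnt[sel]), 2.21, tolerance = 0.35 / 2.21)
})

test_that("observations are the trajectory plus clipped Gaussian noise", {
  p <- default_params()
  pat <- ref_patient(va = 52, obs_end = 365)
  sch <- injection_schedule(c(0, 60, 150), 0.5)
  set.seed(2)
  clean <- generate_observations(pat, sch, p, noise_sd = 0)
  truth <- simulate_trajectory(pat, sch, p, clean$time_days)
  expect_equal(clean$va_letters, truth$va_letters)
  # noise has the configured spread
  at100 <- simulate_trajectory(pat, sch, p, c(0, 100))$va_letters[2]
  res <- replicate(800, generate_observations(pat, sch, p,
                                              visit_times = c(100),
                                              noise_sd = 5)$va_letters[2]) -
    at100
  expect_equal(sd(res), 5, tolerance = 0.1)
  # clipping near the ceiling
  hi <- ref_patient(va = 99.5, obs_end = 60)
  obs <- generate_observations(hi, injection_schedule(), p, noise_sd = 20)
  expect_true(all(obs$va_letters <= 100 & obs$va_letters >= 0))
})

test_that("cohorts are seed-deterministic and round-trip through CSV", {
  a <- generate_cohort(n = 25, seed = 123, params = default_params())
  b <- generate_cohort(n = 25, seed = 123, params = default_params())
  expect_identical(a$patients, b$patients)
  expect_identical(a$schedules, b$schedules)
  expect_identical(a$observations, b$observations)
  dir <- withr::local_tempdir()
  write_cohort_csv(a, dir)
  back <- read_cohort_csv(dir)
  expect_identical(back$patients, a$patients)
  expect_identical(back$schedules, a$schedules)
  expect_identical(back$observations, a$observations)
})
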