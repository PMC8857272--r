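test_that("3l-q8w schedule enumerates loading then 8-weekly maintenance", {
  s <- make_3l_q8w_schedule(window_end = 547.875, dose = 0.5)
  expect_equal(s$time_days,
               c(0, 28, 56, 112, 168, 224, 280, 336, 392, 448, 504))
  expect_equal(nrow(s), 11L)
  expect_true(all(s$dose_mg == 0.5))
  # a 60-day window only fits the loading injections
  expect_equal(make_3l_q8w_schedule(window_end = 60)$time_days, c(0, 28, 56))
  # the first-year intensity matches the trial-like reference of 8 injections
  expect_equal(sum(s$time_days <= 365), 8L)
})

test_that("delay capping shifts the whole schedule, preserving gaps", {
  s <- injection_schedule(c(20, 55, 120), 0.5)
  expect_equal(shift_delay(s, 20, 0)$time_days, c(0, 35, 100))
  s2 <- injection_schedule(c(10, 40), 0.5)
  expect_identical(shift_delay(s2, 10, 14), s2)      # already within the cap
  s3 <- injection_schedule(c(30, 70, 150), 0.5)
  out <- shift_delay(s3, 30, 14)
  expect_equal(out$time_days, c(14, 54, 134))
  expect_equal(diff(out$time_days), diff(s3$time_days))
  expect_equal(nrow(out), nrow(s3))
  expect_error(shift_delay(injection_schedule(5, 0.5), 10, 0), "earlier")
})

test_that("redistribution without loading spaces injections uniformly", {
  one <- injection_schedule(25, 0.5)
  expect_equal(redistribute_without_loading(one)$time_days, 25)
  s <- injection_schedule(c(0, 30, 100, 200), 0.5)
  out <- redistribute_without_loading(s, window_end = 540)
  expect_equal(out$time_days, c(0, 180, 360, 540))
  gaps <- diff(out$time_days)
  expect_lt(max(gaps) - min(gaps), 1e-9)
})

test_that("redistribution with loading keeps delay, count and skeleton", {
  s <- injection_schedule(c(10, 40, 90, 200, 330, 400), 0.5)
  out <- redistribute_with_loading(s, window_end = 547.875,
                                   loading_sigma = 0, maint_sigma = 0)
  step <- (547.875 - 66) / 3
  expect_equal(out$time_days,
               c(10, 38, 66, 66 + step, 66 + 2 * step, 547.875))
  expect_equal(nrow(out), nrow(s))
  # fewer than 3 events: all become loading-style
  two <- injection_schedule(c(5, 300), 0.5)
  expect_equal(redistribute_with_loading(two, loading_sigma = 0)$time_days,
               c(5, 33))
})

test_that("redistribution jitter has the configured sigmas", {
  set.seed(99)
  s <- injection_schedule(c(30, 60, 120, 240, 360, 480), 0.5)
  skeleton <- redistribute_with_loading(s, loading_sigma = 0,
                                        maint_sigma = 0)$time_days
  devs <- replicate(3000,
    redistribute_with_loading(s)$time_days - skeleton)
  expect_equal(sd(devs[1:3, ]), 4, tolerance = 0.05)
  expect_equal(sd(devs[4:6, ]), 7, tolerance = 0.05)
})

test_that("counterfactual transforms conserve the injection count", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(1:9, 1)
    times <- sort(runif(k, 5, 500))
    s <- injection_schedule(times, 0.5)
    d <- times[1]
    expect_equal(nrow(shift_delay(s, d, 0)), k)
    expect_equal(nrow(shift_delay(s, d, 14)), k)
    expect_equal(nrow(redistribute_with_loading(s)), k)
    expect_equal(nrow(redistribute_without_loading(s)), k)
  }
})
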