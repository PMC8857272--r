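# Schedule construction and counterfactual transformations. All month
# arithmetic uses DAYS_PER_MONTH = 30.4375 days.

#' Fixed 3-loading + q8w maintenance schedule
#'
#' Three loading injections every 4 weeks (days 0, 28, 56), followed by
#' maintenance injections every 8 weeks (days 112, 168, ...) while they fall
#' within the window. This is the "3l-q8w" reference pattern whose first-year
#' injection count (8) matches the intensity of PRN/T&E arms in randomised
#' trials.
#'
#' @param window_end End of the treatment window in days (default Month 18).
#' @param dose Dose per injection in mg (default 0.5).
#' @return An injection schedule data frame.
#' @examples
#' nrow(make_3l_q8w_schedule())              # 11 injections to Month 18
#' make_3l_q8w_schedule(window_end = 60)     # loading only
#' @export
make_3l_q8w_schedule <- function(window_end = 18 * DAYS_PER_MONTH,
                                 dose = 0.5) {
  .assert_number(window_end, "window_end", lower = 56)
  times <- c(0, 28, 56)
  if (window_end >= 112)
    times <- c(times, seq(112, window_end, by = 56))
  injection_schedule(times, dose)
}

#' Cap the treatment delay by shifting the whole schedule forward
#'
#' If the patient's delay exceeds `max_delay`, every injection time is reduced
#' by `delay - max_delay`: the number and relative timing of injections are
#' unchanged, and the gap without injections moves from the beginning to the
#' end of the observation window. With `max_delay = 0` the first injection
#' lands at day 0.
#'
#' @param schedule Non-empty injection schedule whose first event is at the
#'   patient's observed delay.
#' @param delay The patient's observed delay in days.
#' @param max_delay Maximum allowed delay in days.
#' @return The shifted schedule.
#' @export
shift_delay <- function(schedule, delay, max_delay) {
  validate_schedule(schedule)
  .assert_number(delay, "delay", lower = 0)
  .assert_number(max_delay, "max_delay", lower = 0)
  if (!nrow(schedule)) .stopf("schedule must be non-empty")
  if (schedule$time_days[1L] < delay - 1e-9)
    .stopf("first injection (day %g) is earlier than the stated delay (%g)",
           schedule$time_days[1L], delay)
  if (delay <= max_delay) return(schedule)
  out <- schedule
  out$time_days <- out$time_days - (delay - max_delay)
  validate_schedule(out)
  out
}

# sort jittered times, clip at zero, and break exact ties so the result is a
# valid strictly-increasing schedule
.sanitize_times <- function(times, min_gap = 1e-6) {
  times <- sort(pmax(times, 0))
  if (length(times) > 1L) {
    for (i in 2:length(times)) {
      if (times[i] - times[i - 1L] < min_gap)
        times[i] <- times[i - 1L] + min_gap
    }
  }
  times
}

#' Redistribute injections with a 3 q4w loading period
#'
#' Keeps the patient's delay (the original first injection time) and total
#' injection count, but re-times the injections: the first three at
#' `delay`, `delay + 28`, `delay + 56` with N(0, `loading_sigma`^2)-day
#' jitter, and the remaining events equally spaced over
#' `(delay + 56, window_end]` with N(0, `maint_sigma`^2)-day jitter. Jittered
#' times are re-sorted and clipped at 0. With fewer than 3 events, all events
#' are placed loading-style (q4w from the delay). Uses the current RNG state;
#' seed at the caller for reproducibility.
#'
#' @param schedule Non-empty injection schedule.
#' @param window_end End of the redistribution window (days; default
#'   Month 18).
#' @param loading_sigma,maint_sigma Jitter standard deviations in days
#'   (defaults 4 and 7); set to 0 for the deterministic skeleton.
#' @return A schedule with the same number of events.
#' @export
redistribute_with_loading <- function(schedule,
                                      window_end = 18 * DAYS_PER_MONTH,
                                      loading_sigma = 4, maint_sigma = 7) {
  validate_schedule(schedule)
  if (!nrow(schedule)) .stopf("schedule must be non-empty")
  k <- nrow(schedule)
  delay <- schedule$time_days[1L]
  n_load <- min(k, 3L)
  load_t <- delay + 28 * (seq_len(n_load) - 1L) +
    stats::rnorm(n_load, 0, loading_sigma)
  maint_t <- numeric()
  if (k > 3L) {
    a <- delay + 56
    step <- (window_end - a) / (k - 3L)
    maint_t <- a + step * seq_len(k - 3L) +
      stats::rnorm(k - 3L, 0, maint_sigma)
  }
  injection_schedule(.sanitize_times(c(load_t, maint_t)),
                     rep(mean(schedule$dose_mg), k))
}

#' Redistribute injections without a loading period
#'
#' The first injection stays at the observed delay; the remaining events are
#' equally spaced over `(delay, window_end]`. Deterministic; count preserved.
#'
#' @inheritParams redistribute_with_loading
#' @return A schedule with the same number of events.
#' @examples
#' s <- injection_schedule(c(0, 30, 100, 200), 0.5)
#' redistribute_without_loading(s, window_end = 540)$time_days # 0 180 360 540
#' @export
redistribute_without_loading <- function(schedule,
                                         window_end = 18 * DAYS_PER_MONTH) {
  validate_schedule(schedule)
  if (!nrow(schedule)) .stopf("schedule must be non-empty")
  k <- nrow(schedule)
  delay <- schedule$time_days[1L]
  times <- delay
  if (k > 1L) {
    step <- (window_end - delay) / (k - 1L)
    times <- c(delay, delay + step * seq_len(k - 1L))
  }
  injection_schedule(times, rep(mean(schedule$dose_mg), k))
}
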