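test_that("power-exponential emptying curve has the defining properties", {
  # no emptying at time zero; half emptied at the half-time, for any shape
  set.seed(21)
  for (i in 1:25) {
    th <- stats::runif(1, 0.5, 30)
    beta <- stats::runif(1, 0.3, 4)
    expect_equal(fraction_remaining(0, th, beta), 1)
    expect_equal(fraction_remaining(th, th, beta), 0.5)
  }
  # direct evaluation, cross-checked in the log domain: 2^(-2^1.5)
  expect_equal(fraction_remaining(4.28, 2.14, 1.5), 2^(-2^1.5),
               tolerance = 1e-12)
  expect_equal(log2(fraction_remaining(4.28, 2.14, 1.5)), -2^1.5)

  # strictly decreasing in t
  t <- seq(0, 30, by = 0.25)
  expect_true(all(diff(fraction_remaining(t, 2.14, 1.5)) < 0))

  expect_error(fraction_remaining(-1, 2, 1.5), ">= 0")
  expect_error(fraction_remaining(1, 0, 1.5), "> 0")
  expect_error(fraction_remaining(1, 2, 0), "> 0")
})

test_that("half-time predictor implements the linear volume/calorie form", {
  expect_equal(half_time_from_food(45, 0), 8.0865)
  expect_error(half_time_from_food(10, 50), "invalid half-time")
  expect_error(half_time_from_food(0, 1), "> 0")
  # published half-times ship as named constants
  expect_equal(mida_half_times[["rice_starch"]], 2.14)
  expect_equal(mida_half_times[["rice_cream"]], 3.17)
  expect_equal(mida_emptying_horizons[["rice_starch"]], 20)
  expect_equal(mida_emptying_horizons[["rice_cream"]], 28)
})

test_that("model-derived schedules conserve the gastric volume exactly", {
  set.seed(22)
  for (i in 1:20) {
    p <- emptying_params(T_half_min = stats::runif(1, 0.5, 10),
                         V_gastric_ml = stats::runif(1, 10, 200),
                         beta = stats::runif(1, 0.5, 3))
    s <- build_pulse_schedule(p)
    expect_equal(schedule_total_volume(s), p$V_gastric_ml, tolerance = 1e-12)
  }
  # per-pulse volumes shrink as the curve flattens
  s <- build_pulse_schedule(emptying_params(2.14, 80))
  expect_true(all(diff(s$rows$per_pulse_volume_ml) < 0))
})

test_that("published pulse-volume fixtures are reproduced verbatim", {
  rs <- load_schedule_fixture("rice_starch")
  expect_equal(rs$rows$per_pulse_volume_ml, c(6.22, 2.36, 0.608, 0.034))
  expect_equal(rs$rows$interval_start_min, c(0, 2, 4, 8))
  expect_equal(rs$rows$n_pulses, c(8L, 8L, 16L, 48L))
  expect_equal(schedule_total_volume(rs), 80.0)

  rc <- load_schedule_fixture("rice_cream")
  expect_equal(rc$rows$per_pulse_volume_ml[1], 4.2)
  expect_equal(rc$rows$per_pulse_volume_ml[4], 0.024)
  expect_equal(rc$rows$interval_end_min[4], 28)
  expect_equal(schedule_total_volume(rc), 80.256)

  expect_error(load_schedule_fixture("porridge"), "unknown food class")
})

test_that("refined schedules converge to the continuous emptying curve", {
  V <- 80; th <- 2.14; beta <- 1.5
  # fine piecewise grid, one pulse per 0.002-min interval; a pulse at time
  # tau delivers the chyme the curve releases over [tau, tau + dt)
  dt <- 0.002
  p <- emptying_params(th, V, beta,
                       interval_bounds_min = seq(0, 20, by = dt),
                       pulse_interval_s = dt * 60)
  s <- build_pulse_schedule(p)
  set.seed(23)
  t_probe <- round(stats::runif(20, 0.5, 19.5) / dt) * dt
  got <- cumulative_delivered(s, t_probe + dt / 2)
  want <- V * (1 - fraction_remaining(t_probe + dt, th, beta))
  expect_true(all(abs(got - want) <= 1e-6 * V))

  # at arbitrary probe times the discretization error is O(dt): refining the
  # grid shrinks the worst-case gap to the continuous curve proportionally
  err_at <- function(dt) {
    s <- build_pulse_schedule(emptying_params(
      th, V, beta, interval_bounds_min = seq(0, 20, by = dt),
      pulse_interval_s = dt * 60))
    tt <- seq(0.3, 19.7, length.out = 50)
    mean(abs(cumulative_delivered(s, tt) -
               V * (1 - fraction_remaining(tt, th, beta))))
  }
  expect_lt(err_at(0.002), err_at(0.05) / 10)
})

test_that("schedules round-trip through CSV", {
  s <- build_pulse_schedule(emptying_params(3.17, 80,
                                            interval_bounds_min = c(0, 3, 6, 12, 28)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, path)
  back <- read_schedule_csv(path)
  expect_equal(back$rows$per_pulse_volume_ml, s$rows$per_pulse_volume_ml,
               tolerance = 1e-12)
  expect_equal(back$rows$n_pulses, s$rows$n_pulses)
})
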