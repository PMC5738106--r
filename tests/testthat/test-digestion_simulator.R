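default_food <- function(...) {
  food_spec("test rice cream", 45, starch_g = 1.0, glucose_g = 0.01, ...)
}

default_parts <- function(food, sampling_plan = default_sampling_plan()) {
  sched <- build_pulse_schedule(emptying_params(
    mida_half_times[["rice_cream"]], 80,
    interval_bounds_min = c(0, 3, 6, 12, 28)))
  tl <- build_timeline(food, sampling_plan = sampling_plan, schedule = sched)
  list(schedule = sched, timeline = tl)
}

test_that("default timeline has the protocol's event structure", {
  food <- default_food()
  tl <- default_parts(food)$timeline
  expect_equal(sum(tl$kind == "sample"), 21)
  expect_equal(sum(tl$kind == "sample" & tl$purpose == "gastric"), 8)
  expect_equal(sum(tl$kind == "feed_pulse"), 8)
  expect_equal(range(tl$time_min), c(0, 248))
  # the final gastric sample precedes the first pyloric pulse at t = 122
  at122 <- tl[tl$time_min == 122, ]
  expect_equal(at122$kind[1], "sample")
  expect_equal(at122$kind[2], "pyloric_pulse")

  # empty sampling plan removes sample events and nothing else
  sp0 <- default_sampling_plan()[0, ]
  tl0 <- build_timeline(food, volume_plan = plan_fluid_volumes(45, 10, 8, 10),
                        sampling_plan = sp0,
                        schedule = default_parts(food)$schedule)
  expect_equal(sum(tl0$kind == "sample"), 0)
  expect_equal(sum(tl0$kind == "feed_pulse"), sum(tl$kind == "feed_pulse"))
  expect_equal(sum(tl0$kind == "pyloric_pulse"),
               sum(tl$kind == "pyloric_pulse"))
})

test_that("zero kinetics leave concentrations constant everywhere", {
  food <- default_food()
  parts <- default_parts(food)
  ts <- simulate_digestion(food, parts$timeline,
                           kinetic_params(k_oral = 0, k_intestinal = 0))
  # on the food-equivalent basis, constant concentration means every record
  # repeats the baseline masses
  expect_true(all(abs(ts$starch_g - food$starch_g) < 1e-12))
  expect_true(all(abs(ts$glucose_g - food$glucose_g) < 1e-12))
})

test_that("gastric starch is exactly flat across the 8 gastric samples", {
  food <- default_food()
  parts <- default_parts(food)
  ts <- simulate_digestion(food, parts$timeline,
                           kinetic_params(k_oral = 0.7, k_intestinal = 0.05))
  gas <- ts$starch_g[ts$purpose == "gastric"]
  expect_length(gas, 8)
  expect_true(all(abs(gas - gas[1]) < 1e-12))
  # and equal to the post-oral concentration (salivary amylase inactivated)
  oral <- ts$starch_g[ts$purpose == "oral"]
  expect_equal(gas[1], oral, tolerance = 1e-12)
  # starch concentration never increases between inflow events
  expect_true(all(diff(ts$starch_g[ts$compartment == "intestinal"]) < 1e-12))
})

test_that("volume and starch-equivalent mass are conserved exactly", {
  food <- default_food(glucogenic_pool_g = 0.2)
  parts <- default_parts(food)
  kin <- kinetic_params(k_oral = 0.9, k_intestinal = 0.3, k_gastric = 0.01)
  ts <- simulate_digestion(food, parts$timeline, kin)
  fs <- attr(ts, "final_state")
  wd <- attr(ts, "withdrawn")
  held_V <- sum(vapply(fs[c("oral", "gastric", "intestinal")],
                       function(s) s[["V"]], numeric(1)))
  expect_equal(held_V + wd[["V"]], attr(ts, "added_volume_ml"),
               tolerance = 1e-12)
  # starch equivalents: S + P + G / yield is invariant under hydrolysis
  se <- function(s) s[["S"]] + s[["P"]] + s[["G"]] / kin$glucose_yield
  held <- sum(vapply(fs[c("oral", "gastric", "intestinal")], se, numeric(1)))
  drawn <- wd[["S"]] + wd[["P"]] + wd[["G"]] / kin$glucose_yield
  scale <- food$portion_volume_ml / food$aliquot_ml
  initial <- (food$starch_g + food$glucogenic_pool_g +
                food$glucose_g / kin$glucose_yield) * scale
  expect_equal(held + drawn, initial, tolerance = 1e-9)
})

test_that("infeasible withdrawals abort with the event time", {
  food <- default_food()
  sp <- default_sampling_plan()
  sp$sample_volume_ml[sp$purpose == "oral"] <- 200
  # a feasible-looking plan whose sampling events overdraw at run time
  tl <- build_timeline(food, volume_plan = plan_fluid_volumes(45, 10, 8, 10),
                       sampling_plan = sp,
                       schedule = default_parts(food)$schedule)
  expect_error(
    simulate_digestion(food, tl,
                       kinetic_params(k_oral = 0.7, k_intestinal = 0.05)),
    "infeasible withdrawal at t=2")
})

test_that("first-order rates are recovered from decay records", {
  # exact recovery from a noiseless exponential table
  tab <- make_decay_table(0.2, 1.5, times = seq(0, 15, by = 1.5))
  fit <- fit_first_order_kinetics(tab, "intestinal")
  expect_equal(fit$rate, 0.2, tolerance = 1e-6)

  # exact recovery from the simulator's post-emptying intestinal tail
  food <- default_food()
  parts <- default_parts(food)
  ts <- simulate_digestion(food, parts$timeline,
                           kinetic_params(k_oral = 0.7, k_intestinal = 0.08))
  fit2 <- fit_first_order_kinetics(ts, "intestinal", window = c(152, 242),
                                   n_boot = 0)
  expect_equal(fit2$rate, 0.08, tolerance = 1e-9)

  # a flat phase yields a rate not significantly different from zero
  set.seed(31)
  flat <- make_decay_table(0, 0.5, times = seq(0, 120, by = 15))
  flat$starch_g <- flat$starch_g * exp(stats::rnorm(nrow(flat), 0, 0.05))
  fit3 <- fit_first_order_kinetics(flat, "intestinal", n_boot = 0)
  expect_lt(fit3$ci[1], 0)
  expect_gt(fit3$ci[2], 0)

  zero <- make_decay_table(0, 0, times = 0:5)
  expect_error(fit_first_order_kinetics(zero, "intestinal"), "nothing to fit")
})
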