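test_that("degree of conversion matches the published worked examples", {
  expect_equal(conversion_degree(1.309, 0.317), 75.78, tolerance = 0.0005)
  expect_equal(conversion_degree(0.411, 0.202), 50.85, tolerance = 0.0005)
  expect_equal(conversion_degree(0.7, 0.7), 0)
  expect_warning(out <- conversion_degree(1, 1.2), "negative conversion")
  expect_equal(out, -20)
  expect_error(conversion_degree(0, 0.1), "> 0")
})

test_that("released glucose is a baseline subtraction, never clipped", {
  expect_equal(glucose_released(0.004, 0.004), 0)
  expect_equal(glucose_released(0.750, 0.004), 0.746)
  expect_warning(out <- glucose_released(0.2, 0.5), "negative released")
  expect_equal(out, -0.3)
  expect_error(glucose_released(-0.1, 0), ">= 0")
})

test_that("%SH uses the 0.9 stoichiometric constant and may exceed 100%", {
  expect_equal(starch_hydrolysis_pct(0.632, 0.411), 138.40, tolerance = 5e-5)
  expect_equal(starch_hydrolysis_pct(0, 1), 0)
  # printed 7.89%; the 0.02-point gap is rounding of the printed inputs
  expect_equal(starch_hydrolysis_pct(0.115, 1.309), 7.91, tolerance = 5e-4)
  expect_warning(starch_hydrolysis_pct(-0.01, 1), "negative")
  expect_error(starch_hydrolysis_pct(0.1, 0), "> 0")
})

test_that("metrics tables apply the definitions per timepoint", {
  ts <- generate_experiment(digestion_preset("rice_cream_basic",
                                             replicates = 2),
                            noise_model(assay_cv = 0))
  m <- metrics_table(ts, s_i_source = "at_dissolution")
  per <- m$per_sample
  # flat gastric series gives a constant gastric conversion
  gas <- per$conversion_pct[per$purpose == "gastric" & per$replicate == 1]
  expect_length(gas, 8)
  expect_true(all(abs(gas - gas[1]) < 1e-9))
  # stoichiometric ceiling: with no glucogenic pool %SH is capped at 100
  expect_true(all(per$sh_pct <= 100 + 1e-9))
  # noiseless, glucogenic-free run: %SH equals the conversion degree exactly
  expect_equal(per$sh_pct, per$conversion_pct, tolerance = 1e-9)

  # a glucogenic pool pushes the final %SH beyond 100%
  tsp <- generate_experiment(digestion_preset("rice_cream_premium",
                                              replicates = 1),
                             noise_model(assay_cv = 0))
  mp <- metrics_table(tsp, s_i_source = "at_dissolution")
  expect_gt(max(mp$per_sample$sh_pct), 100)

  # missing baseline record errors
  expect_error(metrics_table(ts[ts$time_min > 0, ]), "no t=0 record")
  # explicit S_i convention
  me <- metrics_table(ts, s_i_source = "explicit", s_i = 1.309, g_0 = 0.004)
  expect_equal(me$per_sample$conversion_pct, per$conversion_pct,
               tolerance = 1e-12)
})

test_that("metrics are invariant to record order and replicate relabeling", {
  ts <- generate_experiment(digestion_preset("rice_cream_basic",
                                             replicates = 3),
                            noise_model(assay_cv = 0.1, seed = 7))
  m1 <- metrics_table(ts, s_i_source = "at_dissolution")
  set.seed(41)
  shuffled <- ts[sample(nrow(ts)), ]
  shuffled$replicate <- c(3L, 1L, 2L)[shuffled$replicate]
  m2 <- metrics_table(shuffled, s_i_source = "at_dissolution")
  expect_equal(m2$summary$conversion_mean_pct, m1$summary$conversion_mean_pct)
  expect_equal(m2$summary$starch_sd_g, m1$summary$starch_sd_g)
})

test_that("replicate comparison handles identical and degenerate groups", {
  mk <- function(v) data.frame(time_min = 137, replicate = seq_along(v),
                               starch_g = v)
  same <- compare_groups(mk(c(0.2, 0.3, 0.25)), mk(c(0.2, 0.3, 0.25)), 137)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  degen <- compare_groups(mk(c(0, 0, 0)), mk(c(1, 1, 1)), 137)
  expect_true(degen$zero_variance)
  expect_lte(degen$p_value, .Machine$double.eps)
  expect_true(degen$sig01)

  expect_error(compare_groups(mk(0.2), mk(c(0.1, 0.2)), 137),
               ">= 2 replicates")
})

test_that("the t-test keeps its nominal type-I error under the null", {
  set.seed(42)
  n_sim <- 10000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    a <- data.frame(time_min = 0, replicate = 1:3, starch_g = rnorm(3))
    b <- data.frame(time_min = 0, replicate = 1:3, starch_g = rnorm(3))
    if (compare_groups(a, b, 0)$sig05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_sim, 0.04)
  expect_lte(rejections / n_sim, 0.06)
})
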