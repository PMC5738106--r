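test_that("50:50 volume planner reproduces the reference infant protocol", {
  p <- plan_fluid_volumes(45, 10, 8, 10)
  expect_equal(p$ssf_ml, 45)
  expect_equal(p$sgf_ml, 80)
  expect_equal(p$sif_ml, 80)
  expect_equal(p$gastric_total_ml, 160)
  expect_equal(p$chyle_final_ml, 160)

  # sampling-free mass balance doubles the stream at every stage
  p0 <- plan_fluid_volumes(45, 0, 0, 0)
  expect_equal(p0$sgf_ml, 90)
  expect_equal(p0$sif_ml, 180)
  expect_equal(p0$chyle_final_ml, 360)

  # empty protocol
  pe <- plan_fluid_volumes(0, 0, 0, 0)
  expect_true(all(unlist(pe) == 0))
})

test_that("doubling law holds for any sampling-free plan", {
  set.seed(11)
  for (v in stats::runif(20, 1, 500)) {
    p <- plan_fluid_volumes(v, 0, 0, 0)
    expect_equal(p$ssf_ml, v)
    expect_equal(p$sgf_ml, 2 * v)
    expect_equal(p$gastric_total_ml, 4 * v)
    expect_equal(p$sif_ml, 4 * v)
    expect_equal(p$chyle_final_ml, 8 * v)
  }
})

test_that("over-drawn sampling plans fail naming the compartment", {
  expect_error(plan_fluid_volumes(45, 100, 0, 0), "oral")
  expect_error(plan_fluid_volumes(45, 10, 20, 10), "gastric")
  expect_error(plan_fluid_volumes(45, -1, 0, 0), ">= 0")
})

test_that("fluid recipes match the tabulated compositions", {
  ssf <- make_fluid_recipe("SSF", "rice_starch")
  expect_equal(ssf$electrolyte_stock_ml, 31.5)
  amy <- ssf$components[ssf$components$component == "salivary alpha-amylase", ]
  expect_equal(amy$amount, 0.675)
  expect_equal(amy$activity, 75)
  expect_equal(ssf$cacl2_ml, 0.225)
  expect_equal(ssf$hcl_1M_ml, 0.2)
  expect_equal(ssf$target_pH, 7)

  sgf_b <- make_fluid_recipe("SGF", "rice_cream_basic")
  pep <- sgf_b$components[sgf_b$components$component == "pepsin", ]
  expect_equal(pep$amount, 47.33)
  expect_equal(pep$unit, "mg")
  expect_equal(pep$activity, 1000)
  expect_equal(sgf_b$hcl_1M_ml, 1.945)
  expect_equal(sgf_b$target_pH, 3)

  # gastric pepsin is not needed for the low-protein isolated rice starch
  sgf_s <- make_fluid_recipe("SGF", "rice_starch")
  expect_equal(nrow(sgf_s$enzymes), 0)

  expect_error(make_fluid_recipe("SXF", "rice_starch"), "unknown fluid")
  expect_error(make_fluid_recipe("SSF", "polenta"), "unknown food class")
})

test_that("recipe component volumes never exceed the fluid volume", {
  for (fl in c("SSF", "SGF", "SIF"))
    for (fc in c("rice_starch", "rice_cream_basic", "rice_cream_premium")) {
      r <- make_fluid_recipe(fl, fc)
      vols <- r$components$amount[r$components$unit == "ml"]
      expect_lte(sum(vols), r$water_to_volume_ml)
    }
})

test_that("electrolyte stocks sum to the 400-ml solution volume", {
  es <- electrolyte_stocks()
  expect_equal(sum(es$ssf_ml), 400)
  expect_equal(sum(es$sgf_ml), 400)
  expect_equal(sum(es$sif_ml), 400)
})

test_that("recipes round-trip through the CSV writer/reader", {
  r <- make_fluid_recipe("SIF", "rice_cream_premium")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recipe_csv(r, path)
  back <- read_recipe_csv(path)
  expect_equal(back$component, r$components$component)
  expect_equal(back$amount, r$components$amount)
  expect_equal(back$unit, r$components$unit)
})

test_that("pancrelipase dosing scales enzymes by the capsule composition", {
  d <- dose_pancrelipase(7.695, 1000, 10000, 8000, 600)
  expect_equal(unname(d["lipase_U"]), 7695)
  expect_equal(unname(d["amylase_U"]), 6156)
  # capsule-ratio protease; the printed 770 U is kept as a separate,
  # documented discrepancy constant and never asserted equal
  expect_equal(unname(d["protease_U"]), 461.7)
  expect_equal(creon_printed_protease_U, 770)
  expect_error(dose_pancrelipase(0), "> 0")
  expect_error(dose_pancrelipase(-2), "> 0")
})

test_that("glucoamylase activity follows the 0.11 duodenal ratio", {
  expect_equal(glucoamylase_activity(170.5), 18.755)
  expect_equal(glucoamylase_activity(0), 0)
  expect_equal(glucoamylase_activity(100), 11)
  expect_error(glucoamylase_activity(-1), ">= 0")
})

test_that("default sampling plan has the 21-sample structure", {
  sp <- default_sampling_plan()
  expect_equal(nrow(sp), 21)
  expect_equal(sum(sp$purpose == "baseline"), 1)
  expect_equal(sum(sp$purpose == "oral"), 1)
  expect_equal(sum(sp$purpose == "gastric"), 8)
  expect_equal(sum(sp$purpose %in% c("intestinal", "drain")), 11)
  expect_true(all(diff(sp$time_min) > 0))
})
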