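#!/usr/bin/env Rscript
# Protocol planning: fluid volumes under the 50:50 mixing rule, simulated-
# fluid recipes, and pancreatic enzyme doses for the reference infant meal.
#
# Findings: a 45-ml portion needs 45 ml SSF, 80 ml SGF (10 ml of bolus is
# sampled before gastric entry) and 80 ml SIF (half the gastric content is
# sampled), ending with 160 ml of chyle; the 7.695-kg reference infant gets
# 7695 lipase U and 6156 amylase U of pancrelipase per meal.

suppressPackageStartupMessages(library(midasim))
dir.create("results", showWarnings = FALSE)

plan <- plan_fluid_volumes(45, oral_sample_ml = 10, n_gastric_samples = 8,
                           gastric_sample_ml = 10)
print(plan)
write_plan_json(plan, "results/volume_plan.json")

cat("\nSimulated-fluid recipes (written to results/recipes.csv):\n")
recipes <- do.call(rbind, lapply(
  c("rice_starch", "rice_cream_basic", "rice_cream_premium"),
  function(fc) do.call(rbind, lapply(c("SSF", "SGF", "SIF"), function(fl) {
    r <- make_fluid_recipe(fl, fc)
    cbind(food_class = fc, fluid = fl, r$components)
  }))))
write.csv(recipes, "results/recipes.csv", row.names = FALSE, na = "")
cat(sprintf("  %d component rows; SGF carries pepsin only for rice cream\n",
            nrow(recipes)))

doses <- dose_pancrelipase(7.695)
cat(sprintf("\nPancrelipase dose for 7.695 kg at 1000 lipase U/kg/meal:\n"))
cat(sprintf("  lipase %.0f U, amylase %.0f U, protease %.1f U (capsule ratio;\n",
            doses["lipase_U"], doses["amylase_U"], doses["protease_U"]))
cat(sprintf("  the published protocol prints %g U protease, an internal\n",
            creon_printed_protease_U))
cat("  inconsistency with its own capsule composition)\n")
cat(sprintf("\nDuodenal glucoamylase activity at 170.5 U/ml amylase: %.3f U/ml\n",
            glucoamylase_activity(170.5)))

sp <- default_sampling_plan()
write.csv(sp, "results/sampling_plan.csv", row.names = FALSE)
cat(sprintf("\nSampling plan: %d events (%s)\n", nrow(sp),
            paste(names(table(sp$purpose)), table(sp$purpose),
                  sep = "=", collapse = ", ")))
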