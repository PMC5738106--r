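#!/usr/bin/env Rscript
# Noiseless digestion runs of the four reference foods through the full
# discrete-event mass balance, checking the calibrated conversion endpoints.
#
# Findings: gastric starch is exactly flat (no gastric amylolysis by
# construction), and the calibrated kinetics reproduce the published oral
# conversion degrees (71.43 / 87.5 / 75.78 / 50.85 %) and, for the rice
# creams, the conversion at the first intestinal sample (86.32 / 98.29 %).
# The premium food's glucogenic pool drives its final %SH beyond 100%.

suppressPackageStartupMessages(library(midasim))
dir.create("results", showWarnings = FALSE)

foods <- c("rice_starch_classical", "rice_starch_htst",
           "rice_cream_basic", "rice_cream_premium")
summary_rows <- list()
for (fc in foods) {
  design <- digestion_preset(fc, replicates = 1)
  ts <- generate_experiment(design, noise_model(assay_cv = 0))
  write_timeseries_csv(ts, sprintf("results/run_noiseless_%s.csv", fc))
  m <- metrics_table(ts, s_i_source = design$s_i_source)$per_sample
  pick <- function(t, col) m[abs(m$time_min - t) < 1e-8, col][1]
  gas <- m$starch_g[m$purpose == "gastric"]
  summary_rows[[fc]] <- data.frame(
    food = fc,
    k_oral = round(design$kinetics$k_oral, 4),
    k_intestinal = round(design$kinetics$k_intestinal, 4),
    oral_conv_pct = round(pick(2, "conversion_pct"), 2),
    conv_137_pct = round(pick(137, "conversion_pct"), 2),
    conv_248_pct = round(pick(248, "conversion_pct"), 2),
    sh_final_pct = round(pick(248, "sh_pct"), 2),
    gastric_flat = max(gas) - min(gas) < 1e-12)
}
endpoints <- do.call(rbind, summary_rows)
print(endpoints, row.names = FALSE)
write.csv(endpoints, "results/endpoints_noiseless.csv", row.names = FALSE)
cat("\nCalibration anchors: oral conversions and (rice creams) conversion at\n")
cat("137 min; rice-starch intestinal rates are fixed choices, no anchor.\n")
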