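#!/usr/bin/env Rscript
# Synthetic triplicate experiments with 10% assay CV, summarized through the
# digestion metrics: conversion degree, released D-glucose and %SH.
#
# Findings: with triplicates at CV = 0.10 the per-timepoint means track the
# noiseless trajectories, and the basic product's intestinal rate is
# recovered from the post-emptying decay tail within a few percent. The
# premium product hydrolyzes so fast that its starch falls below the 1-mg
# detection floor before the post-emptying window, so its rate cannot be
# recovered from the sampled tail — floored records carry no slope.

suppressPackageStartupMessages(library(midasim))
dir.create("results", showWarnings = FALSE)

for (fc in c("rice_cream_basic", "rice_cream_premium")) {
  design <- digestion_preset(fc, replicates = 3)
  ts <- generate_experiment(design, noise_model(assay_cv = 0.10, seed = 20260918))
  m <- metrics_table(ts, s_i_source = design$s_i_source)
  write_metrics_csv(m, sprintf("results/metrics_%s.csv", fc))
  cat(sprintf("\n== %s (3 replicates, CV 0.10) ==\n", fc))
  show <- m$summary[m$summary$time_min %in% c(0, 2, 122, 137, 248),
                    c("time_min", "compartment", "starch_mean_g",
                      "starch_sd_g", "conversion_mean_pct", "sh_mean_pct")]
  print(show, row.names = FALSE, digits = 4)
  if (fc == "rice_cream_basic") {
    fit <- fit_first_order_kinetics(ts, "intestinal", window = c(152, 242))
    cat(sprintf("recovered k_intestinal %.4f /min (true %.4f, 95%% CI %.4f-%.4f)\n",
                fit$rate, design$kinetics$k_intestinal, fit$ci[1], fit$ci[2]))
  } else {
    cat("k_intestinal not recoverable from the tail: starch is below the\n")
    cat("detection floor at every post-emptying sample\n")
  }
}
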