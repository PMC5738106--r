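# File-format plumbing shared by all modules: dot-decimal, UTF-8 CSV with a
# header row for tables (source tables mix decimal commas; everything is
# normalized on ingest), JSON for structured plans and run metadata.

#' Write / read a digestion time series as CSV
#'
#' Columns: `time_min`, `compartment`, `sample_volume_ml`, `starch_g`,
#' `glucose_g`, `purpose`, `replicate`. Values round-trip to full double
#' precision.
#'
#' @param ts Time-series data frame.
#' @param path File path.
#' @return `write_timeseries_csv` returns `path` invisibly;
#'   `read_timeseries_csv` returns the data frame.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(format(as.data.frame(ts), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("time_min", "sample_volume_ml", "starch_g", "glucose_g")
  for (cl in intersect(num, names(d))) d[[cl]] <- as.numeric(d[[cl]])
  if ("replicate" %in% names(d)) d$replicate <- as.integer(d$replicate)
  class(d) <- c("sim_timeseries", "data.frame")
  d
}

#' Write / read a pulse schedule as CSV
#'
#' Columns: `interval_start_min`, `interval_end_min`, `per_pulse_volume_ml`,
#' `n_pulses`.
#' @param schedule A `pulse_schedule`.
#' @param path File path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  utils::write.csv(format(schedule$rows, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path, pulses_per_min = 4) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in names(r)) r[[cl]] <- as.numeric(r[[cl]])
  .new_pulse_schedule(r$interval_start_min, r$interval_end_min,
                      r$per_pulse_volume_ml, r$n_pulses, pulses_per_min,
                      source = "file")
}

#' Write / read a fluid recipe as a flat CSV
#'
#' One row per component with columns `fluid`, `component`, `amount`,
#' `unit` (plus `activity`, `activity_unit` where tabulated).
#' @param recipe A `fluid_recipe`.
#' @param path File path.
#' @export
write_recipe_csv <- function(recipe, path) {
  stopifnot(inherits(recipe, "fluid_recipe"))
  d <- cbind(fluid = recipe$fluid_name, recipe$components)
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_recipe_csv
#' @export
read_recipe_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$amount <- as.numeric(d$amount)
  if ("activity" %in% names(d)) d$activity <- as.numeric(d$activity)
  d
}

#' Write a volume plan (or any plain list) as JSON
#' @param x A `volume_plan` or named list of scalars.
#' @param path File path.
#' @export
write_plan_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a metrics table (per-sample rows plus a means block) as CSV
#' @param metrics A `digestion_metrics` object.
#' @param path File path for the per-sample rows; the summary goes to
#'   `sub(".csv", "_summary.csv", path)`.
#' @export
write_metrics_csv <- function(metrics, path) {
  stopifnot(inherits(metrics, "digestion_metrics"))
  utils::write.csv(metrics$per_sample, path, row.names = FALSE)
  utils::write.csv(metrics$summary, sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline: plan, schedule, simulate, metrics, compare
#'
#' Executes the whole protocol for one or more preset foods: fluid-volume
#' plan, fluid recipes, pulse schedule, replicated synthetic run, metrics
#' table, and (for exactly two foods) per-timepoint replicate comparisons.
#' Writes every artifact under `out_dir` together with a JSON manifest of
#' inputs, package version, seed and MD5 hashes for reproducibility.
#'
#' @param foods Character vector of preset names (see [digestion_preset()]).
#' @param out_dir Output directory (created if missing).
#' @param replicates Replicates per food (default 3).
#' @param assay_cv Assay CV for the synthetic noise (default 0.10).
#' @param seed Integer seed.
#' @param schedule_source `"model"` or `"fixture"`.
#' @return The manifest (a list), invisibly.
#' @export
run_pipeline <- function(foods, out_dir, replicates = 3, assay_cv = 0.10,
                         seed = 1L, schedule_source = "model") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  runs <- list()
  n_records <- 0L
  for (i in seq_along(foods)) {
    fc <- foods[i]
    design <- digestion_preset(fc, replicates = replicates,
                               schedule_source = schedule_source)
    parts <- design_timeline(design)
    f <- function(name) file.path(out_dir, paste0(fc, "_", name))
    write_plan_json(parts$volume_plan, f("plan.json"))
    recipes <- do.call(rbind, lapply(c("SSF", "SGF", "SIF"), function(fl) {
      r <- make_fluid_recipe(fl, fc)
      cbind(fluid = fl, r$components)
    }))
    utils::write.csv(recipes, f("recipes.csv"), row.names = FALSE, na = "")
    write_schedule_csv(parts$schedule, f("schedule.csv"))
    ts <- generate_experiment(design, noise_model(assay_cv = assay_cv,
                                                  seed = seed + i - 1L))
    write_timeseries_csv(ts, f("run.csv"))
    m <- metrics_table(ts, s_i_source = design$s_i_source)
    write_metrics_csv(m, f("metrics.csv"))
    runs[[fc]] <- ts
    n_records <- n_records + nrow(ts)
    files <- c(files, f("plan.json"), f("recipes.csv"), f("schedule.csv"),
               f("run.csv"), f("metrics.csv"),
               f("metrics_summary.csv"))
  }
  if (length(foods) == 2) {
    a <- runs[[1]]; b <- runs[[2]]
    tp <- intersect(unique(a$time_min), unique(b$time_min))
    comp <- do.call(rbind, lapply(tp, function(t) {
      g <- compare_groups(a, b, t, value = "starch_g")
      data.frame(time_min = t, mean_A = g$mean_A, sd_A = g$sd_A,
                 mean_B = g$mean_B, sd_B = g$sd_B, t = g$t_statistic,
                 p = g$p_value, sig05 = g$sig05, sig01 = g$sig01)
    }))
    cmp_path <- file.path(out_dir, "comparison.csv")
    utils::write.csv(comp, cmp_path, row.names = FALSE)
    files <- c(files, cmp_path)
  }
  manifest <- list(
    foods = foods, replicates = replicates, assay_cv = assay_cv,
    seed = seed, schedule_source = schedule_source,
    n_records = n_records,
    package_version = as.character(utils::packageVersion("midasim")),
    r_version = R.version.string,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
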