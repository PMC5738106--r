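# Digestion metrics on a time series: degree of starch conversion,
# D-glucose released relative to the pre-digestion baseline, and the
# percentage of starch hydrolysis with its 0.9 anhydroglucose/glucose
# stoichiometric constant. A replicate t-test compares two foods at a
# timepoint.

#' Degree of starch conversion
#'
#' `100 * (S_initial - S_t) / S_initial`: the percentage of the initial
#' starch no longer measurable as starch at time t.
#'
#' @param S_initial_g Initial starch mass (g, > 0).
#' @param S_t_g Starch mass at time t (g, >= 0; vectorized). Values above
#'   `S_initial_g` (measurement noise) yield a negative conversion with a
#'   warning, never clipping.
#' @return Conversion (percent).
#' @examples
#' conversion_degree(1.309, 0.317) # 75.78 %
#' @export
conversion_degree <- function(S_initial_g, S_t_g) {
  if (S_initial_g <= 0) stop("S_initial_g must be > 0", call. = FALSE)
  if (any(S_t_g < 0)) stop("S_t_g must be >= 0", call. = FALSE)
  if (any(S_t_g > S_initial_g))
    warning("starch above initial value: negative conversion (assay noise?)",
            call. = FALSE)
  100 * (S_initial_g - S_t_g) / S_initial_g
}

#' D-glucose released relative to the pre-digestion baseline
#'
#' `G_t - G_0`, the free glucose beyond what the prepared food already
#' carried at t = 0. Negative values (noise) are preserved with a warning.
#'
#' @param G_t_g Glucose at time t (g, >= 0; vectorized).
#' @param G_0_g Baseline glucose at t = 0 (g, >= 0).
#' @return Released glucose (g).
#' @export
glucose_released <- function(G_t_g, G_0_g) {
  if (any(G_t_g < 0) || G_0_g < 0) stop("masses must be >= 0", call. = FALSE)
  out <- G_t_g - G_0_g
  if (any(out < 0))
    warning("negative released glucose (assay noise?)", call. = FALSE)
  out
}

#' Percentage of starch hydrolysis
#'
#' `%SH = 100 * 0.9 * G_R / S_i`: released glucose expressed as the fraction
#' of initial starch it accounts for, via the 0.9 stoichiometric constant
#' (hydrolysis adds one water per anhydroglucose unit, so 0.9 g of starch
#' yields 1 g of glucose). May exceed 100% when glucose derives partly from
#' non-starch saccharides, as for fermented foods.
#'
#' @param G_released_g Released D-glucose (g; vectorized). Negative values
#'   warn and are preserved.
#' @param S_initial_g Initial starch (g, > 0).
#' @return Percent starch hydrolysis.
#' @examples
#' starch_hydrolysis_pct(0.632, 0.411) # 138.39 % (exceeds 100)
#' @export
starch_hydrolysis_pct <- function(G_released_g, S_initial_g) {
  if (S_initial_g <= 0) stop("S_initial_g must be > 0", call. = FALSE)
  if (any(G_released_g < 0))
    warning("negative released glucose: negative %SH preserved", call. = FALSE)
  100 * 0.9 * G_released_g / S_initial_g
}

#' Per-timepoint digestion metrics of a time series
#'
#' Applies the conversion-degree, released-glucose and %SH definitions at
#' every timepoint of every replicate, plus a means/SD summary per
#' timepoint. The baseline (t = 0) record of each replicate supplies `S_i`
#' and `G_0` unless `S_i` is given explicitly; the `s_i_source` label
#' records which convention the baseline followed (starch foods measure
#' `S_i` before sterilization, rice-cream foods after dissolving the cream).
#'
#' @param ts Data frame with `time_min`, `compartment`, `starch_g`,
#'   `glucose_g`, `replicate` (e.g. from [simulate_digestion()] or
#'   [generate_experiment()]).
#' @param s_i_source One of `"pre_treatment"`, `"at_dissolution"`,
#'   `"explicit"`.
#' @param s_i,g_0 Explicit initial starch / baseline glucose (g); required
#'   when `s_i_source = "explicit"`, otherwise taken per replicate from the
#'   t = 0 record.
#' @return A `digestion_metrics` list: `$per_sample` (one row per timepoint
#'   per replicate with `conversion_pct`, `glucose_released_g`, `sh_pct`),
#'   `$summary` (per-timepoint means and SDs across replicates), `$s_i`,
#'   `$g_0`, `$s_i_source`.
#' @export
metrics_table <- function(ts, s_i_source = c("pre_treatment",
                                             "at_dissolution", "explicit"),
                          s_i = NULL, g_0 = NULL) {
  s_i_source <- match.arg(s_i_source)
  ts <- as.data.frame(ts)
  ts <- ts[order(ts$replicate, ts$time_min), , drop = FALSE]
  reps <- sort(unique(ts$replicate))
  if (s_i_source == "explicit") {
    if (is.null(s_i)) stop("explicit s_i_source requires s_i", call. = FALSE)
    s_i_rep <- stats::setNames(rep(s_i, length(reps)), reps)
    g_0_rep <- stats::setNames(rep(if (is.null(g_0)) 0 else g_0,
                                   length(reps)), reps)
  } else {
    base <- ts[ts$time_min == 0, , drop = FALSE]
    if (nrow(base) == 0) stop("no t=0 record", call. = FALSE)
    s_i_rep <- stats::setNames(base$starch_g[match(reps, base$replicate)],
                               reps)
    g_0_rep <- stats::setNames(base$glucose_g[match(reps, base$replicate)],
                               reps)
    if (any(is.na(s_i_rep))) stop("no t=0 record", call. = FALSE)
  }
  per <- ts
  key <- as.character(per$replicate)
  per$s_i <- unname(s_i_rep[key])
  per$g_0 <- unname(g_0_rep[key])
  per$conversion_pct <- 100 * (per$s_i - per$starch_g) / per$s_i
  per$glucose_released_g <- per$glucose_g - per$g_0
  per$sh_pct <- 100 * 0.9 * per$glucose_released_g / per$s_i
  tp <- sort(unique(per$time_min))
  summ <- do.call(rbind, lapply(tp, function(t) {
    d <- per[per$time_min == t, , drop = FALSE]
    data.frame(time_min = t, compartment = d$compartment[1],
               n = nrow(d),
               starch_mean_g = mean(d$starch_g),
               starch_sd_g = stats::sd(d$starch_g),
               glucose_mean_g = mean(d$glucose_g),
               glucose_sd_g = stats::sd(d$glucose_g),
               conversion_mean_pct = mean(d$conversion_pct),
               conversion_sd_pct = stats::sd(d$conversion_pct),
               sh_mean_pct = mean(d$sh_pct),
               sh_sd_pct = stats::sd(d$sh_pct),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sample = per, summary = summ,
                 s_i = s_i_rep, g_0 = g_0_rep, s_i_source = s_i_source),
            class = "digestion_metrics")
}

#' @export
print.digestion_metrics <- function(x, ...) {
  cat(sprintf("<digestion_metrics> %d timepoints x %d replicates (S_i: %s)\n",
              nrow(x$summary), length(x$s_i), x$s_i_source))
  print(utils::head(x$summary, 5), row.names = FALSE)
  if (nrow(x$summary) > 5) cat(sprintf("  ... %d more timepoints\n",
                                       nrow(x$summary) - 5))
  invisible(x)
}

#' Compare two foods at a timepoint by replicate t-test
#'
#' Two-sided two-sample Student t-test (equal variances, the named method of
#' the protocol; Welch available via `welch = TRUE`) on per-replicate values
#' at one sampling timepoint.
#'
#' @param tsA,tsB Time-series data frames (or `digestion_metrics$per_sample`
#'   tables) with `time_min`, `replicate` and the value column.
#' @param timepoint Sampling time (min) at which to compare.
#' @param value Column to compare (default `"starch_g"`).
#' @param welch Use the Welch unequal-variance test instead (default FALSE).
#' @param alpha Significance levels are always reported at 0.05 and 0.01.
#' @return A `group_comparison` list: `timepoint`, `mean_A`, `sd_A`, `n_A`,
#'   `mean_B`, `sd_B`, `n_B`, `t_statistic`, `p_value`, `sig05`, `sig01`,
#'   `zero_variance` (TRUE when both groups are exactly constant).
#' @export
compare_groups <- function(tsA, tsB, timepoint, value = "starch_g",
                           welch = FALSE, alpha = c(0.05, 0.01)) {
  pick <- function(ts) {
    d <- as.data.frame(ts)
    v <- d[[value]][abs(d$time_min - timepoint) < 1e-8]
    if (length(v) < 2)
      stop(sprintf("need >= 2 replicates per group at t=%g", timepoint),
           call. = FALSE)
    v
  }
  a <- pick(tsA); b <- pick(tsB)
  zero_var <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (zero_var) {
    if (mean(a) == mean(b)) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(mean(a) - mean(b)) * Inf
      p <- .Machine$double.eps # degenerate: certain difference, p below eps
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    tstat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(timepoint = timepoint, value = value,
                 mean_A = mean(a), sd_A = stats::sd(a), n_A = length(a),
                 mean_B = mean(b), sd_B = stats::sd(b), n_B = length(b),
                 t_statistic = tstat, p_value = p,
                 sig05 = p < 0.05, sig01 = p < 0.01,
                 zero_variance = zero_var, welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s at t=%g min\n", x$value, x$timepoint))
  cat(sprintf("  A: %.4g +/- %.4g (n=%d) | B: %.4g +/- %.4g (n=%d)\n",
              x$mean_A, x$sd_A, x$n_A, x$mean_B, x$sd_B, x$n_B))
  cat(sprintf("  %s t = %.4g, p = %.4g%s%s\n",
              if (x$welch) "Welch" else "Student",
              x$t_statistic, x$p_value,
              if (x$sig01) " **" else if (x$sig05) " *" else "",
              if (x$zero_variance) " [zero variance]" else ""))
  invisible(x)
}
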