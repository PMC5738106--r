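# Discrete-event compartmental mass balance of a full digestion run.
# Between events, starch in each well-mixed compartment hydrolyzes by
# first-order kinetics with a closed-form exponential (the kinetics are
# linear, so no numeric integrator is needed); events move volume and
# concentration-proportional mass (feeds, pyloric pulses, sampling
# withdrawals, terminal drains).

#' First-order hydrolysis kinetics of a digestion run
#'
#' Starch decays as `dS/dt = -k_c S` in compartment `c`, and free glucose
#' grows as `dG/dt = +glucose_yield * k_c * S`. Salivary amylase acts only
#' during the 2-min oral hold (it is inactivated by gastric acid), gastric
#' amylolysis is absent (`k_gastric = 0`), and the intestinal rate covers
#' pancreatic alpha-amylase plus glucoamylase. The glucogenic pool
#' (non-starch glucose-yielding saccharides) converts only in the intestinal
#' phase.
#'
#' @param k_oral Oral hydrolysis rate (1/min, >= 0).
#' @param k_intestinal Intestinal hydrolysis rate (1/min, >= 0).
#' @param k_gastric Gastric rate (1/min, default 0: no gastric amylolysis).
#' @param glucose_yield Glucose mass produced per starch mass consumed
#'   (default 1/0.9: hydrolysis adds one water per anhydroglucose unit).
#' @param glucogenic_rate Intestinal conversion rate of the glucogenic pool
#'   (1/min; default equal to `k_intestinal`).
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(k_oral, k_intestinal, k_gastric = 0,
                           glucose_yield = 1 / 0.9,
                           glucogenic_rate = k_intestinal) {
  stopifnot(k_oral >= 0, k_intestinal >= 0, k_gastric >= 0,
            glucose_yield > 0, glucogenic_rate >= 0)
  structure(list(k_oral = k_oral, k_gastric = k_gastric,
                 k_intestinal = k_intestinal, glucose_yield = glucose_yield,
                 glucogenic_rate = glucogenic_rate),
            class = "kinetic_params")
}

#' Build the event timeline of a digestion run
#'
#' Lays out the full protocol on a continuous clock: a 2-min oral hold; 10-ml
#' boluses fed with equal SGF volumes every 2 min; gastric phase ending at
#' 122 min; pyloric pulses per the emptying schedule, each matched by an
#' equal SIF volume; and every sampling withdrawal of the sampling plan. At
#' equal timestamps, sampling withdrawals precede transfers (the gastric
#' phase ends with its last sample before emptying begins).
#'
#' @param food A [food_spec()].
#' @param volume_plan A [plan_fluid_volumes()] result (defaults to the plan
#'   for `food`'s portion with the default sampling plan).
#' @param sampling_plan Data frame as from [default_sampling_plan()].
#' @param schedule A `pulse_schedule` for the pyloric phase.
#' @param oral_hold_min Oral incubation time (min, default 2).
#' @param feed_interval_min Minutes between bolus feeds (default 2).
#' @param feed_volume_ml Bolus volume per feed (ml, default 10).
#' @param gastric_end_min Clock time when gastric emptying begins (default
#'   122: 2-min oral phase plus 2-h gastric phase).
#' @return An `event_timeline`: data frame with `time_min`, `kind`
#'   (`sample`, `feed_pulse`, `pyloric_pulse`), `compartment`, `volume_ml`,
#'   `purpose`, ordered by time with withdrawals first at ties.
#' @export
build_timeline <- function(food,
                           volume_plan = NULL,
                           sampling_plan = default_sampling_plan(),
                           schedule,
                           oral_hold_min = 2, feed_interval_min = 2,
                           feed_volume_ml = 10, gastric_end_min = 122) {
  stopifnot(inherits(food, "food_spec"))
  if (is.null(volume_plan)) {
    sp <- sampling_plan
    volume_plan <- plan_fluid_volumes(
      food$portion_volume_ml,
      oral_sample_ml = sum(sp$sample_volume_ml[sp$purpose == "oral"]),
      n_gastric_samples = sum(sp$purpose == "gastric"),
      gastric_sample_ml = if (any(sp$purpose == "gastric"))
        sp$sample_volume_ml[sp$purpose == "gastric"][1] else 0)
  }
  ev <- list()
  if (nrow(sampling_plan) > 0) {
    if (any(diff(sampling_plan$time_min) <= 0))
      stop("sampling plan times must strictly increase", call. = FALSE)
    ev[[length(ev) + 1L]] <- data.frame(
      time_min = sampling_plan$time_min, kind = "sample",
      compartment = sampling_plan$compartment,
      volume_ml = sampling_plan$sample_volume_ml,
      purpose = sampling_plan$purpose, stringsAsFactors = FALSE)
  }
  n_feeds <- volume_plan$gastric_food_input_ml / feed_volume_ml
  if (abs(n_feeds - round(n_feeds)) > 1e-9)
    stop("gastric food input is not a whole number of boluses", call. = FALSE)
  n_feeds <- round(n_feeds)
  if (n_feeds > 0) {
    ev[[length(ev) + 1L]] <- data.frame(
      time_min = oral_hold_min + feed_interval_min * (seq_len(n_feeds) - 1),
      kind = "feed_pulse", compartment = "gastric",
      volume_ml = feed_volume_ml, purpose = "feed", stringsAsFactors = FALSE)
  }
  pulses <- schedule_pulses(schedule, t_offset_min = gastric_end_min)
  ev[[length(ev) + 1L]] <- data.frame(
    time_min = pulses$time_min, kind = "pyloric_pulse",
    compartment = "intestinal", volume_ml = pulses$volume_ml,
    purpose = "transfer", stringsAsFactors = FALSE)
  tl <- do.call(rbind, ev)
  prio <- ifelse(tl$kind == "sample", 1L, 2L)
  tl <- tl[order(tl$time_min, prio), , drop = FALSE]
  rownames(tl) <- NULL
  attr(tl, "oral_hold_min") <- oral_hold_min
  attr(tl, "gastric_end_min") <- gastric_end_min
  attr(tl, "volume_plan") <- volume_plan
  class(tl) <- c("event_timeline", "data.frame")
  tl
}

# advance one compartment's state by dt under rate k (and pool rate kg for
# the intestinal glucogenic pool); exact closed form for linear kinetics
.advance_comp <- function(st, k, kg, yield, dt) {
  if (dt <= 0) return(st)
  if (k > 0 && st[["S"]] > 0) {
    dS <- st[["S"]] * (1 - exp(-k * dt))
    st[["S"]] <- st[["S"]] - dS
    st[["G"]] <- st[["G"]] + yield * dS
  }
  if (kg > 0 && st[["P"]] > 0) {
    dP <- st[["P"]] * (1 - exp(-kg * dt))
    st[["P"]] <- st[["P"]] - dP
    st[["G"]] <- st[["G"]] + yield * dP
  }
  st
}

#' Simulate a digestion run over an event timeline
#'
#' Deterministic forward model: compartments are well mixed; between events
#' starch hydrolyzes by the closed-form exponential; events move volume and
#' proportional mass. Sampling events record the withdrawn aliquot.
#'
#' The default reporting basis, `"food_equivalent"`, expresses each sample
#' as the mass carried per 10 ml of original food equivalent, i.e. corrected
#' for the cumulative 50:50 dilutions, so that the degree-of-conversion and
#' %SH metrics compare like with like across compartments. `"aliquot"`
#' reports the raw masses in the withdrawn volume; `"compartment"` reports
#' whole-compartment masses.
#'
#' @param food A [food_spec()].
#' @param timeline An [build_timeline()] event timeline.
#' @param kinetics A [kinetic_params()].
#' @param basis Reporting basis for sample records (see Details).
#' @param replicate_id Integer replicate label for the output records.
#' @return A `sim_timeseries`: data frame with `time_min`, `compartment`,
#'   `sample_volume_ml`, `starch_g`, `glucose_g`, `purpose`, `replicate`,
#'   plus attributes `final_state`, `withdrawn`, `food`, `kinetics`.
#' @export
simulate_digestion <- function(food, timeline, kinetics,
                               basis = c("food_equivalent", "aliquot",
                                         "compartment"),
                               replicate_id = 1L) {
  stopifnot(inherits(food, "food_spec"), inherits(kinetics, "kinetic_params"))
  basis <- match.arg(basis)
  oral_hold <- attr(timeline, "oral_hold_min")
  if (is.null(oral_hold)) oral_hold <- 2
  aliquot <- food$aliquot_ml
  scale <- food$portion_volume_ml / aliquot

  comp0 <- c(V = 0, F = 0, S = 0, G = 0, P = 0)
  state <- list(
    food = c(V = food$portion_volume_ml, F = food$portion_volume_ml,
             S = food$starch_g * scale, G = food$glucose_g * scale,
             P = food$glucogenic_pool_g * scale),
    oral = c(V = 2 * food$portion_volume_ml, F = food$portion_volume_ml,
             S = food$starch_g * scale, G = food$glucose_g * scale,
             P = food$glucogenic_pool_g * scale),
    gastric = comp0, intestinal = comp0)
  withdrawn <- c(V = 0, S = 0, G = 0, P = 0)
  added_V <- 2 * food$portion_volume_ml # food + SSF

  rate_of <- function(cn, t0) {
    switch(cn,
           oral = if (t0 < oral_hold) kinetics$k_oral else 0,
           gastric = kinetics$k_gastric,
           intestinal = kinetics$k_intestinal,
           0) # the virtual pre-digestion food compartment is inert
  }
  advance_all <- function(state, t0, t1) {
    # split at the end of the oral hold so the oral rate switch is exact
    if (t0 < oral_hold && t1 > oral_hold) {
      state <- advance_all(state, t0, oral_hold)
      t0 <- oral_hold
    }
    dt <- t1 - t0
    if (dt <= 0) return(state)
    for (cn in c("oral", "gastric", "intestinal")) {
      kg <- if (cn == "intestinal") kinetics$glucogenic_rate else 0
      state[[cn]] <- .advance_comp(state[[cn]], rate_of(cn, t0), kg,
                                   kinetics$glucose_yield, dt)
    }
    state
  }

  rec <- vector("list", sum(timeline$kind == "sample"))
  ri <- 0L
  t_now <- 0
  for (i in seq_len(nrow(timeline))) {
    t_ev <- timeline$time_min[i]
    state <- advance_all(state, t_now, t_ev)
    t_now <- t_ev
    kind <- timeline$kind[i]
    cn <- timeline$compartment[i]
    v <- timeline$volume_ml[i]
    if (kind == "sample") {
      st <- state[[cn]]
      if (cn != "food" && v > st[["V"]] + 1e-9)
        stop(sprintf("infeasible withdrawal at t=%g min: %s sample %g ml exceeds %.3f ml",
                     t_ev, cn, v, st[["V"]]), call. = FALSE)
      rec_s <- switch(basis,
        food_equivalent = if (st[["F"]] > 0)
          c(st[["S"]], st[["G"]]) * aliquot / st[["F"]] else c(0, 0),
        aliquot = if (st[["V"]] > 0)
          c(st[["S"]], st[["G"]]) * v / st[["V"]] else c(0, 0),
        compartment = c(st[["S"]], st[["G"]]))
      ri <- ri + 1L
      rec[[ri]] <- data.frame(
        time_min = t_ev, compartment = cn, sample_volume_ml = v,
        starch_g = rec_s[1], glucose_g = rec_s[2],
        purpose = timeline$purpose[i], stringsAsFactors = FALSE)
      if (cn != "food") { # the baseline assay aliquot is virtual
        frac <- v / st[["V"]]
        withdrawn <- withdrawn +
          c(V = v, S = st[["S"]] * frac, G = st[["G"]] * frac,
            P = st[["P"]] * frac)
        st[c("S", "G", "P", "F")] <- st[c("S", "G", "P", "F")] * (1 - frac)
        st[["V"]] <- st[["V"]] - v
        state[[cn]] <- st
      }
    } else if (kind == "feed_pulse") {
      src <- state$oral
      if (v > src[["V"]] + 1e-9)
        stop(sprintf("infeasible feed at t=%g min: bolus %g ml exceeds oral %.3f ml",
                     t_ev, v, src[["V"]]), call. = FALSE)
      frac <- v / src[["V"]]
      moved <- src[c("S", "G", "P", "F")] * frac
      src[c("S", "G", "P", "F")] <- src[c("S", "G", "P", "F")] - moved
      src[["V"]] <- src[["V"]] - v
      state$oral <- src
      dst <- state$gastric
      dst[c("S", "G", "P", "F")] <- dst[c("S", "G", "P", "F")] + moved
      dst[["V"]] <- dst[["V"]] + v + v # bolus plus an equal SGF volume
      state$gastric <- dst
      added_V <- added_V + v # the SGF
    } else if (kind == "pyloric_pulse") {
      src <- state$gastric
      v_eff <- min(v, src[["V"]]) # fixture schedules can overshoot by <0.3 ml
      if (v_eff > 0) {
        frac <- v_eff / src[["V"]]
        moved <- src[c("S", "G", "P", "F")] * frac
        src[c("S", "G", "P", "F")] <- src[c("S", "G", "P", "F")] - moved
        src[["V"]] <- src[["V"]] - v_eff
        state$gastric <- src
        dst <- state$intestinal
        dst[c("S", "G", "P", "F")] <- dst[c("S", "G", "P", "F")] + moved
        dst[["V"]] <- dst[["V"]] + v_eff + v_eff # chyme plus matched SIF
        state$intestinal <- dst
        added_V <- added_V + v_eff # the SIF
      }
    }
    for (cn2 in c("oral", "gastric", "intestinal"))
      if (any(state[[cn2]] < -1e-9))
        stop("internal invariant violation: negative compartment state",
             call. = FALSE)
  }
  out <- do.call(rbind, rec[seq_len(ri)])
  if (is.null(out))
    out <- data.frame(time_min = numeric(), compartment = character(),
                      sample_volume_ml = numeric(), starch_g = numeric(),
                      glucose_g = numeric(), purpose = character(),
                      stringsAsFactors = FALSE)
  out$replicate <- as.integer(replicate_id)
  attr(out, "final_state") <- state
  attr(out, "withdrawn") <- withdrawn
  attr(out, "added_volume_ml") <- added_V
  attr(out, "food") <- food
  attr(out, "kinetics") <- kinetics
  attr(out, "basis") <- basis
  class(out) <- c("sim_timeseries", "data.frame")
  out
}

#' Fit a first-order hydrolysis rate to a phase of a time series
#'
#' Least-squares fit of log starch mass against time within one phase
#' (compartment) of a digestion time series, pooling replicates, with a
#' bootstrap-over-replicates confidence interval. Useful for recovering
#' kinetic constants from simulated, synthetic or measured tables. Records
#' with non-positive starch are dropped (log scale); restrict `window` to
#' the post-emptying tail when fitting the intestinal phase of a full run,
#' since during emptying the compartment is a mixture of entry times.
#'
#' @param ts Data frame with `time_min`, `compartment`, `starch_g`,
#'   `replicate` columns (e.g. a `sim_timeseries`).
#' @param phase Compartment to fit: `"oral"`, `"gastric"` or `"intestinal"`.
#' @param window Optional numeric `c(t_min, t_max)` restricting fitted times.
#' @param n_boot Bootstrap resamples of replicates (default 199).
#' @param conf Confidence level (default 0.95).
#' @return List with `rate` (1/min), `ci` (length-2 vector), `se`,
#'   `n_records`, `phase`.
#' @export
fit_first_order_kinetics <- function(ts, phase, window = NULL, n_boot = 199,
                                     conf = 0.95) {
  d <- ts[ts$compartment == phase, , drop = FALSE]
  if (!is.null(window))
    d <- d[d$time_min >= window[1] & d$time_min <= window[2], , drop = FALSE]
  if (nrow(d) == 0 || all(d$starch_g <= 0))
    stop("nothing to fit: no positive starch records in phase", call. = FALSE)
  d <- d[d$starch_g > 0, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 positive records to fit a rate", call. = FALSE)
  fit_rate <- function(dd) {
    fit <- stats::lm(log(starch_g) ~ time_min, data = dd)
    -unname(stats::coef(fit)[2])
  }
  fit <- stats::lm(log(starch_g) ~ time_min, data = d)
  rate <- -unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  reps <- unique(d$replicate)
  if (length(reps) >= 2 && n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      take <- sample(reps, length(reps), replace = TRUE)
      dd <- do.call(rbind, lapply(take, function(r)
        d[d$replicate == r, , drop = FALSE]))
      fit_rate(dd)
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  } else {
    z <- stats::qt(1 - (1 - conf) / 2, df = stats::df.residual(fit))
    ci <- c(rate - z * se, rate + z * se)
  }
  list(rate = rate, ci = ci, se = se, n_records = nrow(d), phase = phase)
}
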