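# Cohort simulator.
#
# Activity is a two-state (active/inactive) Markov chain over minutes with
# phase-dependent transition probabilities, so bout lengths are geometric:
# mean active run 1/q_ai, mean inactive run 1/q_ia, stationary active
# fraction q_ia/(q_ai + q_ia). Active minutes emit right-skewed positive
# integer counts (1 + negative binomial) with the configured mean.
#
# Temperature is
#   BT_t = baseline(phase_t) + gain * MA30(activity)_t + X_t,
#   X_t  = phi * X_{t-1} + eps_t,
# where eps_t is a zero-mean two-sided half-normal mixture: with
# probability p_up a positive draw of scale sigma_up, otherwise a negative
# draw of scale sigma_down. The mixture is the knob that injects
# rise/fall asymmetry into the Poincare partition. An iid-increment mode
# draws dBT_t from the mixture directly (a random walk), for which the
# asymptotic contribution of decreases is in closed form:
#   C1d = E[d^2 | d<0] P(d<0) / E[d^2]
#       = (1-p) sigma_down^2 / (p sigma_up^2 + (1-p) sigma_down^2).

#' Asymptotic short-term decrease contribution of an innovation mixture
#'
#' For iid temperature increments drawn from the two-sided half-normal
#' mixture (`+|N(0, sigma_up^2)|` with probability `p_up`, else
#' `-|N(0, sigma_down^2)|`), the large-sample C1d of the Poincare
#' asymmetry partition equals
#' `(1 - p_up) sigma_down^2 / (p_up sigma_up^2 + (1 - p_up) sigma_down^2)`.
#'
#' @param sigma_down,sigma_up Scales of the negative / positive half-normal
#'   components (degC).
#' @param p_up Probability an increment is positive.
#' @return The asymptotic C1d (fraction in \[0, 1\]).
#' @export
mixture_c1d <- function(sigma_down, sigma_up, p_up) {
  stopifnot(sigma_down > 0, sigma_up > 0, p_up > 0, p_up < 1)
  (1 - p_up) * sigma_down^2 /
    (p_up * sigma_up^2 + (1 - p_up) * sigma_down^2)
}

#' Calibrate a zero-mean innovation mixture to a target C1d
#'
#' Inverts [mixture_c1d()] under the zero-mean constraint
#' `p_up * sigma_up = (1 - p_up) * sigma_down`. The solution is
#' `p_up = c1d` and `sigma_down / sigma_up = c1d / (1 - c1d)`, scaled so
#' the root-mean-square increment equals `sigma_total`.
#'
#' @param c1d Target asymptotic decrease contribution, in (0, 1).
#' @param sigma_total Root-mean-square innovation (degC).
#' @return List with `sigma_down`, `sigma_up`, `p_up`.
#' @export
calibrate_mixture <- function(c1d, sigma_total) {
  stopifnot(c1d > 0, c1d < 1, sigma_total > 0)
  r <- c1d / (1 - c1d)
  list(sigma_down = sigma_total * sqrt(r),
       sigma_up = sigma_total / sqrt(r),
       p_up = c1d)
}

#' Closed-form bout descriptors of the two-state activity chain
#'
#' @param q_ai Probability an active minute is followed by an inactive one.
#' @param q_ia Probability an inactive minute is followed by an active one.
#' @return List with the stationary movement index `mi` (percent), mean
#'   inactive run `di` and mean active run `da` (minutes).
#' @export
bout_expectations <- function(q_ai, q_ia) {
  list(mi = 100 * q_ia / (q_ai + q_ia), di = 1 / q_ia, da = 1 / q_ai)
}

phenotype <- function(q_ai, q_ia, activity_mean, bt_baseline, coupling_gain,
                      ar_coefficient, mixture, response) {
  for (ph in PHASE_LEVELS) {
    stopifnot(q_ai[[ph]] > 0, q_ai[[ph]] < 1, q_ia[[ph]] > 0, q_ia[[ph]] < 1,
              activity_mean[[ph]] >= 1,
              mixture[[ph]]$sigma_down > 0, mixture[[ph]]$sigma_up > 0,
              mixture[[ph]]$p_up > 0, mixture[[ph]]$p_up < 1)
  }
  stopifnot(ar_coefficient >= 0, ar_coefficient < 1)
  list(q_ai = q_ai, q_ia = q_ia, activity_mean = activity_mean,
       bt_baseline = bt_baseline, coupling_gain = coupling_gain,
       ar_coefficient = ar_coefficient, mixture = mixture,
       response = response)
}

default_phenotypes <- function() {
  list(
    control = phenotype(
      q_ai = list(light = 0.40, dark = 0.20),
      q_ia = list(light = 0.10, dark = 0.25),
      activity_mean = list(light = 5, dark = 8),
      bt_baseline = list(light = 36.8, dark = 37.5),
      coupling_gain = 0.04, ar_coefficient = 0.984,
      mixture = list(light = calibrate_mixture(0.577, 0.035),
                     dark = calibrate_mixture(0.525, 0.050)),
      response = list(bt_amplitude = 0.8, activity_amplitude = 12,
                      latency_min = 0, decay_min = 25)),
    substrain = phenotype(
      q_ai = list(light = 0.50, dark = 0.40),
      q_ia = list(light = 0.08, dark = 0.45),
      activity_mean = list(light = 3.5, dark = 5),
      bt_baseline = list(light = 36.8, dark = 37.9),
      coupling_gain = 0.04, ar_coefficient = 0.984,
      mixture = list(light = calibrate_mixture(0.525, 0.050),
                     dark = calibrate_mixture(0.512, 0.070)),
      response = list(bt_amplitude = 0.5, activity_amplitude = 5,
                      latency_min = 10, decay_min = 25))
  )
}

default_event_schedule <- function() {
  data.frame(
    day = c(9L, 10L, 11L, 12L, 13L),
    clock = c("10:00", "10:30", "10:00", "10:30", "08:45"),
    kind = c("handling", "bed_change", "handling", "bed_change", "injection"),
    stringsAsFactors = FALSE)
}

#' Configure the synthetic telemetry cohort
#'
#' Full parameterization of the cohort simulator: study design (animals per
#' group, recording days, intervention schedule), per-group and per-phase
#' bout-process and temperature-process parameters, and the master seed.
#' The defaults reproduce the emulated study design — 6 animals per group
#' recorded for 13 days starting at lights-on, interventions (2 handling,
#' 2 bed-change, 1 morning injection) on the last 5 days — and phenotypes
#' calibrated so the control group shows the canonical rodent pattern
#' (dark-phase maxima in activity and temperature, SD2/SD1 near 10,
#' C1d > 0.5) and the substrain group shows fragmented low activity,
#' dark hyperthermia, larger SD1/SD2, blunted asymmetry and blunted
#' intervention responses.
#'
#' @param n_animals_per_group Animals per group (default 6).
#' @param n_days Complete recording days (default 13).
#' @param seed Master seed; per-animal streams are derived from it by
#'   drawing one sub-seed per animal with `sample.int()` under the master
#'   seed, so cohorts of any size are reproducible.
#' @param lights_on,lights_off Clock times of the light transitions
#'   (defaults 06:00 / 18:00).
#' @param start_date First recording day (recording starts at lights-on).
#' @param groups Named list of group phenotypes; see source for the
#'   calibrated defaults and `calibrate_mixture()` for the asymmetry knob.
#' @param events Intervention schedule: data frame with `day` (1-based
#'   recording day), `clock` (`"HH:MM"`), `kind` (intervention kind).
#' @param temperature_mode `"ar"` (default, autoregressive with activity
#'   coupling) or `"iid_increment"` (random-walk increments drawn straight
#'   from the mixture, for which the asymptotic C1d is known in closed
#'   form).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_animals_per_group = 6L, n_days = 13L,
                             seed = 20151202L,
                             lights_on = "06:00", lights_off = "18:00",
                             start_date = "2015-03-02",
                             groups = default_phenotypes(),
                             events = default_event_schedule(),
                             temperature_mode = c("ar", "iid_increment")) {
  temperature_mode <- match.arg(temperature_mode)
  stopifnot(n_animals_per_group >= 1, n_days >= 1)
  for (g in names(groups)) {
    af <- function(ph) {
      p <- groups[[g]]
      p$q_ia[[ph]] / (p$q_ia[[ph]] + p$q_ai[[ph]])
    }
    if (af("dark") <= af("light"))
      stop("phenotype '", g, "': stationary active fraction must be ",
           "higher in dark than in light", call. = FALSE)
  }
  cfg <- list(n_animals_per_group = as.integer(n_animals_per_group),
              n_days = as.integer(n_days), seed = as.integer(seed),
              lights_on = lights_on, lights_off = lights_off,
              start_date = as.Date(start_date), groups = groups,
              events = events, temperature_mode = temperature_mode)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Minute-by-minute phase labels for a simulated recording
#'
#' @param n_days Number of days; the sequence starts at lights-on.
#' @param lights_on,lights_off Clock times of the transitions.
#' @return Character vector (`"light"`/`"dark"`) of length `n_days * 1440`.
#' @export
phase_sequence <- function(n_days, lights_on = "06:00", lights_off = "18:00") {
  light_len <- (parse_clock(lights_off) - parse_clock(lights_on)) %% 1440L
  rep(c(rep("light", light_len), rep("dark", 1440L - light_len)), n_days)
}

# Simulate the two-state chain over one contiguous same-phase block.
# Returns the minute states (logical active) and the state after the block.
sim_bout_block <- function(len, state0, q_ai, q_ia) {
  states <- logical(0)
  lens <- integer(0)
  filled <- 0L
  s <- state0
  while (filled < len) {
    q <- if (s) q_ai else q_ia
    run <- stats::rgeom(1L, q) + 1L
    states <- c(states, s)
    lens <- c(lens, run)
    filled <- filled + run
    s <- !s
  }
  minute_states <- rep(states, lens)[seq_len(len)]
  list(active = minute_states, final_state = minute_states[len])
}

#' Simulate bout-structured activity counts
#'
#' Two-state Markov chain over minutes with the group's phase-dependent
#' transition probabilities. Inactive minutes emit 0; active minutes emit
#' `1 + NegBinom(size = 2, mu = activity_mean - 1)` counts (right-skewed,
#' mean `activity_mean`). Expected bout lengths are `1/q_ai` (active) and
#' `1/q_ia` (inactive).
#'
#' @param config A [synthetic_config()].
#' @param group Group name in `config$groups`.
#' @param phases Character vector of per-minute phase labels (see
#'   [phase_sequence()]).
#' @param seed Optional seed set before simulation (bit-reproducible).
#' @return Integer vector of activity counts, one per minute.
#' @export
simulate_activity <- function(config, group, phases, seed = NULL) {
  p <- config$groups[[group]]
  if (is.null(p)) stop("unknown group: ", group, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(phases)
  blocks <- rle(phases)
  # initial state from the stationary distribution of the first block
  ph1 <- blocks$values[1]
  state <- stats::runif(1) < p$q_ia[[ph1]] / (p$q_ia[[ph1]] + p$q_ai[[ph1]])
  active <- logical(n)
  pos <- 0L
  for (b in seq_along(blocks$values)) {
    ph <- blocks$values[b]
    len <- blocks$lengths[b]
    blk <- sim_bout_block(len, state, p$q_ai[[ph]], p$q_ia[[ph]])
    active[pos + seq_len(len)] <- blk$active
    state <- blk$final_state
    pos <- pos + len
  }
  counts <- integer(n)
  for (ph in unique(phases)) {
    idx <- which(active & phases == ph)
    mu <- p$activity_mean[[ph]] - 1
    counts[idx] <- if (mu > 0)
      1L + stats::rnbinom(length(idx), size = 2, mu = mu) else 1L
  }
  counts
}

# Trailing moving average with expanding head window (no NA padding).
trailing_ma <- function(x, width = 30L) {
  cs <- cumsum(x)
  n <- length(x)
  lag <- pmax(seq_len(n) - width, 0L)
  denom <- pmin(seq_len(n), width)
  (cs - c(0, cs)[lag + 1L]) / denom
}

draw_mixture <- function(n, sigma_down, sigma_up, p_up) {
  up <- stats::rbinom(n, 1L, p_up) == 1L
  mag <- abs(stats::rnorm(n))
  ifelse(up, mag * sigma_up, -mag * sigma_down)
}

#' Simulate the body-temperature process
#'
#' Default (`mode = "ar"`): phase baseline plus activity coupling (30-min
#' trailing moving average of counts times `coupling_gain`) plus an AR(1)
#' deviation driven by the zero-mean two-sided half-normal innovation
#' mixture. `mode = "iid_increment"` instead draws the minute-to-minute
#' temperature increments straight from the mixture (a random walk started
#' at the first phase's baseline, no coupling), so the asymptotic C1d is
#' [mixture_c1d()] exactly. Output is clipped to the physiological range
#' \[30, 42\] degC; the number of clipped samples is attached as attribute
#' `n_clipped`.
#'
#' @inheritParams simulate_activity
#' @param activity Integer activity counts aligned with `phases`
#'   (required in `"ar"` mode, ignored in `"iid_increment"` mode).
#' @param mode `"ar"` or `"iid_increment"` (overrides the config's
#'   `temperature_mode` when given).
#' @return Numeric temperature vector (degC).
#' @export
simulate_temperature <- function(config, group, phases, activity = NULL,
                                 seed = NULL, mode = NULL) {
  p <- config$groups[[group]]
  if (is.null(p)) stop("unknown group: ", group, call. = FALSE)
  if (is.null(mode)) mode <- config$temperature_mode
  mode <- match.arg(mode, c("ar", "iid_increment"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(phases)
  if (mode == "ar") stopifnot(length(activity) == n)

  sigma_down <- vapply(phases, function(ph) p$mixture[[ph]]$sigma_down,
                       numeric(1), USE.NAMES = FALSE)
  sigma_up <- vapply(phases, function(ph) p$mixture[[ph]]$sigma_up,
                     numeric(1), USE.NAMES = FALSE)
  p_up <- vapply(phases, function(ph) p$mixture[[ph]]$p_up,
                 numeric(1), USE.NAMES = FALSE)
  eps <- draw_mixture(n, sigma_down, sigma_up, p_up)

  if (mode == "iid_increment") {
    bt <- p$bt_baseline[[phases[1]]] + cumsum(eps)
  } else {
    x <- as.numeric(stats::filter(eps, p$ar_coefficient, method = "recursive"))
    baseline <- vapply(phases, function(ph) p$bt_baseline[[ph]],
                       numeric(1), USE.NAMES = FALSE)
    bt <- baseline + p$coupling_gain * trailing_ma(activity) + x
  }
  clipped <- bt < BT_BOUNDS[1] | bt > BT_BOUNDS[2]
  bt <- pmin(pmax(bt, BT_BOUNDS[1]), BT_BOUNDS[2])
  attr(bt, "n_clipped") <- sum(clipped)
  bt
}

# Exponential intervention kernel, added to a signal in place.
apply_response <- function(signal, event_idx, amplitude, latency, decay, n) {
  onset <- event_idx + latency
  if (onset > n || amplitude == 0) return(signal)
  horizon <- min(n, onset + ceiling(6 * decay))
  idx <- onset:horizon
  signal[idx] <- signal[idx] + amplitude * exp(-(idx - onset) / decay)
  signal
}

# Short stable hash of the resolved configuration (polynomial rolling hash
# over its canonical JSON; collision resistance is irrelevant here, the
# hash only identifies a config in run metadata).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$seed <- NULL  # the hash identifies the design, not the realization
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(js))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Simulate a full telemetry cohort
#'
#' Generates one [telemetry_series()] per animal under the configured
#' design: bout-structured activity, coupled autoregressive temperature,
#' daily light-transition events, and scheduled interventions that
#' superimpose a transient `amplitude * exp(-t/decay)` response (after the
#' group's latency) on both signals. Per-animal random streams are derived
#' deterministically from the master seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `series` (named list of [telemetry_series()]),
#'   `events` (combined event data frame: `animal_id`, `time`, `kind`),
#'   `config`, and `config_hash` (stable hash of the resolved config,
#'   independent of the realized noise).
#' @export
#' @examples
#' cohort <- simulate_cohort(synthetic_config(n_animals_per_group = 1,
#'                                            n_days = 2))
#' cohort$series[[1]]
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_per <- config$n_animals_per_group
  groups <- names(config$groups)
  n_total <- n_per * length(groups)
  set.seed(config$seed)
  animal_seeds <- sample.int(.Machine$integer.max, n_total)

  phases <- phase_sequence(config$n_days, config$lights_on, config$lights_off)
  n <- length(phases)
  start_time <- as.POSIXct(paste(format(config$start_date), config$lights_on),
                           tz = "UTC")
  minute_times <- start_time + 60 * (seq_len(n) - 1L)

  # intervention times are shared across the cohort (whole days disturbed)
  ev_sched <- config$events
  ev_times <- if (nrow(ev_sched))
    as.POSIXct(paste(format(config$start_date + (ev_sched$day - 1L)),
                     ev_sched$clock), tz = "UTC")
  else as.POSIXct(character(), tz = "UTC")
  ev_idx <- as.integer(round(as.numeric(ev_times - start_time,
                                        units = "mins"))) + 1L

  lights_times <- sort(c(
    as.POSIXct(paste(format(config$start_date + seq_len(config$n_days) - 1L),
                     config$lights_off), tz = "UTC"),
    as.POSIXct(paste(format(config$start_date + seq_len(config$n_days) - 1L),
                     config$lights_on), tz = "UTC")))
  lights_kind <- ifelse(format(lights_times, "%H:%M") ==
                          sprintf("%02d:%02d",
                                  parse_clock(config$lights_on) %/% 60,
                                  parse_clock(config$lights_on) %% 60),
                        "lights_on", "lights_off")
  in_span <- lights_times >= start_time & lights_times <= minute_times[n]
  lights_times <- lights_times[in_span]
  lights_kind <- lights_kind[in_span]

  series <- list()
  events_all <- list()
  k <- 0L
  for (g in groups) {
    pheno <- config$groups[[g]]
    for (j in seq_len(n_per)) {
      k <- k + 1L
      id <- sprintf("%s%d", toupper(substr(g, 1, 1)), j)
      set.seed(animal_seeds[k])
      act <- simulate_activity(config, g, phases)
      bt <- simulate_temperature(config, g, phases, act)
      n_clipped <- attr(bt, "n_clipped")
      for (e in seq_along(ev_idx)) {
        if (ev_idx[e] < 1L || ev_idx[e] > n) next
        bt <- apply_response(as.numeric(bt), ev_idx[e],
                             pheno$response$bt_amplitude,
                             pheno$response$latency_min,
                             pheno$response$decay_min, n)
        act_resp <- apply_response(rep(0, n), ev_idx[e],
                                   pheno$response$activity_amplitude,
                                   pheno$response$latency_min,
                                   pheno$response$decay_min, n)
        act <- act + as.integer(round(act_resp))
      }
      bt <- pmin(pmax(as.numeric(bt), BT_BOUNDS[1]), BT_BOUNDS[2])

      ev <- data.frame(
        time = c(lights_times, ev_times),
        kind = c(lights_kind, ev_sched$kind),
        stringsAsFactors = FALSE)
      ev <- ev[order(ev$time), , drop = FALSE]

      s <- telemetry_series(id, g, start_time, bt, act, events = ev)
      attr(s, "n_clipped") <- n_clipped
      series[[id]] <- s
      events_all[[id]] <- data.frame(animal_id = id, ev,
                                     stringsAsFactors = FALSE)
    }
  }
  list(series = series,
       events = do.call(rbind, c(events_all, list(make.row.names = FALSE))),
       config = config, config_hash = config_hash(config))
}
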