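# Baseline-referenced response profiles around events: the mean of BT and
# activity per 10-min epoch after an event, referenced to the mean over
# the hour before it. Light transitions are profiled over 1 h,
# interventions (handling, bed change, injection) over 2 h.

default_horizon <- function(kind) {
  if (kind %in% INTERVENTION_KINDS) 120L else 60L
}

#' Baseline-referenced response profile around one event
#'
#' The baseline is the mean over the 60 min before the event
#' (`[event - 60, event)`); post-event epochs are consecutive 10-min
#' windows starting at the event minute (the event minute itself belongs
#' to the first epoch). Missing minutes are excluded from every mean.
#'
#' @param series A [telemetry_series()].
#' @param event_time Event timestamp (`POSIXct` or parseable string), or a
#'   row index into `series$events`.
#' @param kind Event kind; taken from the event log when `event_time`
#'   indexes it. Determines the default horizon: 60 min for light
#'   transitions, 120 min for interventions.
#' @param horizon_minutes Override for the post-event horizon.
#' @param epoch_minutes Post-event averaging window (default 10).
#' @param baseline_minutes Pre-event baseline window (default 60).
#' @return An `event_response_profile`: list with the event, baselines,
#'   an `epochs` data frame (`epoch`, `bt_mean`, `activity_mean`,
#'   `bt_delta`, `activity_delta`) and a `complete` flag. Profiles whose
#'   windows exceed the series span, or whose baseline window has under
#'   50% valid minutes, are flagged incomplete.
#' @export
response_profile <- function(series, event_time, kind = NULL,
                             horizon_minutes = NULL, epoch_minutes = 10L,
                             baseline_minutes = 60L) {
  stopifnot(inherits(series, "telemetry_series"))
  if (is.numeric(event_time) && length(event_time) == 1L &&
      event_time == round(event_time) && event_time <= nrow(series$events)) {
    kind <- series$events$kind[event_time]
    event_time <- series$events$time[event_time]
  }
  event_time <- as_minute_time(event_time)
  if (is.null(kind)) kind <- "handling"
  kind <- match.arg(kind, EVENT_KINDS)
  if (is.null(horizon_minutes)) horizon_minutes <- default_horizon(kind)
  n_epochs <- horizon_minutes %/% epoch_minutes
  stopifnot(n_epochs * epoch_minutes == horizon_minutes)

  n <- length(series$temperature)
  i0 <- as.integer(round(as.numeric(event_time - series$start_time,
                                    units = "mins"))) + 1L
  complete <- i0 - baseline_minutes >= 1L && i0 + horizon_minutes - 1L <= n

  win_mean <- function(x, idx) {
    idx <- idx[idx >= 1L & idx <= n]
    if (!length(idx)) return(NA_real_)
    mean(x[idx], na.rm = TRUE)
  }
  base_idx <- (i0 - baseline_minutes):(i0 - 1L)
  base_idx <- base_idx[base_idx >= 1L & base_idx <= n]
  base_valid <- if (length(base_idx))
    sum(!is.na(series$temperature[base_idx])) / baseline_minutes else 0
  baseline_ok <- base_valid >= 0.5
  baseline_bt <- if (baseline_ok) mean(series$temperature[base_idx],
                                       na.rm = TRUE) else NA_real_
  baseline_act <- if (baseline_ok) mean(series$activity[base_idx],
                                        na.rm = TRUE) else NA_real_

  ep <- lapply(seq_len(n_epochs), function(k) {
    idx <- (i0 + (k - 1L) * epoch_minutes):(i0 + k * epoch_minutes - 1L)
    data.frame(epoch = k,
               t_end_min = k * epoch_minutes,
               bt_mean = win_mean(series$temperature, idx),
               activity_mean = win_mean(series$activity, idx))
  })
  epochs <- do.call(rbind, ep)
  epochs$bt_delta <- epochs$bt_mean - baseline_bt
  epochs$activity_delta <- epochs$activity_mean - baseline_act

  structure(
    list(animal_id = series$animal_id, group = series$group,
         event_time = event_time, kind = kind,
         baseline_bt = baseline_bt, baseline_activity = baseline_act,
         epoch_minutes = as.integer(epoch_minutes),
         horizon_minutes = as.integer(horizon_minutes),
         epochs = epochs,
         complete = complete && baseline_ok),
    class = "event_response_profile")
}

#' @export
print.event_response_profile <- function(x, ...) {
  cat(sprintf("<event_response_profile> %s %s @ %s: %d x %d-min epochs%s\n",
              x$animal_id, x$kind, format(x$event_time, "%Y-%m-%d %H:%M"),
              nrow(x$epochs), x$epoch_minutes,
              if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

#' Response profiles for all logged events of given kinds
#'
#' @param series A [telemetry_series()] with an event log.
#' @param kinds Event kinds to profile (default: the three intervention
#'   kinds).
#' @param ... Passed to [response_profile()].
#' @return List of `event_response_profile`.
#' @export
event_responses <- function(series, kinds = INTERVENTION_KINDS, ...) {
  ev <- series$events[series$events$kind %in% kinds, , drop = FALSE]
  lapply(seq_len(nrow(ev)),
         function(i) response_profile(series, ev$time[i], ev$kind[i], ...))
}

#' Pool event-response profiles into epoch-wise mean and SEM
#'
#' Averages the baseline-referenced deltas epoch-by-epoch across profiles.
#' The three intervention kinds (handling, bed change, injection) produce
#' comparable transient responses and are poolable under a single
#' `"intervention"` label (the default); light transitions pool per kind.
#' Incomplete profiles are dropped.
#'
#' @param profiles List of `event_response_profile` (possibly several
#'   animals/groups).
#' @param group Optional group filter.
#' @param kind Optional kind filter: an event kind, or `"intervention"`
#'   for the pooled interventions.
#' @return Data frame with `group`, `kind`, `signal` (`"bt"`/`"activity"`),
#'   `epoch`, `mean_delta`, `sem_delta`, `n`.
#' @export
pool_event_profiles <- function(profiles, group = NULL, kind = NULL) {
  if (inherits(profiles, "event_response_profile")) profiles <- list(profiles)
  profiles <- Filter(function(p) isTRUE(p$complete), profiles)
  if (!length(profiles)) stop("no complete profiles to pool", call. = FALSE)
  lab <- function(p) if (p$kind %in% INTERVENTION_KINDS) "intervention"
                     else p$kind
  keep <- vapply(profiles, function(p) {
    (is.null(group) || p$group == group) &&
      (is.null(kind) || lab(p) == kind || p$kind == kind)
  }, logical(1))
  profiles <- profiles[keep]
  if (!length(profiles)) stop("no profiles match the filters", call. = FALSE)

  cells <- split(profiles, interaction(
    vapply(profiles, `[[`, character(1), "group"),
    vapply(profiles, lab, character(1)), drop = TRUE))
  out <- lapply(cells, function(ps) {
    n_ep <- unique(vapply(ps, function(p) nrow(p$epochs), integer(1)))
    stopifnot(length(n_ep) == 1L)
    bt <- sapply(ps, function(p) p$epochs$bt_delta)
    ac <- sapply(ps, function(p) p$epochs$activity_delta)
    bt <- matrix(bt, nrow = n_ep)
    ac <- matrix(ac, nrow = n_ep)
    sem <- function(m) apply(m, 1, function(v)
      if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
      else 0)
    rbind(
      data.frame(group = ps[[1]]$group, kind = lab(ps[[1]]), signal = "bt",
                 epoch = seq_len(n_ep), mean_delta = rowMeans(bt, na.rm = TRUE),
                 sem_delta = sem(bt), n = length(ps)),
      data.frame(group = ps[[1]]$group, kind = lab(ps[[1]]),
                 signal = "activity", epoch = seq_len(n_ep),
                 mean_delta = rowMeans(ac, na.rm = TRUE),
                 sem_delta = sem(ac), n = length(ps)))
  })
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}
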