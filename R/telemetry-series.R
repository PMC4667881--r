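#' @keywords internal
"_PACKAGE"

# Closed vocabularies used throughout the package.
GROUP_LEVELS <- c("control", "substrain")
PHASE_LEVELS <- c("light", "dark")
CONDITION_LEVELS <- c("undisturbed", "disturbed")
EVENT_KINDS <- c("handling", "bed_change", "injection", "lights_on", "lights_off")
INTERVENTION_KINDS <- c("handling", "bed_change", "injection")

# Physiological plausibility bounds for abdominal temperature (degC).
BT_BOUNDS <- c(30, 42)

#' One animal's continuous minute-resolution telemetry record
#'
#' Container for a single animal's abdominal body temperature (degC) and
#' gross locomotor activity (arbitrary counts) sampled once per minute,
#' together with its event log (handling, bed change, injection, light
#' transitions). Missing samples are `NA`.
#'
#' @param animal_id Single string identifying the animal.
#' @param group `"control"` or `"substrain"`. Group membership is carried in
#'   the data, never inferred.
#' @param start_time `POSIXct` timestamp (minute resolution) of the first
#'   sample. Coerced to UTC.
#' @param temperature Numeric vector of temperatures in degC; `NA` allowed.
#'   Non-missing values must lie in \[30, 42\] degC.
#' @param activity Vector of non-negative integer activity counts; `NA`
#'   allowed.
#' @param events Optional data frame with columns `time` (`POSIXct`) and
#'   `kind` (one of `handling`, `bed_change`, `injection`, `lights_on`,
#'   `lights_off`). Must be time-ordered and fall within the series span.
#'
#' @return An object of class `telemetry_series`.
#' @export
#' @examples
#' ts <- telemetry_series("r1", "control",
#'   as.POSIXct("2015-03-02 06:00", tz = "UTC"),
#'   temperature = c(37.0, 37.1, NA, 36.9),
#'   activity = c(0L, 3L, 5L, 0L))
#' length(ts$temperature)
telemetry_series <- function(animal_id, group, start_time, temperature,
                             activity, events = NULL) {
  stopifnot(is.character(animal_id), length(animal_id) == 1L)
  group <- match.arg(group, GROUP_LEVELS)
  start_time <- as_minute_time(start_time)
  temperature <- as.numeric(temperature)
  activity <- as_activity(activity)
  if (length(temperature) != length(activity))
    stop("temperature and activity must have equal length", call. = FALSE)
  bad_bt <- !is.na(temperature) &
    (temperature < BT_BOUNDS[1] | temperature > BT_BOUNDS[2])
  if (any(bad_bt))
    stop(sprintf("%d temperature value(s) outside [%g, %g] degC",
                 sum(bad_bt), BT_BOUNDS[1], BT_BOUNDS[2]), call. = FALSE)
  if (is.null(events)) {
    events <- empty_events()
  } else {
    events <- validate_events(events, start_time,
                              n_samples = length(temperature))
  }
  structure(
    list(animal_id = animal_id, group = group, start_time = start_time,
         sampling_interval_min = 1L, temperature = temperature,
         activity = activity, events = events),
    class = "telemetry_series")
}

as_minute_time <- function(x) {
  x <- as.POSIXct(x, tz = "UTC")
  out <- as.POSIXct(floor(as.numeric(x) / 60) * 60,
                    origin = "1970-01-01", tz = "UTC")
  out
}

as_activity <- function(x) {
  xi <- suppressWarnings(as.integer(round(as.numeric(x))))
  if (any(!is.na(xi) & xi < 0L))
    stop("activity counts must be non-negative", call. = FALSE)
  xi
}

empty_events <- function() {
  data.frame(time = as.POSIXct(character(), tz = "UTC"),
             kind = character(), stringsAsFactors = FALSE)
}

validate_events <- function(events, start_time, n_samples) {
  stopifnot(is.data.frame(events), all(c("time", "kind") %in% names(events)))
  events <- events[, c("time", "kind"), drop = FALSE]
  events$time <- as_minute_time(events$time)
  events$kind <- as.character(events$kind)
  bad <- setdiff(unique(events$kind), EVENT_KINDS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(events)) {
    end_time <- start_time + 60 * (n_samples - 1L)
    if (any(events$time < start_time | events$time > end_time))
      stop("events must fall within the series' time span", call. = FALSE)
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  events
}

#' Sample timestamps of a telemetry series
#'
#' @param series A [telemetry_series()].
#' @return `POSIXct` vector, one timestamp per sample.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "telemetry_series"))
  series$start_time + 60 * (seq_along(series$temperature) - 1L)
}

#' @export
print.telemetry_series <- function(x, ...) {
  n <- length(x$temperature)
  cat(sprintf("<telemetry_series> animal %s (%s)\n", x$animal_id, x$group))
  cat(sprintf("  %d samples at 1 min from %s UTC (%.1f days)\n",
              n, format(x$start_time, "%Y-%m-%d %H:%M"), n / 1440))
  cat(sprintf("  temperature: %d missing; activity: %d missing; %d events\n",
              sum(is.na(x$temperature)), sum(is.na(x$activity)),
              nrow(x$events)))
  invisible(x)
}

#' One animal-day-phase slice of a telemetry record
#'
#' A `phase_recording` is the unit on which all descriptors are computed:
#' one animal's samples for one 12-h light or dark phase of one calendar
#' day (720 samples when the day is complete at 1-min sampling).
#'
#' @param animal_id,group Animal identity and group label.
#' @param date Calendar `Date` the phase is attributed to. A dark phase is
#'   attributed to the day on which it starts (the day containing its
#'   18:00-24:00 portion under the default light cycle).
#' @param phase `"light"` or `"dark"`.
#' @param condition `"undisturbed"`, `"disturbed"`, or `NA` before labelling.
#' @param temperature,activity Sample vectors for the phase window.
#' @param partial `TRUE` when the source window was truncated by the start
#'   or end of the series.
#' @param expected_length Number of samples a complete window would hold.
#'
#' @return An object of class `phase_recording`.
#' @export
phase_recording <- function(animal_id, group, date, phase,
                            condition = NA_character_, temperature, activity,
                            partial = FALSE,
                            expected_length = length(temperature)) {
  phase <- match.arg(phase, PHASE_LEVELS)
  if (!is.na(condition)) condition <- match.arg(condition, CONDITION_LEVELS)
  stopifnot(length(temperature) == length(activity))
  structure(
    list(animal_id = animal_id, group = group, date = as.Date(date),
         phase = phase, condition = condition,
         temperature = as.numeric(temperature),
         activity = as_activity(activity),
         partial = isTRUE(partial),
         expected_length = as.integer(expected_length)),
    class = "phase_recording")
}

#' @export
print.phase_recording <- function(x, ...) {
  cat(sprintf("<phase_recording> %s %s %s %s (%s): %d samples%s\n",
              x$animal_id, x$group, format(x$date), x$phase,
              ifelse(is.na(x$condition), "unlabelled", x$condition),
              length(x$temperature), if (x$partial) " [partial]" else ""))
  invisible(x)
}

#' Fraction of missing samples in one signal of a recording
#'
#' @param rec A [phase_recording()].
#' @param signal `"temperature"` or `"activity"`.
#' @return Missing fraction in \[0, 1\], relative to the expected complete
#'   window length (so a partial window counts its truncation as missing).
#' @export
missing_fraction <- function(rec, signal = c("temperature", "activity")) {
  signal <- match.arg(signal)
  x <- rec[[signal]]
  n_expected <- max(rec$expected_length, length(x))
  (n_expected - sum(!is.na(x))) / n_expected
}
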