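# Circadian phase splitting and pooling.
#
# Time convention: timestamps at minute resolution, windows half-open
# [start, end), so a sample stamped exactly at lights-on belongs to the
# light phase and a complete 12:12 day yields exactly 720 samples per
# phase. A dark phase is attributed to the calendar day on which it starts.

parse_clock <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("clock time must be 'HH:MM'", call. = FALSE)
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}

#' Split a telemetry series into light/dark phase recordings
#'
#' Cuts one animal's continuous record at the light transitions into
#' 12-h [phase_recording()] windows. Windows are half-open
#' `[lights_on, lights_off)` for light and `[lights_off, next lights_on)`
#' for dark; a dark phase is attributed to the calendar day on which it
#' starts. Windows truncated by the start or end of the series are flagged
#' `partial` (and excluded from pooling by default).
#'
#' @param series A [telemetry_series()].
#' @param lights_on,lights_off Clock times `"HH:MM"` (defaults 06:00 and
#'   18:00, a 12:12 cycle) or minutes after midnight.
#' @return List of [phase_recording()] in chronological order, with
#'   `condition` unset (see [label_conditions()]).
#' @export
#' @examples
#' cfg <- synthetic_config(n_animals_per_group = 1, n_days = 2)
#' s <- simulate_cohort(cfg)$series[[1]]
#' recs <- split_phases(s)
#' lengths(lapply(recs, `[[`, "temperature"))
split_phases <- function(series, lights_on = "06:00", lights_off = "18:00") {
  stopifnot(inherits(series, "telemetry_series"))
  on <- parse_clock(lights_on)
  off <- parse_clock(lights_off)
  if (on == off) stop("lights_on and lights_off must differ", call. = FALSE)
  n <- length(series$temperature)
  if (n == 0L) stop("series is empty", call. = FALSE)

  t_min <- as.numeric(series$start_time) %/% 60 + (seq_len(n) - 1L)  # epoch minutes
  mod <- t_min %% 1440L
  day0 <- t_min %/% 1440L  # epoch days

  light_len <- (off - on) %% 1440L
  if (on < off) {
    in_light <- mod >= on & mod < off
    light_start <- (day0 * 1440L) + on
    dark_start <- ifelse(mod >= off, day0 * 1440L + off,
                         (day0 - 1L) * 1440L + off)
  } else {
    in_light <- mod >= on | mod < off
    light_start <- ifelse(mod >= on, day0 * 1440L + on,
                          (day0 - 1L) * 1440L + on)
    dark_start <- day0 * 1440L + off
  }
  win_start <- ifelse(in_light, light_start, dark_start)
  phase <- ifelse(in_light, "light", "dark")

  keys <- unique(win_start)
  keys <- keys[order(keys)]
  out <- lapply(keys, function(k) {
    idx <- which(win_start == k)
    ph <- phase[idx[1]]
    expected <- if (ph == "light") light_len else 1440L - light_len
    phase_recording(
      animal_id = series$animal_id, group = series$group,
      date = as.Date(as.POSIXct(k * 60, origin = "1970-01-01", tz = "UTC"),
                     tz = "UTC"),
      phase = ph, temperature = series$temperature[idx],
      activity = series$activity[idx],
      partial = length(idx) < expected, expected_length = expected)
  })
  out
}

#' Label recordings as disturbed or undisturbed from an event log
#'
#' A calendar day is *disturbed* when any handling, bed-change or injection
#' event falls on it; both phase recordings attributed to that day inherit
#' `condition = "disturbed"` (including the dark phase that extends past
#' midnight). Light transitions never disturb.
#'
#' @param recordings List of [phase_recording()].
#' @param events Event data frame with columns `time` and `kind`, and
#'   optionally `animal_id` (required when `recordings` span animals).
#' @param policy Disturbance attribution policy. `"day"` (default, the only
#'   implemented policy) marks the whole calendar day of the event.
#' @return The recordings with `condition` filled in.
#' @export
label_conditions <- function(recordings, events, policy = "day") {
  policy <- match.arg(policy, "day")
  if (inherits(recordings, "phase_recording")) recordings <- list(recordings)
  ev <- events[!events$kind %in% c("lights_on", "lights_off"), , drop = FALSE]
  ev_date <- as.Date(ev$time, tz = "UTC")
  has_ids <- "animal_id" %in% names(ev)
  lapply(recordings, function(rec) {
    dates <- if (has_ids) ev_date[ev$animal_id == rec$animal_id] else ev_date
    rec$condition <- if (rec$date %in% dates) "disturbed" else "undisturbed"
    rec
  })
}

#' Pool phase recordings by phase and disturbance condition
#'
#' Pure filter over a set of recordings: keeps those matching `phase` and
#' `condition`, drops partial windows and recordings exceeding the
#' missingness threshold, and orders the result by `(animal_id, date)`.
#' Each animal-day contributes at most one recording per phase. Pooling is
#' idempotent: re-pooling a pooled set returns it unchanged.
#'
#' @param recordings List of [phase_recording()] (conditions labelled).
#' @param phase Optional `"light"` or `"dark"` filter.
#' @param condition Optional `"undisturbed"` or `"disturbed"` filter.
#' @param max_missing_frac Maximum tolerated missing fraction in either
#'   signal (default 0.05); recordings above it are excluded.
#' @param include_partial Keep windows truncated by the series limits
#'   (default `FALSE`).
#' @return Filtered, ordered list of [phase_recording()]; empty list (with
#'   a message) when nothing matches.
#' @export
pool_recordings <- function(recordings, phase = NULL, condition = NULL,
                            max_missing_frac = 0.05,
                            include_partial = FALSE) {
  if (inherits(recordings, "phase_recording")) recordings <- list(recordings)
  keep <- vapply(recordings, function(rec) {
    if (!is.null(phase) && rec$phase != phase) return(FALSE)
    if (!is.null(condition) &&
        (is.na(rec$condition) || rec$condition != condition)) return(FALSE)
    if (!include_partial && rec$partial) return(FALSE)
    if (missing_fraction(rec, "temperature") > max_missing_frac) return(FALSE)
    if (missing_fraction(rec, "activity") > max_missing_frac) return(FALSE)
    TRUE
  }, logical(1))
  out <- recordings[keep]
  if (!length(out)) {
    message("pool_recordings: no recordings match the requested filters")
    return(out)
  }
  ord <- order(vapply(out, `[[`, character(1), "animal_id"),
               vapply(out, function(r) as.numeric(r$date), numeric(1)),
               vapply(out, `[[`, character(1), "phase"))
  out <- out[ord]
  # one recording per (animal, date, phase)
  key <- vapply(out, function(r)
    paste(r$animal_id, format(r$date), r$phase), character(1))
  out[!duplicated(key)]
}
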