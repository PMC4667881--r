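# CSV interchange format
#
# Telemetry CSV: one row per animal-minute with columns
#   animal_id, group, timestamp, temperature_c, activity_counts
# Event CSV: one row per event with columns
#   animal_id, timestamp, event_kind
# Timestamps are ISO 8601 at minute precision (UTC assumed); an empty cell
# is a missing value.

TELEMETRY_COLUMNS <- c("animal_id", "group", "timestamp",
                       "temperature_c", "activity_counts")
EVENT_COLUMNS <- c("animal_id", "timestamp", "event_kind")

parse_iso_minute <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"),
                    optional = TRUE)
  as_minute_time(out)
}

format_iso_minute <- function(t) format(t, "%Y-%m-%dT%H:%M", tz = "UTC")

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
}

# Coerce a character column to numeric, counting malformed cells.
coerce_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  list(values = out, n_malformed = sum(is.na(out) & !is.na(x)))
}

#' Read minute-resolution telemetry from CSV
#'
#' Reads the tidy interchange format (one row per animal-minute; columns
#' `animal_id, group, timestamp, temperature_c, activity_counts`) into one
#' [telemetry_series()] per animal. Rows are sorted by time; gaps in the
#' minute grid become missing samples; malformed numeric cells become
#' missing with a warning reporting how many were dropped.
#'
#' @param path Path to the telemetry CSV.
#' @param events_path Optional path to an event CSV (columns
#'   `animal_id, timestamp, event_kind`); events are attached per animal.
#' @return Named list of [telemetry_series()], one per `animal_id`.
#' @export
read_telemetry_csv <- function(path, events_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  require_columns(df, TELEMETRY_COLUMNS, path)
  if (nrow(df) == 0L) stop("empty telemetry file: ", path, call. = FALSE)
  df$time <- parse_iso_minute(df$timestamp)
  if (anyNA(df$time))
    stop(sprintf("file '%s': %d unparseable timestamp(s)",
                 path, sum(is.na(df$time))), call. = FALSE)
  key <- paste(df$animal_id, format_iso_minute(df$time))
  if (anyDuplicated(key))
    stop(sprintf("file '%s': duplicate (animal_id, timestamp) rows (e.g. %s)",
                 path, key[anyDuplicated(key)]), call. = FALSE)

  bt <- coerce_numeric(df$temperature_c)
  act <- coerce_numeric(df$activity_counts)
  n_malformed <- bt$n_malformed + act$n_malformed
  if (n_malformed > 0)
    warning(sprintf("%d malformed numeric cell(s) read as missing",
                    n_malformed), call. = FALSE)
  df$temperature_c <- bt$values
  df$activity_counts <- act$values

  events <- if (!is.null(events_path)) read_events_csv(events_path) else NULL

  ids <- unique(df$animal_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$animal_id == id, , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    grp <- unique(rows$group)
    if (length(grp) != 1L)
      stop("animal ", id, " has inconsistent group labels", call. = FALSE)
    # Expand to a regular minute grid; absent minutes become NA samples.
    grid <- seq(rows$time[1], rows$time[nrow(rows)], by = 60)
    idx <- match(as.numeric(grid), as.numeric(rows$time))
    ev <- if (!is.null(events)) events[events$animal_id == id,
                                       c("time", "kind"), drop = FALSE]
    telemetry_series(id, grp, rows$time[1],
                     temperature = rows$temperature_c[idx],
                     activity = rows$activity_counts[idx],
                     events = ev)
  })
  names(out) <- ids
  out
}

#' Write telemetry series to the CSV interchange format
#'
#' @param series_list List of [telemetry_series()] (or a single one).
#' @param path Output CSV path.
#' @param events_path Optional path; when given, all event logs are written
#'   there in the event CSV format.
#' @return Invisibly, `path`.
#' @export
write_telemetry_csv <- function(series_list, path, events_path = NULL) {
  if (inherits(series_list, "telemetry_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.frame(animal_id = s$animal_id, group = s$group,
               timestamp = format_iso_minute(series_times(s)),
               temperature_c = s$temperature,
               activity_counts = s$activity,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(events_path)) {
    ev <- lapply(series_list, function(s) {
      if (nrow(s$events) == 0L) return(NULL)
      data.frame(animal_id = s$animal_id,
                 timestamp = format_iso_minute(s$events$time),
                 event_kind = s$events$kind, stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, ev)
    if (is.null(ev)) ev <- data.frame(animal_id = character(),
                                      timestamp = character(),
                                      event_kind = character())
    utils::write.csv(ev, events_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read an event log CSV
#'
#' @param path Path to a CSV with columns `animal_id, timestamp, event_kind`.
#' @return Data frame with columns `animal_id`, `time` (`POSIXct`), `kind`.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  require_columns(df, EVENT_COLUMNS, path)
  bad <- setdiff(unique(df$event_kind), EVENT_KINDS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(animal_id = df$animal_id,
                    time = parse_iso_minute(df$timestamp),
                    kind = df$event_kind, stringsAsFactors = FALSE)
  out[order(out$animal_id, out$time), , drop = FALSE]
}
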