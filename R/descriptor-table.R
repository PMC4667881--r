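# One row of descriptors per phase recording, the tidy unit for group
# statistics and CSV export.

#' Compute all descriptors for a set of phase recordings
#'
#' Applies [compute_activity_descriptors()],
#' [compute_temperature_descriptors()], [compute_poincare_descriptors()]
#' and [classify_asymmetry()] to each recording and binds the results with
#' the recording metadata into one tidy data frame (one row per
#' recording). Recordings on which a descriptor family cannot be computed
#' (e.g. fewer than 2 valid Poincare pairs) get `NA` in that family's
#' columns.
#'
#' @param recordings List of [phase_recording()].
#' @param lag Poincare return-map lag (default 1 sample).
#' @param threshold Activity threshold (default 0, strictly exceeded).
#' @param epoch_minutes Epoch width for AL and mean BT (default 60).
#' @return Data frame with metadata (`animal_id`, `group`, `date`,
#'   `phase`, `condition`), activity descriptors, temperature descriptors,
#'   Poincare descriptors and asymmetry classifications.
#' @export
compute_descriptor_table <- function(recordings, lag = 1L, threshold = 0,
                                     epoch_minutes = 60L) {
  if (inherits(recordings, "phase_recording")) recordings <- list(recordings)
  if (!length(recordings)) stop("no recordings supplied", call. = FALSE)
  na_row <- function(cols) {
    out <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(cols)),
                                                 cols)))
    out
  }
  act_cols <- c("al", "mi", "rmi", "pn", "di", "da", "n_valid_minutes")
  bt_cols <- c("bt_mean", "bt_min", "bt_max", "bt_amplitude",
               "mean_increase", "mean_decrease", "n_valid_samples")
  pp_cols <- c("n_pairs", "sd1", "sd2", "sdnn", "sd1d", "sd1i",
               "sd2d", "sd2i", "c1d", "c1i", "c2d", "c2i")
  rows <- lapply(recordings, function(rec) {
    meta <- data.frame(animal_id = rec$animal_id, group = rec$group,
                       date = rec$date, phase = rec$phase,
                       condition = rec$condition,
                       partial = rec$partial, stringsAsFactors = FALSE)
    act <- tryCatch(
      compute_activity_descriptors(rec, threshold = threshold,
                                   epoch_minutes = epoch_minutes),
      error = function(e) na_row(act_cols))
    bt <- tryCatch(compute_temperature_descriptors(rec, epoch_minutes),
                   error = function(e) na_row(bt_cols))
    pp <- tryCatch(compute_poincare_descriptors(rec, lag = lag),
                   error = function(e) na_row(pp_cols))
    cbind(meta, act, bt, pp)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cls <- classify_asymmetry(out)
  cbind(out, cls)
}
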