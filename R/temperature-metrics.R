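# Scalar body-temperature descriptors for one phase recording: mean BT
# (mean of 1-h epoch means), extrema, amplitude, and the mean magnitudes
# of positive and negative minute-to-minute changes.

#' Body-temperature descriptors of one phase recording
#'
#' Extrema and amplitude are taken over non-missing samples. `bt_mean` is
#' the mean of per-epoch means (epochs aligned to the phase start; an
#' epoch contributes when it has at least one valid sample) — with
#' complete data this equals the grand mean. Consecutive changes are
#' computed only between adjacent non-missing samples (a 1-min lag is part
#' of the definition, so differences never span a gap); increases and
#' decreases are averaged separately and zero differences belong to
#' neither mean.
#'
#' @param rec A [phase_recording()] (or a bare numeric degC vector).
#' @param epoch_minutes Epoch width for `bt_mean` (default 60).
#' @return One-row data frame with `bt_mean`, `bt_min`, `bt_max`,
#'   `bt_amplitude`, `mean_increase`, `mean_decrease`, `n_valid_samples`.
#'   The change means are `NA` when no change of that sign exists.
#' @export
#' @examples
#' compute_temperature_descriptors(c(37.0, 37.2, 36.9, 36.9))
compute_temperature_descriptors <- function(rec, epoch_minutes = 60L) {
  x <- if (inherits(rec, "phase_recording")) rec$temperature else
    as.numeric(rec)
  valid <- !is.na(x)
  if (sum(valid) < 2L)
    stop("recording needs at least 2 non-missing temperature samples",
         call. = FALSE)

  bt_min <- min(x[valid])
  bt_max <- max(x[valid])

  ep <- epoch_ids(length(x), epoch_minutes)
  ep_means <- tapply(x, ep, mean, na.rm = TRUE)
  bt_mean <- mean(ep_means[is.finite(ep_means)])

  d <- x[-1] - x[-length(x)]
  d <- d[valid[-1] & valid[-length(x)]]
  mean_increase <- if (any(d > 0)) mean(d[d > 0]) else NA_real_
  mean_decrease <- if (any(d < 0)) mean(-d[d < 0]) else NA_real_

  data.frame(bt_mean = bt_mean, bt_min = bt_min, bt_max = bt_max,
             bt_amplitude = bt_max - bt_min,
             mean_increase = mean_increase, mean_decrease = mean_decrease,
             n_valid_samples = sum(valid))
}
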