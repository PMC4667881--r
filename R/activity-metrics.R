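# Rest-activity fragmentation descriptors for one phase recording:
#   AL  - activity level: mean count sum per 1-h epoch
#   MI  - movement index: percentage of minutes with count > 0
#   RMI - relative movement index: mean count over active minutes
#   PN  - phase number: total count of active + inactive runs
#   DI / DA - mean duration of inactive / active runs (min)

#' Segment an activity sequence into active/inactive runs
#'
#' Maximal runs of consecutive minutes sharing the activity predicate
#' (`count > threshold`). Missing minutes break runs (a run is by
#' definition uninterrupted) and belong to no run, unless
#' `bridge_single_missing` imputes an isolated missing minute flanked by
#' the same state.
#'
#' @param activity Integer counts, `NA` allowed.
#' @param threshold Counts strictly above this are active (default 0).
#' @param min_bout Minimum run duration in minutes; shorter runs are
#'   absorbed into their surroundings by state-flipping, iterated to a
#'   fixed point. Default 1 (no smoothing).
#' @param bridge_single_missing Impute a single `NA` between two minutes of
#'   equal state (default `FALSE`).
#' @return Data frame with columns `state` (`"active"`/`"inactive"`) and
#'   `length` (minutes); zero rows for an empty or all-missing sequence.
#'   Run lengths sum to the number of valid minutes.
#' @export
#' @examples
#' run_segmentation(c(0, 0, 3, 5, 0, 2))
run_segmentation <- function(activity, threshold = 0, min_bout = 1L,
                             bridge_single_missing = FALSE) {
  x <- as.numeric(activity)
  if (!length(x)) return(data.frame(state = character(), length = integer()))
  active <- ifelse(is.na(x), NA, x > threshold)
  if (bridge_single_missing && length(active) > 2L) {
    mid <- which(is.na(active))
    mid <- mid[mid > 1L & mid < length(active)]
    fixable <- mid[!is.na(active[mid - 1L]) & !is.na(active[mid + 1L]) &
                     active[mid - 1L] == active[mid + 1L]]
    active[fixable] <- active[fixable - 1L]
  }
  runs_of <- function(a) {
    r <- rle(a)
    keep <- !is.na(r$values)
    data.frame(state = ifelse(r$values[keep], "active", "inactive"),
               length = r$lengths[keep], stringsAsFactors = FALSE)
  }
  runs <- runs_of(active)
  if (min_bout > 1L) {
    repeat {
      short <- which(runs$length < min_bout)
      if (!length(short) || nrow(runs) == 1L) break
      # flip the first short run and re-merge
      flip <- short[1]
      seq_states <- rep(runs$state == "active", runs$length)
      offs <- cumsum(c(0, runs$length))
      seq_states[(offs[flip] + 1):offs[flip + 1]] <-
        !seq_states[(offs[flip] + 1):offs[flip + 1]]
      runs <- runs_of(seq_states)
    }
  }
  runs
}

epoch_ids <- function(n, epoch_minutes) (seq_len(n) - 1L) %/% epoch_minutes

#' Motor-activity descriptors of one phase recording
#'
#' @param rec A [phase_recording()] (or a bare counts vector).
#' @param threshold Active threshold, strictly exceeded (default 0).
#' @param epoch_minutes Epoch width for the activity level (default 60).
#'   Epochs are non-overlapping windows aligned to the phase start;
#'   incomplete or partly missing epochs are excluded from AL.
#' @param min_bout,bridge_single_missing Passed to [run_segmentation()].
#' @return One-row data frame with `al`, `mi`, `rmi`, `pn`, `di`, `da`
#'   plus `n_valid_minutes`. `rmi` and `da` are `NA` (not zero) when no
#'   minute is active; `di` is `NA` when none is inactive.
#' @export
#' @examples
#' compute_activity_descriptors(c(0, 0, 3, 5, 0, 2), epoch_minutes = 6)
compute_activity_descriptors <- function(rec, threshold = 0,
                                         epoch_minutes = 60L,
                                         min_bout = 1L,
                                         bridge_single_missing = FALSE) {
  x <- if (inherits(rec, "phase_recording")) rec$activity else as.numeric(rec)
  valid <- !is.na(x)
  n_valid <- sum(valid)
  if (n_valid == 0L)
    stop("recording has no non-missing activity sample", call. = FALSE)

  active <- valid & x > threshold
  mi <- 100 * sum(active) / n_valid
  rmi <- if (any(active)) mean(x[active]) else NA_real_

  ep <- epoch_ids(length(x), epoch_minutes)
  full <- tabulate(ep + 1L) == epoch_minutes
  ep_ok <- full & tapply(valid, ep, all)
  al <- if (any(ep_ok))
    mean(tapply(ifelse(valid, x, 0), ep, sum)[ep_ok]) else NA_real_

  runs <- run_segmentation(x, threshold = threshold, min_bout = min_bout,
                           bridge_single_missing = bridge_single_missing)
  pn <- nrow(runs)
  di <- if (any(runs$state == "inactive"))
    mean(runs$length[runs$state == "inactive"]) else NA_real_
  da <- if (any(runs$state == "active"))
    mean(runs$length[runs$state == "active"]) else NA_real_

  data.frame(al = al, mi = mi, rmi = rmi, pn = pn, di = di, da = da,
             n_valid_minutes = n_valid)
}
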