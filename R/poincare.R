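# Poincare-plot analysis of the temperature series.
#
# The plot is the lag-1 return map (BT_n, BT_{n+1}). SD1 measures the
# dispersion of points perpendicular to the identity line BT_{n+1} = BT_n
# (short-term variability); SD2 measures the dispersion along it
# (long-term variability). With pairs (x_i, y_i), i = 1..n:
#
#   sd1^2 = sum((y_i - x_i)^2) / (2 (n - 1))
#           (second moment of perpendicular distances about the identity
#            line itself — the line, not the cloud mean, is the reference)
#   sd2^2 = sum(D_i^2) / (n - 1),  D_i = (x_i + y_i - 2 m) / sqrt(2),
#           m = mean of all coordinates entering the pairs
#   sdnn^2 = (sd1^2 + sd2^2) / 2   (matches the series' overall SD when
#            sd1 is negligible against sd2)
#
# The asymmetry partition splits both variances by the sign of the change
# delta_i = y_i - x_i: points above the identity line are increases,
# below it decreases. Using the identity line (for sd1) and the centroid
# (for sd2) as reference points makes the decomposition exact:
#   sd1d^2 + sd1i^2 = sd1^2,  sd2d^2 + sd2i^2 = sd2^2,
# with on-line points (delta = 0) contributing nothing to the sd1
# components and split equally between sd2d^2 and sd2i^2. The relative
# contributions are c1d = sd1d^2/sd1^2 etc., so c1d + c1i = 1 and
# c2d + c2i = 1. A consequence of referencing sd1 to the line rather than
# the cloud mean is sd1^2 + sd2^2 = Var(x) + Var(y) + n/(2(n-1)) *
# mean(delta)^2: exact up to a drift term that vanishes for stationary
# series.

#' Lagged coordinate pairs of a temperature series
#'
#' Builds the return-map pairs `(BT_n, BT_{n+lag})`, binding each
#' temperature with the next one. Pairs whose span `[n, n+lag]` contains a
#' missing sample are dropped; order is preserved.
#'
#' @param bt Numeric temperature vector (`NA` allowed).
#' @param lag Lag in samples (default 1, i.e. 1 min at the native
#'   sampling).
#' @return Data frame with columns `x` (`BT_n`) and `y` (`BT_{n+lag}`) and
#'   attribute `lag`; possibly zero rows.
#' @export
#' @examples
#' lagged_pairs(c(37.0, 37.1, 37.2, 36.9))
lagged_pairs <- function(bt, lag = 1L) {
  bt <- as.numeric(bt)
  lag <- as.integer(lag)
  stopifnot(lag >= 1L)
  if (length(bt) <= lag)
    return(structure(data.frame(x = numeric(), y = numeric()), lag = lag))
  n <- length(bt) - lag
  ok <- !vapply(seq_len(n), function(i) anyNA(bt[i:(i + lag)]), logical(1))
  structure(data.frame(x = bt[seq_len(n)][ok], y = bt[seq_len(n) + lag][ok]),
            lag = lag)
}

#' SD1, SD2 and SDNN of a Poincare plot
#'
#' Short-term variability `sd1` (dispersion perpendicular to the identity
#' line, referenced to the line), long-term variability `sd2` (dispersion
#' along the line about the centroid), and the total variability
#' `sdnn = sqrt((sd1^2 + sd2^2)/2)`. Sample `(n - 1)` denominators
#' throughout.
#'
#' @param pairs Pair data frame from [lagged_pairs()].
#' @return Named list with `sd1`, `sd2`, `sdnn`, `n_pairs` (degC).
#' @export
sd1_sd2 <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) stop("fewer than 2 valid pairs", call. = FALSE)
  delta <- pairs$y - pairs$x
  m <- mean(c(pairs$x, pairs$y))
  D <- (pairs$x + pairs$y - 2 * m) / sqrt(2)
  sd1 <- sqrt(sum(delta^2) / (2 * (n - 1)))
  sd2 <- sqrt(sum(D^2) / (n - 1))
  list(sd1 = sd1, sd2 = sd2, sdnn = sqrt((sd1^2 + sd2^2) / 2), n_pairs = n)
}

#' Decrease/increase asymmetry partition of the Poincare variances
#'
#' Splits `sd1^2` and `sd2^2` by the sign of the consecutive change
#' `delta_n = BT_{n+1} - BT_n` (above the identity line: increases; below:
#' decreases) and returns the component standard deviations and relative
#' contributions. The decomposition is exact: `sd1d^2 + sd1i^2 = sd1^2`
#' and `sd2d^2 + sd2i^2 = sd2^2`; on-line points contribute nothing to the
#' short-term components and are split equally between the long-term ones.
#'
#' @param pairs Pair data frame from [lagged_pairs()].
#' @return Named list with `sd1d`, `sd1i`, `sd2d`, `sd2i` (degC) and
#'   `c1d`, `c1i`, `c2d`, `c2i` (fractions; `NA` when the corresponding
#'   total variance is zero).
#' @export
#' @examples
#' p <- lagged_pairs(c(37.0, 37.1, 37.2, 36.9))
#' asymmetry_partition(p)$c1d  # 0.09 / 0.11
asymmetry_partition <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) stop("fewer than 2 valid pairs", call. = FALSE)
  delta <- pairs$y - pairs$x
  m <- mean(c(pairs$x, pairs$y))
  D <- (pairs$x + pairs$y - 2 * m) / sqrt(2)
  denom <- n - 1
  dec <- delta < 0
  inc <- delta > 0
  on_line <- delta == 0

  sd1d2 <- sum(delta[dec]^2) / (2 * denom)
  sd1i2 <- sum(delta[inc]^2) / (2 * denom)
  sd2d2 <- (sum(D[dec]^2) + 0.5 * sum(D[on_line]^2)) / denom
  sd2i2 <- (sum(D[inc]^2) + 0.5 * sum(D[on_line]^2)) / denom

  sd1sq <- sd1d2 + sd1i2
  sd2sq <- sd2d2 + sd2i2
  ratio <- function(part, total) if (total > 0) part / total else NA_real_
  list(sd1d = sqrt(sd1d2), sd1i = sqrt(sd1i2),
       sd2d = sqrt(sd2d2), sd2i = sqrt(sd2i2),
       c1d = ratio(sd1d2, sd1sq), c1i = ratio(sd1i2, sd1sq),
       c2d = ratio(sd2d2, sd2sq), c2i = ratio(sd2i2, sd2sq))
}

#' Full Poincare descriptor set for one recording
#'
#' Convenience wrapper: builds the lagged pairs and returns SD1/SD2/SDNN
#' together with the asymmetry partition as one row.
#'
#' @param rec A [phase_recording()] or a bare numeric temperature vector.
#' @param lag Return-map lag in samples (default 1).
#' @return One-row data frame with `n_pairs`, `sd1`, `sd2`, `sdnn`,
#'   `sd1d`, `sd1i`, `sd2d`, `sd2i`, `c1d`, `c1i`, `c2d`, `c2i`.
#' @export
compute_poincare_descriptors <- function(rec, lag = 1L) {
  x <- if (inherits(rec, "phase_recording")) rec$temperature else
    as.numeric(rec)
  pairs <- lagged_pairs(x, lag = lag)
  base <- sd1_sd2(pairs)
  part <- asymmetry_partition(pairs)
  data.frame(n_pairs = base$n_pairs, sd1 = base$sd1, sd2 = base$sd2,
             sdnn = base$sdnn, part, stringsAsFactors = FALSE)
}

#' Classify a recording as short-/long-term asymmetric
#'
#' Short-term asymmetry is declared when `sd1d > sd1i` (decreases dominate
#' the short-term variance), long-term asymmetry when `sd2i > sd2d`
#' (increases dominate the long-term variance). Exact ties classify as not
#' asymmetric.
#'
#' @param desc Descriptor list or data frame containing `sd1d`, `sd1i`,
#'   `sd2d`, `sd2i` (vectorized over rows).
#' @return Data frame with logical columns `short_term_asymmetric` and
#'   `long_term_asymmetric`.
#' @export
classify_asymmetry <- function(desc) {
  data.frame(short_term_asymmetric = desc$sd1d > desc$sd1i,
             long_term_asymmetric = desc$sd2i > desc$sd2d)
}

#' Poincare scatter plot of a temperature series
#'
#' @param rec A [phase_recording()] or numeric temperature vector.
#' @param lag Return-map lag (default 1).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the pair data frame.
#' @export
plot_poincare <- function(rec, lag = 1L, ...) {
  x <- if (inherits(rec, "phase_recording")) rec$temperature else
    as.numeric(rec)
  pairs <- lagged_pairs(x, lag = lag)
  graphics::plot(pairs$x, pairs$y, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5), asp = 1,
                 xlab = expression(BT[n] ~ (degree * C)),
                 ylab = expression(BT[n + 1] ~ (degree * C)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pairs)
}
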