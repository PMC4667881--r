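# Shared fixtures and independent oracles, built in code at test time.

# Small cohort: 2 animals/group, 3 days, one handling event on day 3.
tiny_config <- function(seed = 42L, ...) {
  args <- list(n_animals_per_group = 2L, n_days = 3L, seed = seed, ...)
  if (is.null(args$events))
    args$events <- data.frame(day = 3L, clock = "09:00", kind = "handling",
                              stringsAsFactors = FALSE)
  do.call(synthetic_config, args)
}

empty_events_df <- function() {
  data.frame(time = as.POSIXct(character(), tz = "UTC"), kind = character())
}

no_event_schedule <- function() {
  data.frame(day = integer(), clock = character(), kind = character(),
             stringsAsFactors = FALSE)
}

# A hand-buildable series: one complete day starting at lights-on.
make_series <- function(temperature, activity = rep(0L, length(temperature)),
                        start = "2015-03-02 06:00", id = "r1",
                        group = "control", events = NULL) {
  telemetry_series(id, group, as.POSIXct(start, tz = "UTC"),
                   temperature, activity, events = events)
}

# Independent geometric oracle for the Poincare descriptors: per-point
# perpendicular distance to the identity line (projection onto (1,-1)/sqrt2)
# and along-line coordinate (projection onto (1,1)/sqrt2), aggregated with
# (n-1) denominators; the perpendicular moment is referenced to the line,
# the along-line variance to its own mean.
poincare_oracle <- function(x, lag = 1L) {
  n <- length(x) - lag
  keep <- vapply(seq_len(n), function(i) !anyNA(x[i:(i + lag)]), logical(1))
  a <- x[seq_len(n)][keep]
  b <- x[seq_len(n) + lag][keep]
  perp <- (a - b) / sqrt(2)          # signed distance to identity line
  along <- (a + b) / sqrt(2)
  m <- length(a)
  sd1 <- sqrt(sum(perp^2) / (m - 1))
  sd2 <- stats::sd(along)
  list(sd1 = sd1, sd2 = sd2, n = m)
}

# Brute-force asymmetry partition oracle: loops point by point.
partition_oracle <- function(x, lag = 1L) {
  n <- length(x) - lag
  keep <- vapply(seq_len(n), function(i) !anyNA(x[i:(i + lag)]), logical(1))
  a <- x[seq_len(n)][keep]
  b <- x[seq_len(n) + lag][keep]
  m <- mean(c(a, b))
  np <- length(a)
  s1d <- s1i <- s2d <- s2i <- 0
  for (i in seq_len(np)) {
    delta <- b[i] - a[i]
    D2 <- ((a[i] + b[i] - 2 * m) / sqrt(2))^2
    if (delta < 0) {
      s1d <- s1d + delta^2 / 2
      s2d <- s2d + D2
    } else if (delta > 0) {
      s1i <- s1i + delta^2 / 2
      s2i <- s2i + D2
    } else {
      s2d <- s2d + D2 / 2
      s2i <- s2i + D2 / 2
    }
  }
  list(sd1d2 = s1d / (np - 1), sd1i2 = s1i / (np - 1),
       sd2d2 = s2d / (np - 1), sd2i2 = s2i / (np - 1))
}

# Two-sided exact binomial p by brute-force minimum-likelihood summation.
binom_oracle <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= dbinom(k, n, 0.5) * (1 + 1e-7)])
}
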