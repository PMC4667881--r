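test_that("lagged pairs bind each temperature with the next", {
  p <- lagged_pairs(c(1, 2, 3))
  expect_equal(p$x, c(1, 2))
  expect_equal(p$y, c(2, 3))
  expect_identical(nrow(lagged_pairs(rnorm(720) + 37)), 719L)
  # pairs spanning a missing sample are dropped
  expect_identical(nrow(lagged_pairs(c(37, NA, 37.5))), 0L)
  expect_identical(nrow(lagged_pairs(c(37, NA, 37.5, 37.6), lag = 2)), 0L)
  expect_identical(nrow(lagged_pairs(c(37, 37.2, NA, 37.5, 37.6))), 2L)
  expect_error(sd1_sd2(lagged_pairs(c(37, NA, 37.5))), "fewer than 2")
})

test_that("degenerate plots give zero dispersion, not errors", {
  p <- lagged_pairs(rep(37, 100))
  s <- sd1_sd2(p)
  expect_equal(c(s$sd1, s$sd2, s$sdnn), c(0, 0, 0))
})

test_that("a strictly alternating series is pure short-term variability", {
  x <- rep(c(37, 36), length.out = 721)
  s <- sd1_sd2(lagged_pairs(x))
  expect_equal(s$sd1, 1 / sqrt(2), tolerance = 1e-3)
  expect_lt(s$sd2, 1e-9)
  # and perfectly symmetric: equal rises and falls
  part <- asymmetry_partition(lagged_pairs(x))
  expect_equal(part$c1d, 0.5, tolerance = 1e-12)
  expect_equal(part$c1i, 0.5, tolerance = 1e-12)
})

test_that("descriptors agree with the geometric rotation oracle", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:720, 1)
    x <- 37 + cumsum(rnorm(n, 0, 0.05))
    s <- sd1_sd2(lagged_pairs(x))
    o <- poincare_oracle(x)
    expect_equal(s$sd1, o$sd1, tolerance = 1e-12)
    expect_equal(s$sd2, o$sd2, tolerance = 1e-12)
  }
})

test_that("asymmetry partition matches the brute-force oracle exactly", {
  set.seed(102)
  for (i in 1:20) {
    n <- sample(10:300, 1)
    # quantized values force exact ties onto the identity line
    x <- 37 + round(cumsum(rnorm(n, 0, 0.05)), 1)
    part <- asymmetry_partition(lagged_pairs(x))
    o <- partition_oracle(x)
    expect_equal(part$sd1d^2, o$sd1d2, tolerance = 1e-14)
    expect_equal(part$sd1i^2, o$sd1i2, tolerance = 1e-14)
    expect_equal(part$sd2d^2, o$sd2d2, tolerance = 1e-14)
    expect_equal(part$sd2i^2, o$sd2i2, tolerance = 1e-14)
  }
})

test_that("decomposition and total-variability identities are exact", {
  set.seed(103)
  for (i in 1:25) {
    n <- sample(10:720, 1)
    x <- 37 + round(cumsum(rnorm(n, 0, 0.05)), 2)
    pairs <- lagged_pairs(x)
    s <- sd1_sd2(pairs)
    part <- asymmetry_partition(pairs)
    expect_equal(part$sd1d^2 + part$sd1i^2, s$sd1^2, tolerance = 1e-13)
    expect_equal(part$sd2d^2 + part$sd2i^2, s$sd2^2, tolerance = 1e-13)
    expect_equal(s$sdnn^2, (s$sd1^2 + s$sd2^2) / 2, tolerance = 1e-13)
    expect_equal(part$c1d + part$c1i, 1, tolerance = 1e-13)
    expect_equal(part$c2d + part$c2i, 1, tolerance = 1e-13)
    # total variance identity, exact once the drift term of the
    # line-referenced sd1 is accounted for
    m <- nrow(pairs)
    drift <- m * mean(pairs$y - pairs$x)^2 / (2 * (m - 1))
    expect_equal(s$sd1^2 + s$sd2^2,
                 stats::var(pairs$x) + stats::var(pairs$y) + drift,
                 tolerance = 1e-9)
  }
})

test_that("hand-computed partition example reproduces", {
  part <- asymmetry_partition(lagged_pairs(c(37.0, 37.1, 37.2, 36.9)))
  # deltas +0.1, +0.1, -0.3: decreases contribute 0.09 of 0.11
  expect_equal(part$c1d, 0.09 / 0.11, tolerance = 1e-12)
  expect_equal(part$c1i, 0.02 / 0.11, tolerance = 1e-12)
})

test_that("time reversal swaps decrease and increase components", {
  set.seed(104)
  x <- 37 + cumsum(rnorm(400, 0.0005, 0.03))
  f <- asymmetry_partition(lagged_pairs(x))
  r <- asymmetry_partition(lagged_pairs(rev(x)))
  expect_equal(f$sd1d, r$sd1i, tolerance = 1e-12)
  expect_equal(f$sd1i, r$sd1d, tolerance = 1e-12)
  expect_equal(f$c1d, r$c1i, tolerance = 1e-12)
  sf <- sd1_sd2(lagged_pairs(x))
  sr <- sd1_sd2(lagged_pairs(rev(x)))
  expect_equal(sf$sd1, sr$sd1, tolerance = 1e-12)
  expect_equal(sf$sd2, sr$sd2, tolerance = 1e-12)
})

test_that("scaling about the mean scales SDs and fixes contributions", {
  set.seed(105)
  x <- 37 + cumsum(rnorm(400, 0, 0.03))
  k <- 2.7
  y <- mean(x) + k * (x - mean(x))
  a <- compute_poincare_descriptors(x)
  b <- compute_poincare_descriptors(y)
  for (col in c("sd1", "sd2", "sdnn", "sd1d", "sd1i", "sd2d", "sd2i"))
    expect_equal(b[[col]], k * a[[col]], tolerance = 1e-10)
  for (col in c("c1d", "c1i", "c2d", "c2i"))
    expect_equal(b[[col]], a[[col]], tolerance = 1e-10)
})

test_that("zero short-term variance reports missing contributions", {
  part <- asymmetry_partition(lagged_pairs(rep(37, 50)))
  expect_true(is.na(part$c1d))
  expect_true(is.na(part$c2i))
})

test_that("asymmetry classification uses strict inequalities", {
  expect_true(classify_asymmetry(
    list(sd1d = 0.03, sd1i = 0.02, sd2d = 0.1, sd2i = 0.1))$short_term_asymmetric)
  cls <- classify_asymmetry(
    list(sd1d = 0.02, sd1i = 0.02, sd2d = 0.1, sd2i = 0.1))
  expect_false(cls$short_term_asymmetric)  # exact tie: not asymmetric
  expect_false(cls$long_term_asymmetric)
  expect_true(classify_asymmetry(
    list(sd1d = 0.02, sd1i = 0.02, sd2d = 0.1, sd2i = 0.2))$long_term_asymmetric)
})
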