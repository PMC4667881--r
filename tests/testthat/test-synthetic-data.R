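test_that("fixed seeds make activity and temperature bit-reproducible", {
  cfg <- tiny_config()
  phases <- phase_sequence(1)
  a1 <- simulate_activity(cfg, "control", phases, seed = 99)
  a2 <- simulate_activity(cfg, "control", phases, seed = 99)
  expect_identical(a1, a2)
  b1 <- simulate_temperature(cfg, "control", phases, a1, seed = 7)
  b2 <- simulate_temperature(cfg, "control", phases, a1, seed = 7)
  expect_identical(as.numeric(b1), as.numeric(b2))
  # whole-cohort determinism, and different seeds give different series
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  c3 <- simulate_cohort(tiny_config(seed = 43L))
  expect_identical(c1$series[[1]]$temperature, c2$series[[1]]$temperature)
  expect_false(identical(c1$series[[1]]$temperature,
                         c3$series[[1]]$temperature))
  expect_identical(c1$config_hash, c3$config_hash)
})

test_that("bout process matches its geometric run-length law", {
  # q_ai = q_ia = 0.5 -> mean active run 2.0
  cfg <- tiny_config()
  for (ph in c("light", "dark")) {
    cfg$groups$control$q_ai[[ph]] <- 0.5
    cfg$groups$control$q_ia[[ph]] <- 0.5
  }
  act <- simulate_activity(cfg, "control", rep("dark", 1e5), seed = 5)
  runs <- run_segmentation(act)
  mean_active <- mean(runs$length[runs$state == "active"])
  expect_lt(abs(mean_active - 2) / 2, 0.05)
  # near-degenerate limit: chain saturates active, MI -> 100%
  lim <- tiny_config()
  lim$groups$control$q_ai$dark <- 1e-4
  lim$groups$control$q_ia$dark <- 0.9999
  act_lim <- simulate_activity(lim, "control", rep("dark", 5000), seed = 6)
  expect_gt(compute_activity_descriptors(act_lim)$mi, 99)
})

test_that("closed-form MI/DI/DA are recovered from long simulations", {
  cfg <- tiny_config()
  q_ai <- cfg$groups$control$q_ai$dark
  q_ia <- cfg$groups$control$q_ia$dark
  act <- simulate_activity(cfg, "control", rep("dark", 2e4), seed = 21)
  d <- compute_activity_descriptors(act)
  ex <- bout_expectations(q_ai, q_ia)
  expect_lt(abs(d$mi - ex$mi) / ex$mi, 0.10)
  expect_lt(abs(d$di - ex$di) / ex$di, 0.10)
  expect_lt(abs(d$da - ex$da) / ex$da, 0.10)
  # RMI recovers the configured active-minute mean
  expect_lt(abs(d$rmi - cfg$groups$control$activity_mean$dark) /
              cfg$groups$control$activity_mean$dark, 0.10)
})

test_that("symmetric innovations give a symmetric Poincare partition", {
  cfg <- tiny_config(temperature_mode = "iid_increment")
  cfg$groups$control$mixture$light <-
    list(sigma_down = 0.03, sigma_up = 0.03, p_up = 0.5)
  bt <- simulate_temperature(cfg, "control", rep("light", 2e4), seed = 31)
  expect_lt(abs(compute_poincare_descriptors(bt)$c1d - 0.5), 0.02)
})

test_that("iid-increment mode recovers the mixture's closed-form C1d", {
  cfg <- tiny_config(temperature_mode = "iid_increment")
  mix <- cfg$groups$control$mixture$light
  target <- mixture_c1d(mix$sigma_down, mix$sigma_up, mix$p_up)
  expect_equal(target, 0.577, tolerance = 1e-12)
  set.seed(41)
  c1ds <- replicate(10, compute_poincare_descriptors(
    simulate_temperature(cfg, "control", rep("light", 720)))$c1d)
  expect_lt(abs(mean(c1ds) - target), 0.03)
})

test_that("calibrate_mixture inverts mixture_c1d with zero mean", {
  for (c1d in c(0.512, 0.525, 0.577, 0.7)) {
    m <- calibrate_mixture(c1d, 0.05)
    expect_equal(mixture_c1d(m$sigma_down, m$sigma_up, m$p_up), c1d,
                 tolerance = 1e-12)
    # zero-mean constraint of the half-normal mixture
    expect_equal(m$p_up * m$sigma_up, (1 - m$p_up) * m$sigma_down,
                 tolerance = 1e-12)
    # total second moment preserved
    expect_equal(m$p_up * m$sigma_up^2 + (1 - m$p_up) * m$sigma_down^2,
                 0.05^2, tolerance = 1e-12)
  }
})

test_that("raising sigma_down at fixed total variance raises mean C1d", {
  cfg <- tiny_config(temperature_mode = "iid_increment")
  means <- vapply(c(0.52, 0.56, 0.60), function(target) {
    cfg$groups$control$mixture$light <- calibrate_mixture(target, 0.03)
    set.seed(51)
    mean(replicate(20, compute_poincare_descriptors(
      simulate_temperature(cfg, "control", rep("light", 720)))$c1d))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("dark baseline exceeding light baseline shows in every recording", {
  cohort <- simulate_cohort(tiny_config(events = no_event_schedule()))
  for (s in cohort$series) {
    recs <- pool_recordings(
      label_conditions(split_phases(s), empty_events_df()))
    bt_mean <- vapply(recs, function(r) mean(r$temperature), numeric(1))
    phase <- vapply(recs, `[[`, character(1), "phase")
    expect_gt(min(bt_mean[phase == "dark"]), max(bt_mean[phase == "light"]))
  }
})

test_that("zero-amplitude events leave the signals untouched", {
  cfg <- tiny_config()
  flat <- tiny_config()
  for (g in names(flat$groups)) {
    flat$groups[[g]]$response$bt_amplitude <- 0
    flat$groups[[g]]$response$activity_amplitude <- 0
  }
  none <- tiny_config(events = no_event_schedule())
  c_flat <- simulate_cohort(flat)
  c_none <- simulate_cohort(none)
  # identical noise streams: the intervention kernel is deterministic, so
  # disturbed and undisturbed days are statistically indistinguishable
  expect_identical(c_flat$series[[1]]$temperature,
                   c_none$series[[1]]$temperature)
  expect_identical(c_flat$series[[1]]$activity, c_none$series[[1]]$activity)
  expect_gt(nrow(c_flat$series[[1]]$events), nrow(c_none$series[[1]]$events))
})

test_that("simulated temperatures respect the physiological bounds", {
  cohort <- simulate_cohort(tiny_config())
  for (s in cohort$series) {
    expect_true(all(s$temperature >= 30 & s$temperature <= 42))
    expect_true(all(s$activity >= 0))
  }
})

test_that("phenotype validation rejects inverted circadian structure", {
  bad <- synthetic_config()$groups
  bad$control$q_ia$dark <- 0.01  # dark active fraction below light
  expect_error(synthetic_config(groups = bad), "active fraction")
})
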