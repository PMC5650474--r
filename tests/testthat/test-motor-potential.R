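# Lagged correlation maps, population averaging, optimal efferent delay and
# trial-shuffled bootstrap significance.

make_coupled_instance <- function(n_trials = 9, n_times = 20, delay = 12,
                                  seed = 3) {
  # a_i(t) = g * v_i(t + delay) + c, noiseless: correlation 1 at lag -delay
  set.seed(seed)
  kin_time <- 0:(n_times - 1)
  act_time <- -30:(n_times + 29)
  v <- matrix(rnorm(n_trials * n_times), n_trials)
  a <- matrix(rnorm(n_trials * length(act_time), sd = 0.05), n_trials)
  idx <- match(kin_time - delay, act_time)
  a[, idx] <- 2 * v + 0.3
  list(activity = a, kinematics = v, activity_time = act_time,
       kin_time = kin_time)
}

test_that("constructed gain coupling gives correlation 1 at the injected lag", {
  inst <- make_coupled_instance(delay = 12)
  m <- lagged_correlation_map(inst$activity, inst$kinematics,
                              inst$activity_time, inst$kin_time,
                              lags = -30:30, times = inst$kin_time)
  at_lag <- m$corr[match(-12, m$lags), ]
  expect_true(all(abs(at_lag - 1) < 1e-12))
  # strictly lower elsewhere (gain jitter decorrelates other columns)
  others <- m$corr[m$lags != -12, ]
  expect_true(all(others[!is.na(others)] < 1 - 1e-6))
  tr <- optimal_delay_trace(m)
  expect_true(all(tr$delay == -12))
  expect_equal(mean_efferent_delay(tr, c(0, 19)), -12)
})

test_that("every map cell equals the brute-force Pearson oracle to 1e-12", {
  set.seed(8)
  n_trials <- 7; n_times <- 20
  kin_time <- -5:(n_times - 6)
  act_time <- -40:40
  a <- matrix(rnorm(n_trials * length(act_time)), n_trials)
  v <- matrix(rnorm(n_trials * n_times), n_trials)
  lags <- -20:20
  m <- lagged_correlation_map(a, v, act_time, kin_time, lags = lags,
                              times = kin_time)
  oracle <- brute_force_map(a, v, act_time, kin_time, lags, kin_time)
  expect_lt(max(abs(m$corr - oracle), na.rm = TRUE), 1e-12)
  expect_identical(unname(is.na(m$corr)), is.na(oracle))
})

test_that("neurons with fewer than 7 trials are excluded, not an error", {
  inst <- make_coupled_instance(n_trials = 6)
  expect_null(lagged_correlation_map(inst$activity, inst$kinematics,
                                     inst$activity_time, inst$kin_time))
})

test_that("population averaging is an unweighted NA-aware mean", {
  inst <- make_coupled_instance()
  m <- lagged_correlation_map(inst$activity, inst$kinematics,
                              inst$activity_time, inst$kin_time,
                              lags = -15:15, times = inst$kin_time)
  p1 <- population_average_map(list(m))
  expect_equal(p1$corr, m$corr)
  m2 <- m; m2$corr <- -m$corr
  p2 <- population_average_map(list(m, m2))
  expect_true(all(abs(p2$corr[!is.na(p2$corr)]) < 1e-12))
  # missing cells are ignored, not propagated
  m3 <- m; m3$corr[1, 1] <- NA
  p3 <- population_average_map(list(m, m3))
  expect_equal(p3$corr[1, 1], m$corr[1, 1])
})

test_that("a peak drifting parallel to the unity line has constant delay", {
  lags <- -20:20; times <- 0:15
  corr <- matrix(0, length(lags), length(times))
  for (j in seq_along(times)) {
    corr[match(-8, lags), j] <- 1   # peak at activity time t - 8 for every t
  }
  pm <- structure(list(corr = corr, lags = lags, times = times),
                  class = "mp_corr_map")
  tr <- optimal_delay_trace(pm)
  expect_true(all(tr$delay == -8))
})

test_that("argmax ties break toward the most causal lag and slices use nearest grid", {
  lags <- -10:10; times <- 0:4
  corr <- matrix(0, length(lags), length(times))
  corr[match(c(-6, 4), lags), ] <- 0.7    # exact tie at lags -6 and +4
  pm <- structure(list(corr = corr, lags = lags, times = times),
                  class = "mp_corr_map")
  expect_true(all(optimal_delay_trace(pm, ma_window = 1)$delay_raw == -6))
  sl <- correlation_timecourse_at_delay(pm, -6.4)
  expect_equal(unique(sl$lag), -6)
  expect_true(all(sl$corr == 0.7))
  sl2 <- correlation_timecourse_at_delay(pm, 0)
  expect_true(all(sl2$corr == 0))
})

test_that("mean efferent delay averages the smoothed trace over the window", {
  tr <- data.frame(time = 0:9, delay = rep(-12, 10))
  expect_equal(mean_efferent_delay(tr, c(0, 9)), -12)
  tr2 <- data.frame(time = 1:3, delay = c(-10, -12, -14))
  expect_equal(mean_efferent_delay(tr2, c(1, 3), min_points = 3), -12)
  expect_error(mean_efferent_delay(tr2, c(10, 20)), "delay points")
})

test_that("bootstrap significance is reproducible and calibrated on null data", {
  set.seed(12)
  times <- 0:19
  null_neurons <- lapply(1:8, function(i) {
    list(activity = matrix(rnorm(12 * 80), 12),
         kinematics = matrix(rnorm(12 * 20), 12),
         activity_time = -30:49, kin_time = times)
  })
  b1 <- bootstrap_significance(null_neurons, delay = -12, times = times,
                               n_shuffles = 100, seed = 9)
  b2 <- bootstrap_significance(null_neurons, delay = -12, times = times,
                               n_shuffles = 100, seed = 9)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$significant, b2$significant)
  expect_lt(mean(b1$significant), 0.25)     # null: no systematic significance
  expect_true(all(b1$ci_lower <= b1$ci_upper))
  # maximal signal: kinematics equal to (lagged) activity
  sig_neurons <- lapply(1:6, function(i) {
    inst <- make_coupled_instance(n_trials = 10, seed = 100 + i)
    list(activity = inst$activity, kinematics = inst$kinematics,
         activity_time = inst$activity_time, kin_time = inst$kin_time)
  })
  bs <- bootstrap_significance(sig_neurons, delay = -12, times = 0:19,
                               n_shuffles = 60, seed = 2)
  expect_true(all(bs$significant))
  # degenerate: identical trials -> undefined correlations, not significant
  deg <- list(list(activity = matrix(1, 8, 80), kinematics = matrix(2, 8, 20),
                   activity_time = -30:49, kin_time = times))
  bd <- bootstrap_significance(deg, delay = -12, times = times,
                               n_shuffles = 20, seed = 3)
  expect_true(all(is.na(bd$actual)))
  expect_false(any(bd$significant))
})

test_that("injected efference delays of 6, 12 and 20 ms are recovered within 2 ms", {
  for (d in c(6, 12, 20)) {
    cfg <- generator_config(n_control_trials = 40, n_blink_trials = 0,
                            n_brem_fixation_trials = 0, efference_delay = d)
    pop <- generate_population(10, cfg, seed = 500 + d)
    sdat <- lapply(seq_along(pop), function(i)
      preprocess_session(pop[[i]], neuron = sprintf("n%02d", i)))
    res <- motor_potential_analysis(sdat, condition = "control",
                                    n_shuffles = 2, seed = 1,
                                    delay_window = c(15, 45))
    expect_lt(abs(res$mean_delay - (-d)), 2)
  }
})
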