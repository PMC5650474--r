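# Synthetic-data generator: determinism, BREM loop closure, task structure,
# rate-velocity coupling and onset-delay structure.

test_that("sessions are deterministic given the seed and count bookkeeping holds", {
  cfg <- small_config()
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1, s2)
  cond <- vapply(s1$trials, `[[`, "", "condition")
  expect_equal(sum(cond == "control"), cfg$n_control_trials)
  expect_equal(sum(cond == "blink"), cfg$n_blink_trials)
  expect_equal(sum(cond == "brem"), cfg$n_brem_fixation_trials)
  expect_equal(nrow(s1$ground_truth), length(s1$trials))
  # gate opens at or before the saccade on every trial
  gt <- s1$ground_truth
  expect_true(all(gt$gate_open <= gt$sacc_on, na.rm = TRUE))
})

test_that("a session without blink trials is a valid control-only input", {
  cfg <- generator_config(n_control_trials = 5, n_blink_trials = 0,
                          n_brem_fixation_trials = 2, seed = 3)
  s <- generate_session(cfg)
  expect_equal(sum(vapply(s$trials, `[[`, "", "condition") == "blink"), 0)
  sd1 <- preprocess_session(s)
  expect_null(sd1$detections)
  expect_true(is.finite(sd1$divisor))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(generator_config(efference_delay = -1), "efference_delay")
  expect_error(generator_config(blink_threshold_fraction = 1.5),
               "blink_threshold_fraction")
  expect_error(generator_config(n_blink_trials = -2), "n_blink_trials")
  expect_error(generator_config(delay_range = c(800, 500)), "delay_range")
  expect_error(generator_config(post_blink_slope_multiplier = 0.5),
               "post_blink_slope_multiplier")
})

test_that("BREM draws close the loop and reduce to the template without variability", {
  cfg0 <- generator_config(brem_gain_sd = 0, brem_noise_sd = 0, seed = 1)
  set.seed(1)
  d1 <- generate_brem_velocity(cfg0)
  d2 <- generate_brem_velocity(cfg0)
  expect_equal(d1$h_vel, d2$h_vel)
  expect_equal(d1$v_vel, d2$v_vel)
  cfg <- generator_config(seed = 1)
  set.seed(7)
  for (i in 1:20) {
    d <- generate_brem_velocity(cfg)
    expect_lt(abs(sum(d$h_vel) / 1000), 0.5)   # net displacement, deg
    expect_lt(abs(sum(d$v_vel) / 1000), 0.5)
  }
})

test_that("Monte-Carlo BREM mean and s.d. match the analytic template and gain jitter", {
  cfg <- generator_config(seed = 1)
  tpl <- motorpotential:::brem_template_shape(cfg)
  set.seed(11)
  draws <- replicate(200, generate_brem_velocity(cfg)$h_vel)
  m <- rowMeans(draws)
  # central 80% of support, restricted to samples with substantial signal
  n <- length(tpl$h)
  core <- seq(ceiling(n * 0.1), floor(n * 0.9))
  core <- core[abs(tpl$h[core]) > 0.3 * max(abs(tpl$h))]
  expect_lt(max(abs(m[core] - tpl$h[core]) / abs(tpl$h[core])), 0.10)
  # at the template peak the s.d. is dominated by the configured gain jitter
  pk <- which.max(abs(tpl$h))
  sd_pred <- sqrt((cfg$brem_gain_sd * tpl$h[pk])^2 + cfg$brem_noise_sd^2)
  expect_lt(abs(sd(draws[pk, ]) - sd_pred) / sd_pred, 0.25)
})

test_that("control trials follow the task event ordering and the main sequence", {
  cfg <- small_config()
  s <- generate_session(cfg)
  for (tr in s$trials) {
    if (tr$condition != "control") next
    expect_lt(tr$events$target_on, tr$events$go_cue)
  }
  gt <- s$ground_truth
  ctrl <- gt[gt$condition == "control", ]
  expect_true(all(ctrl$sacc_on > 0))
  # main sequence: peak velocity strictly increases with amplitude
  amps <- c(5, 10, 15, 20, 25)
  vp <- main_sequence_velocity(amps, cfg)
  expect_true(all(diff(vp) > 0))
  peak_speed <- function(ecc) {
    cfg2 <- generator_config(n_control_trials = 1, n_blink_trials = 0,
                             n_brem_fixation_trials = 0, seed = 5,
                             target_eccentricity = ecc, burst_gain_sd = 0,
                             rate_noise_sd = 0, perp_noise_sd = 0,
                             position_noise_sd = 0, keep_latent = TRUE)
    tr <- generate_session(cfg2)$trials[[1]]
    max(sqrt(tr$latent$vh^2 + tr$latent$vv^2))
  }
  expect_gt(peak_speed(20), peak_speed(10))
})

test_that("without rate noise and burst jitter, peak eye speed is identical across trials", {
  cfg <- generator_config(n_control_trials = 6, n_blink_trials = 0,
                          n_brem_fixation_trials = 0, seed = 8,
                          burst_gain_sd = 0, rate_noise_sd = 0,
                          perp_noise_sd = 0, position_noise_sd = 0,
                          keep_latent = TRUE)
  s <- generate_session(cfg)
  peaks <- vapply(s$trials, function(tr)
    max(sqrt(tr$latent$vh^2 + tr$latent$vv^2)), numeric(1))
  expect_lt(diff(range(peaks)), 1e-9)
})

test_that("generated rate leads mid-saccade velocity by the efference delay with strong correlation", {
  cfg <- generator_config(n_control_trials = 100, n_blink_trials = 0,
                          n_brem_fixation_trials = 0, seed = 13,
                          keep_latent = TRUE)
  s <- generate_session(cfg)
  gt <- s$ground_truth
  d <- cfg$efference_delay
  # across-trial correlation of rate(t - 12 ms) with mid-saccade velocity
  mid <- 20   # ms after saccade onset, near the velocity peak
  a <- vapply(seq_along(s$trials), function(i) {
    tr <- s$trials[[i]]
    tr$latent$nrate[which(tr$time == gt$sacc_on[i] + mid - d)]
  }, numeric(1))
  v <- vapply(seq_along(s$trials), function(i) {
    tr <- s$trials[[i]]
    tr$latent$v_goal[which(tr$time == gt$sacc_on[i] + mid)]
  }, numeric(1))
  expect_gt(cor(a, v), 0.8)
  # brute-force lag sweep: trial-averaged correlation peaks at -efference_delay
  lags <- -30:10
  lag_cor <- vapply(lags, function(L) {
    aa <- vapply(seq_along(s$trials), function(i) {
      tr <- s$trials[[i]]
      tr$latent$nrate[which(tr$time == gt$sacc_on[i] + mid + L)]
    }, numeric(1))
    cor(aa, v)
  }, numeric(1))
  expect_lte(abs(lags[which.max(lag_cor)] - (-d)), 1)
})

test_that("blink trials express the leak coupling and a bimodal-ish onset-delay spread", {
  cfg <- generator_config(n_control_trials = 0, n_blink_trials = 200,
                          n_brem_fixation_trials = 0, seed = 17)
  s <- generate_session(cfg)
  delays <- s$ground_truth$onset_delay_true
  expect_true(all(delays >= 0))
  frac <- mean(delays >= 20)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.9)
  # with the leak removed, pre-saccade velocity carries no rate signal
  cfg0 <- generator_config(n_control_trials = 0, n_blink_trials = 60,
                           n_brem_fixation_trials = 0, seed = 18,
                           leak_gain = 0, keep_latent = TRUE)
  s0 <- generate_session(cfg0)
  gt0 <- s0$ground_truth
  ok <- which(gt0$onset_delay_true >= 25)
  v <- vapply(ok, function(i) {
    tr <- s0$trials[[i]]
    tr$latent$v_goal[which(tr$time == gt0$sacc_on[i] - 15)]
  }, numeric(1))
  expect_true(all(abs(v) < 1e-9))   # pure BREM handled separately; v_goal = 0
  # post-blink slope multiplier 1 makes true pre and post slopes equal
  cfg1 <- generator_config(n_control_trials = 0, n_blink_trials = 10,
                           n_brem_fixation_trials = 0, seed = 19,
                           post_blink_slope_multiplier = 1)
  gt1 <- generate_session(cfg1)$ground_truth
  expect_equal(gt1$slope_pre_hz, gt1$slope_post_hz)
})
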