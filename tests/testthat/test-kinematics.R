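# BREM templates, embedded-saccade detection, inclusion criteria and
# kinematic variables.

test_that("template mean/sd follow sample statistics with an s.d. floor", {
  f <- sin(seq(0, 2 * pi, length.out = 50)) * 30
  expect_warning(
    tpl0 <- build_brem_template(rbind(f, f), rbind(f, f), time = 0:49),
    "floored")
  expect_equal(tpl0$mean_h, f, ignore_attr = TRUE)
  expect_true(all(tpl0$sd_h >= 1e-3))
  tpl <- suppressWarnings(
    build_brem_template(rbind(f, -f), rbind(f, -f), time = 0:49))
  expect_equal(tpl$mean_h, rep(0, 50), ignore_attr = TRUE)
  keep <- abs(f) > 1            # away from zero crossings (floor applies there)
  expect_equal(tpl$sd_h[keep], abs(f)[keep] * sqrt(2), ignore_attr = TRUE)
  expect_error(build_brem_template(matrix(f, 1), matrix(f, 1)), "2 BREM")
})

test_that("template estimated from generator draws matches the analytic shape", {
  cfg <- generator_config(seed = 1)
  shape <- motorpotential:::brem_template_shape(cfg)
  set.seed(21)
  hs <- t(replicate(50, generate_brem_velocity(cfg)$h_vel))
  vs <- t(replicate(50, generate_brem_velocity(cfg)$v_vel))
  tpl <- build_brem_template(hs, vs, time = shape$time)
  n <- length(shape$h)
  core <- seq(ceiling(n * 0.1), floor(n * 0.9))
  core <- core[abs(shape$h[core]) > 0.3 * max(abs(shape$h))]
  expect_lt(max(abs(tpl$mean_h[core] - shape$h[core]) / abs(shape$h[core])),
            0.05)
})

test_that("embedded-saccade detection implements the 15-consecutive-sample rule", {
  tpl <- flat_template(n = 150, mean = 0, sd = 4)   # bounds at +/-10
  base_h <- rep(0, 150); base_v <- rep(0, 150)
  # template-mean trace: no deviation
  none <- detect_embedded_saccade(base_h, base_v, tpl, verify_speed = 0)
  expect_false(none$found)
  # horizontal exceeds bounds from 40 ms for 20 samples, vertical from 55 ms
  h <- base_h; h[41:60] <- 20
  v <- base_v; v[56:75] <- 20
  emb <- detect_embedded_saccade(h, v, tpl, verify_speed = 0)
  expect_true(emb$found)
  expect_equal(emb$onset_delay, 40)
  expect_equal(emb$component, "horizontal")
  expect_equal(emb$classification, "triggered")
  # a 14-sample excursion at 40 ms is ignored; the 30-sample one at 70 wins
  h2 <- base_h; h2[41:54] <- 20; h2[71:100] <- 20
  emb2 <- detect_embedded_saccade(h2, base_v, tpl, verify_speed = 0)
  expect_equal(emb2$onset_delay, 70)
  # onsets under 20 ms are classified early
  h3 <- base_h; h3[11:40] <- 20
  expect_equal(detect_embedded_saccade(h3, base_v, tpl,
                                       verify_speed = 0)$classification,
               "early")
})

test_that("saccade-likeness verification skips slow sustained excursions", {
  tpl <- flat_template(n = 200, mean = 0, sd = 4)
  h <- rep(0, 200)
  h[31:80] <- 20            # slow sustained drift: out of bounds, not a saccade
  h[101:140] <- 250         # the actual saccade
  with_ver <- detect_embedded_saccade(h, rep(0, 200), tpl)
  expect_equal(with_ver$onset_delay, 100)
  without <- detect_embedded_saccade(h, rep(0, 200), tpl, verify_speed = 0)
  expect_equal(without$onset_delay, 30)
})

test_that("widening the bounds never yields an earlier onset", {
  tpl <- flat_template(n = 200, mean = 0, sd = 4)
  set.seed(31)
  for (i in 1:20) {
    h <- cumsum(rnorm(200, sd = 3)); h[120:180] <- h[120:180] + 200
    v <- cumsum(rnorm(200, sd = 3))
    onsets <- vapply(c(1.5, 2.5, 4), function(m) {
      e <- detect_embedded_saccade(h, v, tpl, sd_multiplier = m,
                                   verify_speed = 0)
      if (e$found) e$onset_delay else 1e9   # "not found" counts as latest
    }, numeric(1))
    expect_true(all(diff(onsets) >= 0))
  }
})

test_that("inclusion criteria split neurons into threshold and motor-potential sets", {
  det <- rbind(
    data.frame(neuron = "a", trial_id = 1:6, onset_delay = c(25, 30, 40, 22, 28, 35)),
    data.frame(neuron = "b", trial_id = 1:10, onset_delay = c(rep(25, 5), rep(10, 5))),
    data.frame(neuron = "c", trial_id = 1:8, onset_delay = rep(30, 8)))
  inc <- apply_inclusion_criteria(det)
  expect_false("a" %in% inc$threshold_neurons)   # only 6 qualifying trials
  expect_true("b" %in% inc$threshold_neurons)    # 10 blink trials
  expect_false("b" %in% inc$motor_neurons)       # only 5 with delay >= 20
  expect_true("c" %in% inc$motor_neurons)        # 8 trials, all delayed
  expect_equal(nrow(inc$motor_set[inc$motor_set$neuron == "c", ]), 8)
  expect_true(all(inc$motor_set$onset_delay >= 20))
})

test_that("kinematic variables match their analytic definitions", {
  expect_equal(vectorial_velocity(3, 4), 5)
  expect_equal(vectorial_velocity(0, 0), 0)
  set.seed(41)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(vectorial_velocity(a, b), sqrt(a^2 + b^2))
  # residual subtraction
  tpl <- flat_template(n = 50, mean = 0, sd = 1)
  tpl$mean_h <- sin(1:50); tpl$mean_v <- cos(1:50)
  r0 <- residual_velocity(tpl$mean_h, tpl$mean_v, tpl)
  expect_equal(r0$h, rep(0, 50))
  r1 <- residual_velocity(tpl$mean_h + 10, tpl$mean_v, tpl)
  expect_equal(r1$h, rep(10, 50))
  expect_equal(r1$v, rep(0, 50))
  # beyond template support nothing is subtracted
  r2 <- residual_velocity(c(tpl$mean_h, 5, 5), c(tpl$mean_v, 1, 1), tpl)
  expect_equal(tail(r2$h, 2), c(5, 5))
  # signed goal projection
  expect_equal(project_on_goal(10, 0, 0), 10)
  expect_equal(project_on_goal(10, 0, 90), 0, tolerance = 1e-12)
  expect_equal(project_on_goal(-5, 5, 135), sqrt(50), tolerance = 1e-9)
  expect_equal(project_on_goal(5, 0, 180), -5)
  expect_equal(project_on_goal(0, 0, 45), 0)
})

test_that("goal projection is rotation-consistent", {
  set.seed(43)
  h <- rnorm(50); v <- rnorm(50)
  for (rot in c(30, 120, 275)) {
    th <- rot * pi / 180
    h2 <- cos(th) * h - sin(th) * v
    v2 <- sin(th) * h + cos(th) * v
    expect_equal(project_on_goal(h2, v2, 10 + rot),
                 project_on_goal(h, v, 10), tolerance = 1e-9)
  }
})

test_that("projected and raw kinematics agree closely during control saccades", {
  sd1 <- main_sdata()[[1]]
  proj <- neuron_motor_data(sd1, "control", window = c(5, 35), lag_range = 0,
                            variant = "projected")
  raw <- neuron_motor_data(sd1, "control", window = c(5, 35), lag_range = 0,
                           variant = "raw")
  cc <- cor(as.vector(proj$kinematics), as.vector(raw$kinematics))
  expect_gt(cc, 0.95)
})

test_that("endpoint accuracy normalises by target eccentricity", {
  expect_equal(endpoint_accuracy(c(10, 0), c(10, 0)), 0)
  expect_equal(endpoint_accuracy(c(0, 0), c(10, 0)), 1)
  expect_equal(endpoint_accuracy(c(10, 1), c(10, 0)), 0.1)
  expect_error(endpoint_accuracy(c(1, 1), c(0, 0)), "eccentricity")
})
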