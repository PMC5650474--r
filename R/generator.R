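# Synthetic delayed-saccade sessions with reflex-blink perturbations.
#
# The generative model couples a premotor rate model to eye kinematics through
# an efference delay and an omnipause-like gate; every latent quantity needed
# for parameter-recovery tests is recorded in the session's ground-truth table.

TARGET_ON_MS <- 300     # fixed target onset within a trial
FIX_BLINK_MS <- 400     # blink time on fixation-BREM trials

#' Main-sequence peak velocity
#'
#' Saturating amplitude -> peak-velocity relation
#' `Vp(A) = burst_gain * (1 - exp(-A / main_sequence_a0))`.
#'
#' @param amplitude saccade amplitude, deg.
#' @param config an [generator_config()] object.
#' @return peak velocity in deg/s.
#' @export
main_sequence_velocity <- function(amplitude, config) {
  config$burst_gain * (1 - exp(-amplitude / config$main_sequence_a0))
}

# Asymmetric raised-cosine velocity bell on the ms grid: a cosine rise over
# `rise` * duration and a cosine fall over the remainder (saccadic velocity
# profiles rise faster than they decay).  The time integral equals
# duration / 2 independent of `rise`, so amplitude bookkeeping is unchanged.
bell_profile <- function(t, onset, duration, rise = 0.25) {
  tau <- t - onset
  out <- numeric(length(t))
  d1 <- rise * duration
  d2 <- duration - d1
  up <- tau >= 0 & tau < d1
  dn <- tau >= d1 & tau <= duration
  out[up] <- 0.5 * (1 - cos(pi * tau[up] / d1))
  out[dn] <- 0.5 * (1 + cos(pi * (tau[dn] - d1) / d2))
  out
}

# Analytic BREM velocity template: each component is a difference of two
# gamma-shaped pulses (fast outward lobe, slower return lobe) normalised to
# equal area, so the loop closes exactly (zero net displacement).
brem_template_shape <- function(config) {
  t <- 0:config$brem_duration
  shape2 <- function(sh1, sc1, sh2, sc2) {
    p1 <- stats::dgamma(t, shape = sh1, scale = sc1)
    p2 <- stats::dgamma(t, shape = sh2, scale = sc2)
    p1 <- p1 / sum(p1)
    p2 <- p2 / sum(p2)
    d <- p1 - p2
    d / max(d)
  }
  list(time = t,
       h = config$brem_peak_h * shape2(2, 12, 5, 22),
       v = config$brem_peak_v * shape2(2, 16, 6, 20))
}

#' Draw one blink-related eye movement (BREM) velocity profile
#'
#' Returns the analytic loop-shaped template scaled by a per-trial gain drawn
#' from `N(1, brem_gain_sd)` plus smooth additive noise (demeaned over the
#' support, so the loop still closes).  With `brem_gain_sd = 0` and
#' `brem_noise_sd = 0` every call returns the identical template.
#'
#' @param config an [generator_config()] object.
#' @return list with `time` (ms), `h_vel`, `v_vel` (deg/s) and the drawn `gain`.
#' @export
generate_brem_velocity <- function(config) {
  tpl <- brem_template_shape(config)
  gain <- 1 + config$brem_gain_sd * stats::rnorm(1)
  n <- length(tpl$time)
  noise1 <- config$brem_noise_sd * smooth_noise(n, config$brem_noise_smooth_ms)
  noise2 <- config$brem_noise_sd * smooth_noise(n, config$brem_noise_smooth_ms)
  list(time = tpl$time,
       h_vel = gain * tpl$h + (noise1 - mean(noise1)),
       v_vel = gain * tpl$v + (noise2 - mean(noise2)),
       gain = gain)
}

# Inhomogeneous gamma-renewal spike generator via time rescaling.
# rate_hz: firing rate per 1 ms sample; shape 1 recovers a Poisson process.
sim_spikes <- function(rate_hz, shape) {
  lam <- cumsum(pmax(rate_hz, 0)) / 1000
  total <- lam[length(lam)]
  if (total <= 0) return(numeric(0))
  n_guess <- ceiling(total) + 10L + ceiling(4 * sqrt(total + 1))
  ct <- cumsum(stats::rgamma(n_guess, shape = shape, rate = shape))
  while (ct[length(ct)] < total) {
    ct <- c(ct, ct[length(ct)] +
              cumsum(stats::rgamma(n_guess, shape = shape, rate = shape)))
  }
  ev <- ct[ct <= total]
  if (!length(ev)) return(numeric(0))
  # invert the rescaling (make the cumulative strictly increasing first)
  lam <- lam + seq_along(lam) * 1e-12
  stats::approx(x = c(0, lam), y = c(0, seq_along(lam)), xout = ev)$y
}

# Per-trial latent draws shared between control and blink trials.
draw_trial_latents <- function(config) {
  d <- config$efference_delay
  t_thr <- max(60, stats::rnorm(1, config$rt_mean - config$afferent_delay - d,
                                config$rt_sd))
  list(
    t_thr = t_thr,                                  # ramp-start -> threshold, ms
    slope = config$threshold_level / t_thr,          # normalised units per ms
    scale = max(0.2, 1 + config$rate_scale_sd * stats::rnorm(1)),
    g     = max(0.1, 1 + config$burst_gain_sd * stats::rnorm(1)),
    perp  = config$perp_noise_sd * stats::rnorm(1),
    delay = stats::runif(1, config$delay_range[1], config$delay_range[2])
  )
}

# Assemble one trial from its latent variables.  `t_blink` is NA on control
# trials.  Returns list(trial, truth).
build_trial <- function(config, lat, t_blink, trial_id, condition) {
  d <- round(config$efference_delay)
  theta <- config$threshold_level
  b0 <- config$baseline_rate / config$peak_rate
  phi <- config$target_direction * pi / 180
  A <- config$target_eccentricity
  vp <- main_sequence_velocity(A, config)
  dur <- round(2 * A * 1000 / vp)

  go <- TARGET_ON_MS + round(lat$delay)
  ramp_start <- go + config$afferent_delay
  blink <- !is.na(t_blink)

  if (!blink) {
    t_trig <- round(ramp_start + lat$t_thr)
    cap_level <- theta
  } else {
    target_level <- config$blink_threshold_fraction * theta
    lvl_blink <- lat$slope * clamp(t_blink - ramp_start, 0, lat$t_thr)
    if (lvl_blink >= target_level) {
      t_trig <- t_blink + 2
    } else {
      t_trig <- t_blink + (target_level - lvl_blink) /
        (config$post_blink_slope_multiplier * lat$slope)
    }
    t_trig <- round(t_trig)
    cap_level <- max(target_level, lvl_blink)
  }
  t_sacc <- t_trig + d
  t_end <- t_sacc + dur + 150
  if (blink) t_end <- max(t_end, t_blink + config$brem_duration + 50)
  t <- 0:t_end
  n <- length(t)

  # preparatory level (normalised units, before the per-trial scale factor)
  if (!blink) {
    level <- lat$slope * clamp(t - ramp_start, 0, lat$t_thr)
  } else {
    pre <- lat$slope * clamp(t - ramp_start, 0, lat$t_thr)
    lvl_blink <- lat$slope * clamp(t_blink - ramp_start, 0, lat$t_thr)
    post <- lvl_blink + config$post_blink_slope_multiplier * lat$slope *
      (t - t_blink)
    level <- ifelse(t < t_blink, pre, pmin(post, cap_level))
  }
  prep <- lat$scale * (b0 + level)

  rise <- config$saccade_rise_fraction
  burst_shape <- bell_profile(t, t_trig, dur, rise)
  # preparatory noise is suppressed while the burst drive is active
  eps <- config$prep_noise_sd * smooth_noise(n, config$noise_smooth_ms) *
    (1 - burst_shape)
  nu  <- config$rate_noise_sd * smooth_noise(n, config$noise_smooth_ms)
  nrate <- prep + eps + (1 - theta) * burst_shape * (lat$g + nu)
  rate_hz <- config$peak_rate * pmax(nrate, 0)
  spikes <- sim_spikes(rate_hz, config$spike_regularity)

  # velocity read-out of the delayed rate
  shift <- function(x) c(rep(0, d), x[1:(n - d)])
  amp_scale <- 1
  if (blink) {
    gate_env <- as.numeric(t >= t_blink)
    taper <- t > (t_sacc + dur)
    gate_env[taper] <- pmax(0, 1 - (t[taper] - t_sacc - dur) / 20)
    # displacement-feedback compensation: the goal-directed profile covers
    # the error remaining after the expected pre/peri-saccadic leak drift,
    # keeping blink-triggered movements as accurate as control saccades
    leak_disp <- sum(config$leak_gain * shift(prep) * gate_env) / 1000
    amp_scale <- max(0.5, (A - leak_disp) / A)
  }
  burst_vel <- amp_scale * vp * bell_profile(t, t_trig + d, dur, rise) *
    (lat$g + shift(nu))
  v_goal <- burst_vel
  if (blink) {
    v_goal <- v_goal + config$leak_gain * shift(prep + eps) * gate_env
  }
  v_perp <- vp * bell_profile(t, t_trig + d, dur, rise) * lat$perp

  vh <- cos(phi) * v_goal - sin(phi) * v_perp
  vv <- sin(phi) * v_goal + cos(phi) * v_perp
  brem_gain <- NA_real_
  if (blink) {
    bdraw <- generate_brem_velocity(config)
    brem_gain <- bdraw$gain
    idx <- t - t_blink
    sel <- idx >= 0 & idx <= config$brem_duration
    vh[sel] <- vh[sel] + bdraw$h_vel[idx[sel] + 1L]
    vv[sel] <- vv[sel] + bdraw$v_vel[idx[sel] + 1L]
  }

  # noiseless 50 deg/s crossing (what a velocity-criterion detector estimates)
  det_speed <- sqrt((cos(phi) * burst_vel)^2 + (sin(phi) * burst_vel)^2)
  crit <- which(det_speed >= 50)
  sacc_on_criterion <- if (length(crit)) t[crit[1]] else NA_real_

  h_pos <- cumsum(vh) / 1000 + config$position_noise_sd * stats::rnorm(n)
  v_pos <- cumsum(vv) / 1000 + config$position_noise_sd * stats::rnorm(n)

  trial <- list(
    trial_id = trial_id,
    condition = condition,
    target = c(x = A * cos(phi), y = A * sin(phi)),
    events = list(target_on = TARGET_ON_MS, go_cue = go,
                  blink_on = if (blink) t_blink else NA_real_),
    time = t, h_pos = h_pos, v_pos = v_pos,
    spikes = spikes
  )
  if (isTRUE(config$keep_latent)) {
    trial$latent <- list(nrate = nrate, v_goal = v_goal,
                         vh = vh, vv = vv)
  }
  truth <- data.frame(
    trial_id = trial_id, condition = condition,
    go_cue = go, t_blink = if (blink) t_blink else NA_real_,
    gate_open = if (blink) t_blink else t_trig,
    sacc_on = t_sacc, sacc_on_criterion = sacc_on_criterion,
    onset_delay_true = if (blink) t_sacc - t_blink else NA_real_,
    rt_true = t_sacc - go,
    scale = lat$scale, burst_gain_i = lat$g, brem_gain_i = brem_gain,
    slope_pre_hz = lat$scale * lat$slope * config$peak_rate,
    slope_post_hz = lat$scale * lat$slope * config$peak_rate *
      if (blink) config$post_blink_slope_multiplier else 1
  )
  list(trial = trial, truth = truth)
}

#' Generate one control (unperturbed) delayed-saccade trial
#'
#' Uses the current RNG state; see [generate_session()] for seeded sessions.
#'
#' @param config an [generator_config()] object.
#' @param trial_id identifier recorded in the trial and ground-truth records.
#' @return list with elements `trial` (eye traces, events, spikes) and `truth`
#'   (one-row ground-truth data frame).
#' @export
generate_control_trial <- function(config, trial_id = 1L) {
  lat <- draw_trial_latents(config)
  build_trial(config, lat, t_blink = NA, trial_id = trial_id,
              condition = "control")
}

#' Generate one blink-perturbed trial
#'
#' The blink time is drawn uniformly in `blink_window` after the GO cue,
#' conditioned on preceding the trial's natural initiation time (in the
#' experiment, movements already underway at blink time are not
#' blink-triggered).  From blink onset the gate is open: the eye velocity is a
#' BREM draw plus `leak_gain` times the delayed preparatory rate, and the
#' saccade launches when the accelerated ramp reaches
#' `blink_threshold_fraction` of the control initiation level.
#'
#' @inheritParams generate_control_trial
#' @export
generate_blink_trial <- function(config, trial_id = 1L) {
  for (i in 1:200) {
    lat <- draw_trial_latents(config)
    go <- TARGET_ON_MS + round(lat$delay)
    t_blink <- round(go + stats::runif(1, config$blink_window[1],
                                       config$blink_window[2]))
    t_nat <- go + config$afferent_delay + lat$t_thr
    if (t_blink <= t_nat - 5) break
    if (i == 200) {                      # force a slow trial, keep determinism
      lat$t_thr <- (t_blink - go - config$afferent_delay) + 60
      lat$slope <- config$threshold_level / lat$t_thr
    }
  }
  build_trial(config, lat, t_blink = t_blink, trial_id = trial_id,
              condition = "blink")
}

# Fixation-BREM trial: blink during fixation, no target, baseline firing.
generate_brem_fixation_trial <- function(config, trial_id = 1L) {
  t_blink <- FIX_BLINK_MS
  t_end <- t_blink + config$brem_duration + 100
  t <- 0:t_end
  n <- length(t)
  scale <- max(0.2, 1 + config$rate_scale_sd * stats::rnorm(1))
  rate_hz <- config$baseline_rate * scale +
    config$prep_noise_sd * config$peak_rate *
      smooth_noise(n, config$noise_smooth_ms)
  spikes <- sim_spikes(rate_hz, config$spike_regularity)
  bdraw <- generate_brem_velocity(config)
  vh <- numeric(n); vv <- numeric(n)
  idx <- t - t_blink
  sel <- idx >= 0 & idx <= config$brem_duration
  vh[sel] <- bdraw$h_vel[idx[sel] + 1L]
  vv[sel] <- bdraw$v_vel[idx[sel] + 1L]
  h_pos <- cumsum(vh) / 1000 + config$position_noise_sd * stats::rnorm(n)
  v_pos <- cumsum(vv) / 1000 + config$position_noise_sd * stats::rnorm(n)
  trial <- list(trial_id = trial_id, condition = "brem",
                target = c(x = NA_real_, y = NA_real_),
                events = list(target_on = NA_real_, go_cue = NA_real_,
                              blink_on = t_blink),
                time = t, h_pos = h_pos, v_pos = v_pos, spikes = spikes)
  truth <- data.frame(
    trial_id = trial_id, condition = "brem", go_cue = NA_real_,
    t_blink = t_blink, gate_open = t_blink, sacc_on = NA_real_,
    sacc_on_criterion = NA_real_, onset_delay_true = NA_real_,
    rt_true = NA_real_, scale = scale, burst_gain_i = NA_real_,
    brem_gain_i = bdraw$gain, slope_pre_hz = NA_real_,
    slope_post_hz = NA_real_)
  list(trial = trial, truth = truth)
}

#' Generate a full synthetic session (one neuron)
#'
#' Deterministic given `config$seed`: fixation-BREM trials, control trials and
#' blink trials are drawn in a fixed order from a single RNG stream.
#'
#' @param config an [generator_config()] object.
#' @return An object of class `mp_session`: list with `trials` (list of trial
#'   records), `ground_truth` (data frame, one row per trial) and `config`.
#' @examples
#' s <- generate_session(generator_config(n_control_trials = 3,
#'                                        n_blink_trials = 2,
#'                                        n_brem_fixation_trials = 2,
#'                                        seed = 7))
#' table(vapply(s$trials, `[[`, "", "condition"))
#' @export
generate_session <- function(config) {
  validate_config(config)
  set.seed(as.integer(config$seed) %% .Machine$integer.max)
  trials <- vector("list", config$n_brem_fixation_trials +
                     config$n_control_trials + config$n_blink_trials)
  truths <- vector("list", length(trials))
  id <- 0L
  for (i in seq_len(config$n_brem_fixation_trials)) {
    id <- id + 1L
    r <- generate_brem_fixation_trial(config, id)
    trials[[id]] <- r$trial; truths[[id]] <- r$truth
  }
  for (i in seq_len(config$n_control_trials)) {
    id <- id + 1L
    r <- generate_control_trial(config, id)
    trials[[id]] <- r$trial; truths[[id]] <- r$truth
  }
  for (i in seq_len(config$n_blink_trials)) {
    id <- id + 1L
    r <- generate_blink_trial(config, id)
    trials[[id]] <- r$trial; truths[[id]] <- r$truth
  }
  out <- list(trials = trials,
              ground_truth = do.call(rbind, truths),
              config = config)
  class(out) <- "mp_session"
  out
}

#' @export
print.mp_session <- function(x, ...) {
  cond <- vapply(x$trials, `[[`, "", "condition")
  cat(sprintf("Synthetic session: %d trials (%d control, %d blink, %d BREM)\n",
              length(cond), sum(cond == "control"), sum(cond == "blink"),
              sum(cond == "brem")))
  cat(sprintf("  efference delay %g ms, seed %s\n",
              x$config$efference_delay, format(x$config$seed)))
  invisible(x)
}

#' Generate a population of single-neuron sessions
#'
#' One session per neuron, with session seeds derived deterministically from
#' `seed`.  By default target directions are spread evenly around the circle
#' (response-field centres span all directions), while the fixed nasal-downward
#' BREM is shared by all sessions.
#'
#' @param n_neurons number of sessions.
#' @param config base [generator_config()]; per-session seed, target
#'   direction and eccentricity are overridden.
#' @param seed population-level seed.
#' @param spread_directions logical; evenly space target directions.
#' @param eccentricity_range per-session target eccentricities are drawn
#'   uniformly from this range (deg), mimicking response-field centres
#'   spanning 9-25 deg; set to `NULL` to keep `config$target_eccentricity`.
#' @return list of `mp_session` objects.
#' @export
generate_population <- function(n_neurons, config = generator_config(),
                                seed = 1L, spread_directions = TRUE,
                                eccentricity_range = c(9, 25)) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  session_seeds <- sample.int(2^31 - 2, n_neurons)
  dirs <- if (spread_directions) {
    seq(0, 360, length.out = n_neurons + 1)[seq_len(n_neurons)]
  } else rep(config$target_direction, n_neurons)
  eccs <- if (is.null(eccentricity_range)) {
    rep(config$target_eccentricity, n_neurons)
  } else {
    stats::runif(n_neurons, eccentricity_range[1], eccentricity_range[2])
  }
  lapply(seq_len(n_neurons), function(i) {
    cfg <- config
    cfg$seed <- session_seeds[i]
    cfg$target_direction <- dirs[i]
    cfg$target_eccentricity <- eccs[i]
    generate_session(cfg)
  })
}
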