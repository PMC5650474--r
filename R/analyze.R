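# Session-level preprocessing: velocities, movement detection, BREM template,
# embedded-saccade detection, spike densities and alignment helpers that feed
# the motor-potential and initiation analyses.

#' Preprocess one session
#'
#' Computes component velocities (zero-phase smoothed derivative of position),
#' detects movements with the 50/30 deg/s criteria, builds the session BREM
#' template from fixation-blink trials, detects the goal-directed saccade
#' embedded in each blink-triggered movement (±`sd_multiplier` s.d. /
#' `min_run`-sample rule), computes spike density functions and the
#' control-derived normalisation divisor.
#'
#' @param session an `mp_session` (from [generate_session()] or
#'   [read_session_bundle()]).
#' @param kernel_width Gaussian s.d. of the spike-density kernel, ms
#'   (3 ms for correlation/threshold analyses).
#' @param sd_multiplier,min_run embedded-saccade detection parameters.
#' @param neuron identifier attached to output tables.
#' @return object of class `mp_session_data`.
#' @export
preprocess_session <- function(session, kernel_width = 3,
                               sd_multiplier = 2.5, min_run = 15L,
                               neuron = "n1") {
  trials <- session$trials
  cond <- vapply(trials, `[[`, "", "condition")
  support <- session$config$brem_duration

  prep <- lapply(trials, function(tr) {
    vh <- compute_velocity(tr$h_pos)
    vv <- compute_velocity(tr$v_pos)
    search_from <- switch(tr$condition,
      control = tr$events$go_cue + 30,
      blink   = tr$events$blink_on - 20,
      brem    = tr$events$blink_on - 20)
    mv <- detect_movement(vh, vv, time = tr$time, search_from = search_from)
    dens <- spike_density(tr$spikes, kernel_width,
                          window = range(tr$time))
    list(vh = vh, vv = vv, movement = mv, density = dens$rate)
  })

  # BREM template from fixation-blink trials aligned to detected onset
  bidx <- which(cond == "brem")
  template <- NULL
  if (length(bidx) >= 2) {
    slices <- lapply(bidx, function(i) {
      p <- prep[[i]]
      if (!p$movement$found) return(NULL)
      i0 <- match(p$movement$onset, trials[[i]]$time)
      take <- i0:min(i0 + support, length(p$vh))
      cbind(h = p$vh[take], v = p$vv[take])
    })
    slices <- Filter(Negate(is.null), slices)
    len <- min(vapply(slices, nrow, 1L))
    template <- build_brem_template(
      t(vapply(slices, function(s) s[seq_len(len), "h"], numeric(len))),
      t(vapply(slices, function(s) s[seq_len(len), "v"], numeric(len))),
      time = 0:(len - 1))
  }

  # embedded-saccade detection on blink trials
  detections <- lapply(which(cond == "blink"), function(i) {
    p <- prep[[i]]
    out <- data.frame(neuron = neuron, trial_id = trials[[i]]$trial_id,
                      movement_on = NA_real_, sacc_on = NA_real_,
                      onset_delay = NA_real_, component = NA_character_,
                      classification = NA_character_)
    if (!p$movement$found || is.null(template)) return(out)
    out$movement_on <- p$movement$onset
    i0 <- match(p$movement$onset, trials[[i]]$time)
    take <- i0:length(p$vh)
    emb <- detect_embedded_saccade(p$vh[take], p$vv[take], template,
                                   sd_multiplier = sd_multiplier,
                                   min_run = min_run)
    if (emb$found) {
      out$onset_delay <- emb$onset_delay
      out$sacc_on <- p$movement$onset + emb$onset_delay
      out$component <- emb$component
      out$classification <- emb$classification
    }
    out
  })
  detections <- if (length(detections)) do.call(rbind, detections) else NULL

  # saccade onset per trial: control = detected movement onset;
  # blink = movement onset + embedded onset delay
  sacc_on <- rep(NA_real_, length(trials))
  for (i in which(cond == "control")) {
    if (prep[[i]]$movement$found) sacc_on[i] <- prep[[i]]$movement$onset
  }
  if (!is.null(detections)) {
    ids <- vapply(trials, `[[`, 1L, "trial_id")
    sacc_on[match(detections$trial_id, ids)] <- detections$sacc_on
  }

  # control-derived normalisation divisor (peak of trial-averaged density
  # aligned on saccade onset)
  cidx <- which(cond == "control" & !is.na(sacc_on))
  avg <- aligned_average(trials, prep, cidx, sacc_on, c(-300, 150), "density")
  norm <- normalize_rates(lapply(prep, `[[`, "density"), avg$mean)
  for (i in seq_along(prep)) prep[[i]]$density_norm <- norm$normalised[[i]]

  behavior <- do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]; p <- prep[[i]]
    if (tr$condition == "brem" || !p$movement$found) return(NULL)
    ioff <- match(p$movement$offset, tr$time)
    acc <- endpoint_accuracy(c(tr$h_pos[ioff], tr$v_pos[ioff]), tr$target)
    data.frame(neuron = neuron, trial_id = tr$trial_id,
               condition = tr$condition,
               rt = p$movement$onset - tr$events$go_cue,
               blink_rel = if (tr$condition == "blink")
                 tr$events$blink_on - tr$events$go_cue else NA_real_,
               accuracy = acc,
               peak_velocity = p$movement$peak_velocity)
  }))

  structure(list(session = session, prep = prep, cond = cond,
                 template = template, detections = detections,
                 sacc_on = sacc_on, divisor = norm$divisor,
                 behavior = behavior, neuron = neuron,
                 kernel_width = kernel_width),
            class = "mp_session_data")
}

# Average a per-trial series aligned to per-trial reference times.
# series: "density", "density_norm".  Returns list(time, mean, mat).
aligned_average <- function(trials, prep, idx, ref, window, series) {
  w <- window[1]:window[2]
  mat <- t(vapply(idx, function(i) {
    j <- match(ref[i] + w, trials[[i]]$time)
    prep[[i]][[series]][j]
  }, numeric(length(w))))
  list(time = w, mean = colMeans(mat, na.rm = TRUE), mat = mat)
}

# Per-trial goal direction (deg) from fixation at the origin to the target.
goal_direction <- function(trial) {
  atan2(trial$target["y"], trial$target["x"]) * 180 / pi
}

#' Aligned activity and kinematics matrices for one neuron
#'
#' Builds the across-trial matrices used by [lagged_correlation_map()] and
#' [bootstrap_significance()]: normalised spike density and the chosen
#' kinematic variable, aligned to saccade onset.  For blink trials the
#' kinematics are the BREM-template-subtracted residuals; for the
#' `"projected"` variants the (residual) velocity is projected on the goal
#' direction, for `"raw"` the unsigned vectorial velocity is used.
#'
#' @param sdata an `mp_session_data`.
#' @param condition `"control"` or `"blink"`.
#' @param trial_ids optional subset of trial ids (e.g. the motor-potential
#'   inclusion set).
#' @param window movement-time window around saccade onset, ms.
#' @param lag_range maximum |lag|, ms: the activity matrix is extended by
#'   this much on both sides.
#' @param variant `"projected"` (default) or `"raw"`.
#' @return list with `activity`, `kinematics`, `activity_time`, `kin_time`,
#'   `n_trials`.
#' @export
neuron_motor_data <- function(sdata, condition, trial_ids = NULL,
                              window = c(-50, 50), lag_range = 50,
                              variant = c("projected", "raw")) {
  variant <- match.arg(variant)
  trials <- sdata$session$trials
  ids <- vapply(trials, `[[`, 1L, "trial_id")
  idx <- which(sdata$cond == condition & !is.na(sdata$sacc_on))
  if (!is.null(trial_ids)) idx <- idx[ids[idx] %in% trial_ids]
  kin_time <- window[1]:window[2]
  act_time <- (window[1] - lag_range):(window[2] + lag_range)
  get_row <- function(i) {
    tr <- trials[[i]]; p <- sdata$prep[[i]]
    vh <- p$vh; vv <- p$vv
    if (condition == "blink") {
      # subtract the template aligned at overall movement onset
      m_on <- sdata$detections$movement_on[
        match(tr$trial_id, sdata$detections$trial_id)]
      rel <- tr$time - m_on
      sel <- rel >= 0 & rel <= max(sdata$template$time)
      vh[sel] <- vh[sel] - sdata$template$mean_h[rel[sel] + 1L]
      vv[sel] <- vv[sel] - sdata$template$mean_v[rel[sel] + 1L]
    }
    kin <- if (variant == "projected") {
      project_on_goal(vh, vv, goal_direction(tr))
    } else {
      vectorial_velocity(vh, vv)
    }
    ref <- sdata$sacc_on[i]
    list(a = p$density_norm[match(ref + act_time, tr$time)],
         v = kin[match(ref + kin_time, tr$time)])
  }
  rows <- lapply(idx, get_row)
  list(activity = t(vapply(rows, `[[`, numeric(length(act_time)), "a")),
       kinematics = t(vapply(rows, `[[`, numeric(length(kin_time)), "v")),
       activity_time = act_time, kin_time = kin_time,
       n_trials = length(rows))
}
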