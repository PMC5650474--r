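# BREM templates, embedded-saccade detection, inclusion criteria and
# kinematic variables.

#' Build a BREM velocity template from fixation-blink trials
#'
#' Pointwise mean and standard deviation of horizontal and vertical BREM
#' velocity, with traces aligned to their detected movement onset and
#' truncated to a common support.  Upper/lower detection bounds follow as
#' mean +/- `sd_multiplier` * sd.
#'
#' @param h_traces,v_traces matrices (trials x time) of aligned component
#'   velocities, deg/s.
#' @param time ms grid of the common support (default 0-based).
#' @param sd_floor zero standard deviations are floored at this value
#'   (deg/s) with a warning.
#' @return object of class `mp_brem_template`: `time`, `mean_h`, `mean_v`,
#'   `sd_h`, `sd_v`, `n_trials`.
#' @export
build_brem_template <- function(h_traces, v_traces,
                                time = seq_len(ncol(h_traces)) - 1,
                                sd_floor = 1e-3) {
  if (!is.matrix(h_traces) || nrow(h_traces) < 2)
    stop("at least 2 BREM trials are required to build a template",
         call. = FALSE)
  stopifnot(identical(dim(h_traces), dim(v_traces)))
  sd_col <- function(m) apply(m, 2, stats::sd)
  sd_h <- sd_col(h_traces); sd_v <- sd_col(v_traces)
  if (any(sd_h < sd_floor) || any(sd_v < sd_floor)) {
    warning("BREM template s.d. floored at ", sd_floor,
            " deg/s at some samples", call. = FALSE)
    sd_h <- pmax(sd_h, sd_floor); sd_v <- pmax(sd_v, sd_floor)
  }
  structure(list(time = time,
                 mean_h = colMeans(h_traces), mean_v = colMeans(v_traces),
                 sd_h = sd_h, sd_v = sd_v, n_trials = nrow(h_traces)),
            class = "mp_brem_template")
}

#' Detect the goal-directed saccade embedded in a blink-triggered movement
#'
#' Per component, finds the first time at which the movement velocity deviates
#' from the BREM template mean by more than `sd_multiplier` standard
#' deviations and stays outside those bounds for at least `min_run`
#' consecutive samples; the earlier component crossing is taken as saccade
#' onset.  Beyond the template support the last defined bound is used.
#' Onsets are classified as `"early"` (< `classify_ms`) or `"triggered"`.
#'
#' Candidate deviations are additionally verified to be saccade-like: within
#' `verify_within` ms of a candidate onset the residual (template-subtracted)
#' vectorial velocity must reach `verify_speed` deg/s, otherwise the
#' candidate is rejected and the search continues.  This is the algorithmic
#' counterpart of manually checking that detected deviations are actual
#' saccades rather than sustained excursions of BREM variability, which the
#' bound rule alone cannot distinguish.  Set `verify_speed = 0` to disable.
#'
#' @param h_vel,v_vel movement velocity aligned to its own overall movement
#'   onset, on the template grid (sample 1 = movement onset).
#' @param template an `mp_brem_template`.
#' @param sd_multiplier bound half-width in template s.d. units (default 2.5).
#' @param min_run minimum consecutive samples outside the bounds (default 15).
#' @param classify_ms early/triggered classification boundary, ms.
#' @param verify_speed,verify_within saccade-likeness verification: required
#'   residual speed (deg/s) within this many ms of the candidate onset.
#' @return list of class `mp_embedded`: `found`, `onset_delay` (ms from
#'   movement onset), `component` and `classification`; `found = FALSE` when
#'   no qualifying excursion exists (trial excluded downstream).
#' @export
detect_embedded_saccade <- function(h_vel, v_vel, template,
                                    sd_multiplier = 2.5, min_run = 15L,
                                    classify_ms = 20,
                                    verify_speed = 100, verify_within = 40) {
  n <- length(h_vel)
  extend <- function(x) {
    if (n <= length(x)) x[seq_len(n)] else c(x, rep(x[length(x)], n - length(x)))
  }
  res_h <- h_vel - extend(template$mean_h)
  res_v <- v_vel - extend(template$mean_v)
  out_h <- abs(res_h) > sd_multiplier * extend(template$sd_h)
  out_v <- abs(res_v) > sd_multiplier * extend(template$sd_v)
  res_speed <- sqrt(res_h^2 + res_v^2)
  verified <- function(i) {
    if (verify_speed <= 0) return(TRUE)
    max(res_speed[i:min(n, i + verify_within)]) >= verify_speed
  }
  # earliest verified sustained excursion over both components
  next_candidate <- function(flag, from) {
    i <- first_sustained(flag[from:length(flag)], min_run)
    if (is.na(i)) NA_integer_ else from + i - 1L
  }
  best <- NA_integer_; best_comp <- NA_character_
  for (comp in c("horizontal", "vertical")) {
    flag <- if (comp == "horizontal") out_h else out_v
    from <- 1L
    while (from <= n) {
      cand <- next_candidate(flag, from)
      if (is.na(cand)) break
      if (verified(cand)) {
        if (is.na(best) || cand < best) {
          best <- cand; best_comp <- comp
        }
        break
      }
      # skip past the rejected excursion
      run_end <- cand
      while (run_end <= n && flag[run_end]) run_end <- run_end + 1L
      from <- run_end
    }
  }
  if (is.na(best)) {
    return(structure(list(found = FALSE, onset_delay = NA_real_,
                          component = NA_character_,
                          classification = NA_character_),
                     class = "mp_embedded"))
  }
  onset_delay <- template$time[1] + (best - 1L)
  structure(list(found = TRUE, onset_delay = onset_delay,
                 component = best_comp,
                 classification = if (onset_delay < classify_ms) "early"
                                  else "triggered"),
            class = "mp_embedded")
}

#' Apply the neuron/trial inclusion criteria
#'
#' Given a per-trial detection table across neurons, forms the two analysis
#' sets: the *threshold* set keeps neurons with at least `min_trials` blink
#' trials (all their blink trials retained); the *motor-potential /
#' accumulation* set keeps neurons with at least `min_trials` blink trials
#' whose embedded-saccade onset delay is at least `min_delay` ms (only those
#' trials retained).
#'
#' @param detections data frame with columns `neuron`, `trial_id`,
#'   `onset_delay` (NA when no embedded saccade was found).
#' @param min_trials minimum qualifying blink trials per neuron (default 7).
#' @param min_delay onset-delay criterion, ms (default 20).
#' @return list with data frames `threshold_set` and `motor_set` (subsets of
#'   `detections`) and the corresponding neuron id vectors
#'   `threshold_neurons`, `motor_neurons`.
#' @export
apply_inclusion_criteria <- function(detections, min_trials = 7L,
                                     min_delay = 20) {
  det <- detections[!is.na(detections$onset_delay), , drop = FALSE]
  n_all <- table(det$neuron)
  thr_neurons <- names(n_all)[n_all >= min_trials]
  delayed <- det[det$onset_delay >= min_delay, , drop = FALSE]
  n_del <- table(delayed$neuron)
  mot_neurons <- names(n_del)[n_del >= min_trials]
  list(threshold_set = det[det$neuron %in% thr_neurons, , drop = FALSE],
       motor_set = delayed[delayed$neuron %in% mot_neurons, , drop = FALSE],
       threshold_neurons = thr_neurons,
       motor_neurons = mot_neurons)
}

#' Vectorial (radial) velocity
#'
#' Pointwise Euclidean magnitude of the two velocity components.
#'
#' @param h_vel,v_vel component velocities, deg/s.
#' @return numeric vector, deg/s (non-negative).
#' @export
vectorial_velocity <- function(h_vel, v_vel) {
  stopifnot(length(h_vel) == length(v_vel))
  sqrt(h_vel^2 + v_vel^2)
}

#' Residual velocity after BREM template subtraction
#'
#' Componentwise subtraction of the template mean from a blink-triggered
#' movement aligned to its overall movement onset; beyond the template
#' support nothing is subtracted.
#'
#' @param h_vel,v_vel aligned movement velocity (sample 1 = movement onset).
#' @param template an `mp_brem_template`.
#' @return list with residual components `h` and `v`.
#' @export
residual_velocity <- function(h_vel, v_vel, template) {
  n <- length(h_vel)
  pad <- function(m) {
    if (n <= length(m)) m[seq_len(n)] else c(m, rep(0, n - length(m)))
  }
  list(h = h_vel - pad(template$mean_h), v = v_vel - pad(template$mean_v))
}

#' Signed projection of a velocity signal on the saccade-goal direction
#'
#' Returns `sqrt(vh^2 + vv^2) * cos(theta)` where `theta` is the angle between
#' the instantaneous velocity vector and the goal direction - equivalently the
#' scalar projection onto the goal unit vector, which can be negative when the
#' eye moves away from the goal.  Zero-magnitude vectors project to 0.
#'
#' @param h_vel,v_vel (residual) velocity components, deg/s.
#' @param goal_direction goal direction in degrees (fixation -> target).
#' @return signed projected velocity, deg/s.
#' @export
project_on_goal <- function(h_vel, v_vel, goal_direction) {
  phi <- goal_direction * pi / 180
  h_vel * cos(phi) + v_vel * sin(phi)
}

#' Normalised saccade endpoint error
#'
#' Euclidean distance from the movement endpoint to the target, divided by
#' target eccentricity (distance fixation -> target).
#'
#' @param endpoint,target,fixation length-2 numeric (x, y) positions, deg.
#' @return unitless normalised error.
#' @export
endpoint_accuracy <- function(endpoint, target, fixation = c(0, 0)) {
  ecc <- sqrt(sum((target - fixation)^2))
  if (ecc == 0) stop("target eccentricity is zero", call. = FALSE)
  sqrt(sum((endpoint - target)^2)) / ecc
}
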