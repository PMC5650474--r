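# Population-level analyses and the end-to-end pipeline.

#' Population motor-potential analysis
#'
#' Per neuron, builds the aligned activity/kinematics matrices and the lagged
#' correlation map; averages maps across neurons; derives the optimal
#' efferent-delay trace and the bootstrap significance of the correlation
#' time course at the mean delay.
#'
#' @param sessions_data list of `mp_session_data`.
#' @param condition `"control"` or `"blink"`.
#' @param trial_sets optional named list (by neuron id) of trial-id vectors to
#'   keep (e.g. the motor-potential inclusion set).
#' @param window movement-time window, ms.
#' @param lags lag grid, ms.
#' @param variant kinematic variant, see [neuron_motor_data()].
#' @param delay_window window over which the mean efferent delay is taken
#'   (and at whose rounded mean the bootstrap slice is computed).
#' @param n_shuffles,seed bootstrap parameters.
#' @param min_trials per-neuron inclusion threshold (default 7).
#' @return list of class `mp_motor_result`: `popmap`, `delay_trace`,
#'   `mean_delay`, `bootstrap`, `n_neurons`.
#' @export
motor_potential_analysis <- function(sessions_data, condition = "control",
                                     trial_sets = NULL,
                                     window = c(-50, 50), lags = -50:50,
                                     variant = "projected",
                                     delay_window = c(15, 45),
                                     n_shuffles = 100L, seed = 1L,
                                     min_trials = 7L) {
  ndata <- lapply(sessions_data, function(sd) {
    keep <- if (!is.null(trial_sets)) trial_sets[[sd$neuron]] else NULL
    if (!is.null(trial_sets) && is.null(keep)) return(NULL)
    neuron_motor_data(sd, condition, trial_ids = keep, window = window,
                      lag_range = max(abs(lags)), variant = variant)
  })
  ndata <- Filter(function(x) !is.null(x) && x$n_trials >= min_trials, ndata)
  if (!length(ndata)) stop("no neurons pass the inclusion criteria",
                           call. = FALSE)
  maps <- lapply(ndata, function(nd) {
    lagged_correlation_map(nd$activity, nd$kinematics, nd$activity_time,
                           nd$kin_time, lags = lags,
                           times = nd$kin_time, min_trials = min_trials)
  })
  popmap <- population_average_map(maps)
  trace <- optimal_delay_trace(popmap)
  mean_delay <- mean_efferent_delay(trace, delay_window)
  boot <- bootstrap_significance(ndata, delay = round(mean_delay),
                                 times = popmap$times,
                                 n_shuffles = n_shuffles, seed = seed)
  structure(list(popmap = popmap, delay_trace = trace,
                 mean_delay = mean_delay, delay_window = delay_window,
                 bootstrap = boot, n_neurons = length(maps),
                 condition = condition, variant = variant),
            class = "mp_motor_result")
}

#' @export
print.mp_motor_result <- function(x, ...) {
  cat(sprintf("Motor potential (%s, %s kinematics): %d neurons\n",
              x$condition, x$variant, x$n_neurons))
  cat(sprintf("  mean optimal efferent delay in [%g, %g] ms: %.2f ms\n",
              x$delay_window[1], x$delay_window[2], x$mean_delay))
  sig <- x$bootstrap$time[x$bootstrap$significant]
  if (length(sig))
    cat(sprintf("  significant correlation from %g to %g ms\n",
                min(sig), max(sig)))
  invisible(x)
}

#' Initiation-threshold analysis
#'
#' Saccade-aligned normalised activity compared between control and blink
#' trials: per-neuron bin means (population signed-rank tests and linear
#' fits) and per-neuron trial-wise classification (rank-sum at
#' `alpha_classify`).
#'
#' @param sessions_data list of `mp_session_data`.
#' @param trial_sets named list (by neuron) of blink trial ids to use
#'   (the threshold inclusion set); `NULL` = all detected blink trials.
#' @param bin_edges left edges of the 10 ms bins, ms.
#' @param bin_width bin width, ms.
#' @param alpha_population,alpha_classify significance levels.
#' @return list of class `mp_threshold_result`: `bins` (comparison table),
#'   `classification`, `control_bins`, `blink_bins`.
#' @export
threshold_analysis <- function(sessions_data, trial_sets = NULL,
                               bin_edges = seq(-50, 10, by = 10),
                               bin_width = 10,
                               alpha_population = 0.05,
                               alpha_classify = 0.001) {
  per_neuron <- lapply(sessions_data, function(sd) {
    trials <- sd$session$trials
    ids <- vapply(trials, `[[`, 1L, "trial_id")
    keep <- if (!is.null(trial_sets)) trial_sets[[sd$neuron]] else
      ids[sd$cond == "blink"]
    cidx <- which(sd$cond == "control" & !is.na(sd$sacc_on))
    kidx <- which(sd$cond == "blink" & !is.na(sd$sacc_on) & ids %in% keep)
    if (!length(kidx)) return(NULL)
    win <- c(min(bin_edges) - 5, max(bin_edges) + bin_width + 5)
    ctrl <- aligned_average(trials, sd$prep, cidx, sd$sacc_on, win,
                            "density_norm")
    blnk <- aligned_average(trials, sd$prep, kidx, sd$sacc_on, win,
                            "density_norm")
    bin_rows <- function(mat, time) {
      t(apply(mat, 1, function(r) binned_activity(time, r, bin_edges,
                                                  bin_width)))
    }
    list(ctrl_mean = binned_activity(ctrl$time, ctrl$mean, bin_edges,
                                     bin_width),
         blink_mean = binned_activity(blnk$time, blnk$mean, bin_edges,
                                      bin_width),
         ctrl_trials = bin_rows(ctrl$mat, ctrl$time),
         blink_trials = bin_rows(blnk$mat, blnk$time))
  })
  per_neuron <- Filter(Negate(is.null), per_neuron)
  if (!length(per_neuron)) stop("no neurons with blink trials", call. = FALSE)
  control_bins <- t(vapply(per_neuron, `[[`,
                           numeric(length(bin_edges)), "ctrl_mean"))
  blink_bins <- t(vapply(per_neuron, `[[`,
                         numeric(length(bin_edges)), "blink_mean"))
  bins <- population_bin_comparison(control_bins, blink_bins,
                                    alpha = alpha_population)
  cls <- classify_neuron_timecourse(lapply(per_neuron, `[[`, "ctrl_trials"),
                                    lapply(per_neuron, `[[`, "blink_trials"),
                                    alpha = alpha_classify)
  structure(list(bins = bins, classification = cls,
                 control_bins = control_bins, blink_bins = blink_bins,
                 bin_edges = bin_edges),
            class = "mp_threshold_result")
}

#' Accumulation-rate-change analysis
#'
#' Per neuron: the trial-averaged 10 ms-kernel normalised density aligned on
#' blink onset (blink trials with onset delay >= `min_delay`) and on
#' pseudo-blink onset (pooled surrogate control trials with the matching
#' onset-gap condition) is fitted piecewise-linearly 20 ms before/after the
#' (pseudo-)blink; slopes and modulation indices are compared across neurons.
#'
#' @param sessions_data list of `mp_session_data` preprocessed with the
#'   10 ms kernel (`preprocess_session(kernel_width = 10)`).
#' @param trial_sets named list (by neuron) of blink trial ids (the
#'   motor-potential/accumulation inclusion set).
#' @param n_pseudo pseudo-trials per neuron (default 1000).
#' @param seed RNG seed for the surrogate draws.
#' @param min_delay onset-gap condition, ms (default 20).
#' @param half fit half-window, ms (default 20).
#' @return list of class `mp_rate_result`: `fits` (per-neuron data frame),
#'   `tests` (from [compare_rate_conditions()]).
#' @export
accumulation_analysis <- function(sessions_data, trial_sets = NULL,
                                  n_pseudo = 1000L, seed = 1L,
                                  min_delay = 20, half = 20) {
  fits <- lapply(sessions_data, function(sd) {
    trials <- sd$session$trials
    ids <- vapply(trials, `[[`, 1L, "trial_id")
    keep <- if (!is.null(trial_sets)) trial_sets[[sd$neuron]] else
      ids[sd$cond == "blink"]
    kidx <- which(sd$cond == "blink" & ids %in% keep & !is.na(sd$sacc_on))
    cidx <- which(sd$cond == "control" & !is.na(sd$sacc_on))
    if (length(kidx) < 1 || length(cidx) < 1) return(NULL)
    win <- c(-half - 5, half + 5)
    blink_on <- vapply(kidx, function(i) trials[[i]]$events$blink_on,
                       numeric(1))
    ref <- sd$sacc_on; ref[kidx] <- blink_on
    bl <- aligned_average(trials, sd$prep, kidx, ref, win, "density_norm")
    fit_b <- piecewise_rate_fit(bl$time, bl$mean, 0, half = half)

    # surrogate: pseudo-blink times (relative to GO) resampled from this
    # session's blink-time distribution, assigned to resampled control trials
    go <- vapply(trials, function(tr) tr$events$go_cue %||% NA_real_,
                 numeric(1))
    blink_rel <- vapply(which(sd$cond == "blink"),
                        function(i) trials[[i]]$events$blink_on - go[i],
                        numeric(1))
    sur <- make_surrogate_control(cidx, sd$sacc_on[cidx] - go[cidx],
                                  blink_rel, n_pseudo = n_pseudo,
                                  seed = seed, min_onset_gap = min_delay)
    # the same control trial can recur with different pseudo-blink times,
    # so the pooled pseudo-trial average is built row by row
    pa_ref <- go[sur$trial_id] + sur$pseudo_blink
    w <- win[1]:win[2]
    mat <- t(vapply(seq_len(nrow(sur)), function(r) {
      i <- sur$trial_id[r]
      j <- match(pa_ref[r] + w, trials[[i]]$time)
      sd$prep[[i]]$density_norm[j]
    }, numeric(length(w))))
    fit_s <- piecewise_rate_fit(w, colMeans(mat, na.rm = TRUE), 0,
                                half = half)
    data.frame(neuron = sd$neuron,
               rate_pre_blink = fit_b$rate_pre,
               rate_post_blink = fit_b$rate_post,
               index_blink = fit_b$modulation_index,
               rate_pre_surrogate = fit_s$rate_pre,
               rate_post_surrogate = fit_s$rate_post,
               index_surrogate = fit_s$modulation_index)
  })
  fits <- do.call(rbind, Filter(Negate(is.null), fits))
  tests <- compare_rate_conditions(
    data.frame(rate_pre = fits$rate_pre_blink,
               rate_post = fits$rate_post_blink,
               modulation_index = fits$index_blink),
    data.frame(rate_pre = fits$rate_pre_surrogate,
               rate_post = fits$rate_post_surrogate,
               modulation_index = fits$index_surrogate))
  structure(list(fits = fits, tests = tests), class = "mp_rate_result")
}

#' Behavioural summary: reaction times and endpoint accuracy
#'
#' Reaction time (movement onset from the GO cue) compared between blink and
#' control trials with a one-tailed t-test (blink < control); endpoint
#' accuracy with a two-tailed t-test; Spearman correlation of blink time with
#' accuracy.
#'
#' @param sessions_data list of `mp_session_data`.
#' @return list of class `mp_behavior`.
#' @export
behavioral_summary <- function(sessions_data) {
  beh <- do.call(rbind, lapply(sessions_data, `[[`, "behavior"))
  ctrl <- beh[beh$condition == "control", ]
  blnk <- beh[beh$condition == "blink", ]
  has_blink <- nrow(blnk) >= 3
  rt_test <- if (has_blink)
    stats::t.test(blnk$rt, ctrl$rt, alternative = "less") else NULL
  acc_test <- if (has_blink) stats::t.test(blnk$accuracy, ctrl$accuracy)
              else NULL
  sp <- if (has_blink) suppressWarnings(
    stats::cor.test(blnk$blink_rel, blnk$accuracy, method = "spearman"))
    else NULL
  structure(list(
    rt_mean_control = mean(ctrl$rt),
    rt_mean_blink = if (has_blink) mean(blnk$rt) else NA_real_,
    rt_p = if (has_blink) rt_test$p.value else NA_real_,
    accuracy_mean_control = mean(ctrl$accuracy),
    accuracy_mean_blink = if (has_blink) mean(blnk$accuracy) else NA_real_,
    accuracy_p = if (has_blink) acc_test$p.value else NA_real_,
    blinktime_accuracy_rho = if (has_blink) unname(sp$estimate) else NA_real_,
    blinktime_accuracy_p = if (has_blink) sp$p.value else NA_real_,
    table = beh), class = "mp_behavior")
}

#' @export
print.mp_behavior <- function(x, ...) {
  cat(sprintf("RT: control %.0f ms, blink %.0f ms (one-tailed p = %.3g)\n",
              x$rt_mean_control, x$rt_mean_blink, x$rt_p))
  cat(sprintf("Accuracy: control %.3f, blink %.3f (p = %.3g)\n",
              x$accuracy_mean_control, x$accuracy_mean_blink, x$accuracy_p))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Generates (or takes) a population of synthetic sessions and runs every
#' stage: preprocessing, embedded-saccade detection, inclusion criteria,
#' behavioural summary, control and blink motor-potential analyses (with
#' pre/post-onset efferent delays and bootstrap significance), the
#' initiation-threshold analysis and the accumulation-rate analysis.
#'
#' @param config an [generator_config()]; ignored if `sessions` is given.
#' @param sessions optional list of `mp_session` objects.
#' @param n_neurons population size when generating.
#' @param seed population seed (also used for bootstrap/surrogate stages).
#' @param post_window,pre_window delay-averaging windows, ms.  Both keep a
#'   15 ms guard around the detected saccade onset, where the optimal-delay
#'   argmax is dominated by onset-detection jitter covariance rather than
#'   the efferent coupling.
#' @param n_shuffles,n_pseudo bootstrap / surrogate sizes.
#' @param variant kinematic variant for the correlation analyses.
#' @return object of class `mp_report`.
#' @export
run_full_analysis <- function(config = generator_config(), sessions = NULL,
                              n_neurons = 20L, seed = 1L,
                              post_window = c(15, 45), pre_window = c(-30, -15),
                              n_shuffles = 100L, n_pseudo = 1000L,
                              variant = "projected") {
  if (is.null(sessions))
    sessions <- generate_population(n_neurons, config, seed = seed)
  sdata <- lapply(seq_along(sessions), function(i) {
    preprocess_session(sessions[[i]], kernel_width = 3,
                       neuron = sprintf("n%02d", i))
  })
  sdata10 <- lapply(seq_along(sessions), function(i) {
    preprocess_session(sessions[[i]], kernel_width = 10,
                       neuron = sprintf("n%02d", i))
  })
  detections <- do.call(rbind, lapply(sdata, `[[`, "detections"))
  has_det <- !is.null(detections) && nrow(detections) > 0
  inclusion <- if (has_det) apply_inclusion_criteria(detections) else
    list(threshold_set = NULL, motor_set = NULL,
         threshold_neurons = character(0), motor_neurons = character(0))
  sets_from <- function(df) if (is.null(df)) list() else
    split(df$trial_id, df$neuron)
  thr_sets <- sets_from(inclusion$threshold_set)
  mot_sets <- sets_from(inclusion$motor_set)

  behavior <- behavioral_summary(sdata)

  has_blink <- has_det && length(inclusion$motor_neurons) > 0
  keep_motor <- vapply(sdata, function(sd) sd$neuron %in%
                         inclusion$motor_neurons, logical(1))

  control_mp <- motor_potential_analysis(
    if (any(keep_motor)) sdata[keep_motor] else sdata,
    condition = "control", window = c(-50, 50),
    delay_window = post_window, n_shuffles = n_shuffles, seed = seed,
    variant = variant)

  blink_mp <- NULL; pre_delay <- NA_real_; pre_post_p <- NA_real_
  threshold <- NULL; rates <- NULL
  if (has_blink) {
    blink_mp <- motor_potential_analysis(
      sdata[keep_motor], condition = "blink", trial_sets = mot_sets,
      window = c(-50, 50), delay_window = post_window,
      n_shuffles = n_shuffles, seed = seed, variant = variant)
    pre_delay <- mean_efferent_delay(blink_mp$delay_trace, pre_window)
    pre_sel <- blink_mp$delay_trace$time >= pre_window[1] &
      blink_mp$delay_trace$time <= pre_window[2]
    post_sel <- blink_mp$delay_trace$time >= post_window[1] &
      blink_mp$delay_trace$time <= post_window[2]
    pre_post_p <- stats::t.test(blink_mp$delay_trace$delay[pre_sel],
                                blink_mp$delay_trace$delay[post_sel])$p.value
    threshold <- threshold_analysis(sdata, trial_sets = thr_sets)
    rates <- accumulation_analysis(sdata10[keep_motor],
                                   trial_sets = mot_sets,
                                   n_pseudo = n_pseudo, seed = seed)
  }
  structure(list(
    behavior = behavior, detections = detections, inclusion = inclusion,
    control_motor = control_mp, blink_motor = blink_mp,
    control_post_delay = control_mp$mean_delay,
    blink_post_delay = if (!is.null(blink_mp)) blink_mp$mean_delay
                       else NA_real_,
    blink_pre_delay = pre_delay, pre_post_p = pre_post_p,
    threshold = threshold, rates = rates,
    n_neurons = length(sdata), seed = seed), class = "mp_report")
}

#' @export
print.mp_report <- function(x, ...) {
  cat(sprintf("Full pipeline report (%d neurons, seed %s)\n",
              x$n_neurons, format(x$seed)))
  print(x$behavior)
  cat(sprintf("Control post-onset efferent delay: %.2f ms\n",
              x$control_post_delay))
  if (!is.null(x$blink_motor)) {
    cat(sprintf("Blink post-onset delay: %.2f ms; pre-onset: %.2f ms (p = %.2f)\n",
                x$blink_post_delay, x$blink_pre_delay, x$pre_post_p))
  } else cat("Blink analyses: absent (no blink trials)\n")
  invisible(x)
}
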