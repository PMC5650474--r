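# Across-trial lagged correlation between activity and kinematics, optimal
# efferent delay, and trial-shuffled bootstrap significance.

#' Lagged across-trial correlation map for one neuron
#'
#' For each movement time `t` in `times` and each lag `delta` in `lags`,
#' computes the Pearson correlation *across trials* between the activity at
#' `t + delta` and the kinematic variable at `t`:
#' `c(t + delta, t) = corr(a(t + delta), v(t))`.
#' Negative lags mean activity leads the movement (causal).  Cells where
#' either vector has zero variance are `NA` and are excluded from population
#' averages.
#'
#' @param activity matrix (trials x time) of activity; its columns are
#'   indexed by `activity_time` (ms).
#' @param kinematics matrix (trials x time) of the kinematic variable,
#'   columns indexed by `kin_time` (ms, typically relative to saccade onset).
#' @param activity_time,kin_time column time stamps, ms.
#' @param lags integer lags, ms (default -50..50).
#' @param times movement times at which to evaluate (default: all of
#'   `kin_time` for which every lag is available).
#' @param min_trials neurons with fewer trials are excluded (returns `NULL`).
#' @return object of class `mp_corr_map`: `corr` (lags x times matrix),
#'   `lags`, `times`, `n_trials`; or `NULL` if excluded.
#' @export
lagged_correlation_map <- function(activity, kinematics,
                                   activity_time, kin_time,
                                   lags = -50:50, times = NULL,
                                   min_trials = 7L) {
  stopifnot(nrow(activity) == nrow(kinematics),
            ncol(activity) == length(activity_time),
            ncol(kinematics) == length(kin_time))
  n <- nrow(activity)
  if (n < min_trials) return(NULL)
  if (is.null(times)) {
    times <- kin_time[kin_time + min(lags) >= min(activity_time) &
                      kin_time + max(lags) <= max(activity_time)]
  }
  # full cross-correlation between all activity and kinematic columns
  std <- function(m) {
    mc <- sweep(m, 2, colMeans(m))
    s <- sqrt(colSums(mc^2))
    out <- sweep(mc, 2, s, "/")
    out[, s == 0] <- NA_real_
    out
  }
  ka <- match(times, kin_time)
  cc <- crossprod(std(activity), std(kinematics[, ka, drop = FALSE]))
  corr <- matrix(NA_real_, length(lags), length(times),
                 dimnames = list(lag = lags, time = times))
  for (j in seq_along(times)) {
    ia <- match(times[j] + lags, activity_time)
    ok <- !is.na(ia)
    corr[ok, j] <- cc[ia[ok], j]
  }
  structure(list(corr = corr, lags = lags, times = times, n_trials = n),
            class = "mp_corr_map")
}

#' Average correlation maps across neurons
#'
#' Unweighted mean of per-neuron correlation maps, cell by cell, ignoring
#' missing cells.  All maps must share the same lag/time grids.
#'
#' @param maps list of `mp_corr_map` objects (`NULL` entries are dropped).
#' @return an `mp_corr_map` with `n_neurons` recorded.
#' @export
population_average_map <- function(maps) {
  maps <- Filter(Negate(is.null), maps)
  if (!length(maps)) stop("no neuron maps to average", call. = FALSE)
  ref <- maps[[1]]
  arr <- vapply(maps, function(m) m$corr, ref$corr)
  avg <- apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  dimnames(avg) <- dimnames(ref$corr)
  structure(list(corr = avg, lags = ref$lags, times = ref$times,
                 n_neurons = length(maps)),
            class = "mp_corr_map")
}

#' Optimal efferent-delay trace from a population correlation map
#'
#' For each movement time, finds the activity time at which the population
#' average correlation peaks; the optimal delay is its (signed) distance from
#' the unity line, i.e. the arg-max lag.  Ties are broken toward the most
#' negative (most causal) lag.  A centred moving average (`ma_window` ms,
#' shrinking at the edges) smooths the trace.
#'
#' @param popmap `mp_corr_map` (population average).
#' @param ma_window moving-average window, ms (default 5).
#' @return data frame of class `mp_delay_trace` with `time`, `delay_raw`
#'   and `delay` (smoothed), ms; `delay < 0` means activity leads (causal).
#' @export
optimal_delay_trace <- function(popmap, ma_window = 5L) {
  raw <- apply(popmap$corr, 2, function(col) {
    if (all(is.na(col))) return(NA_real_)
    popmap$lags[which.max(col)]       # lags ascend, so first max = most causal
  })
  out <- data.frame(time = popmap$times, delay_raw = raw,
                    delay = moving_average(raw, ma_window))
  class(out) <- c("mp_delay_trace", "data.frame")
  out
}

#' Mean optimal efferent delay over a movement-time window
#'
#' @param trace an `mp_delay_trace` (or data frame with `time`, `delay`).
#' @param window length-2 numeric, ms (inclusive).
#' @param min_points minimum defined delay points required (default 5).
#' @return scalar mean delay, ms.
#' @export
mean_efferent_delay <- function(trace, window, min_points = 5L) {
  sel <- trace$time >= window[1] & trace$time <= window[2] &
    !is.na(trace$delay)
  if (sum(sel) < min_points)
    stop(sprintf("fewer than %d defined delay points in window [%g, %g]",
                 min_points, window[1], window[2]), call. = FALSE)
  mean(trace$delay[sel])
}

#' Correlation time course at a fixed efferent delay
#'
#' Slice of the population map at the lag nearest to `delay`.
#'
#' @param popmap `mp_corr_map`.
#' @param delay lag to slice at, ms (rounded to the nearest grid lag).
#' @return data frame with `time` and `corr`.
#' @export
correlation_timecourse_at_delay <- function(popmap, delay) {
  i <- which.min(abs(popmap$lags - delay))
  data.frame(time = popmap$times, corr = popmap$corr[i, ],
             lag = popmap$lags[i])
}

#' Trial-shuffled bootstrap significance of the correlation time course
#'
#' For each shuffle, the trial pairing between activity and kinematics is
#' permuted within each neuron and the population average correlation at the
#' given delay recomputed.  At each time point the distribution of
#' (actual - shuffled) differences across shuffles gives a 95% confidence
#' interval; the correlation is significant where that interval excludes 0.
#'
#' @param neuron_data list, one element per neuron, each a list with
#'   `activity`, `kinematics` matrices and `activity_time`, `kin_time`.
#' @param delay efferent delay (lag) at which to evaluate, ms.
#' @param times movement-time grid, ms.
#' @param n_shuffles number of trial shuffles (default 100).
#' @param seed RNG seed for the shuffles.
#' @param conf confidence level (default 0.95).
#' @return list of class `mp_bootstrap`: `time`, `actual` (population mean
#'   correlation), `shuffle_mean`, `ci_lower`, `ci_upper` (CI of the
#'   difference distribution), `significant` (logical).
#' @export
bootstrap_significance <- function(neuron_data, delay, times,
                                   n_shuffles = 100L, seed = 1L,
                                   conf = 0.95) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2", call. = FALSE)
  trace_one <- function(nd, perm = NULL) {
    ia <- match(times + delay, nd$activity_time)
    ik <- match(times, nd$kin_time)
    a <- nd$activity[, ia, drop = FALSE]
    v <- nd$kinematics[, ik, drop = FALSE]
    if (!is.null(perm)) v <- v[perm, , drop = FALSE]
    col_cor(a, v)
  }
  pop_mean <- function(mat) {
    apply(mat, 2, function(x) if (all(is.na(x))) NA_real_
          else mean(x, na.rm = TRUE))
  }
  actual_mat <- t(vapply(neuron_data, trace_one, numeric(length(times))))
  actual <- pop_mean(actual_mat)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  shuffles <- matrix(NA_real_, n_shuffles, length(times))
  for (s in seq_len(n_shuffles)) {
    m <- t(vapply(neuron_data, function(nd) {
      trace_one(nd, perm = sample(nrow(nd$activity)))
    }, numeric(length(times))))
    shuffles[s, ] <- pop_mean(m)
  }
  diffs <- sweep(-shuffles, 2, actual, "+")      # actual - shuffled
  alpha <- (1 - conf) / 2
  ci <- apply(diffs, 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  sig <- ci[1, ] > 0 | ci[2, ] < 0
  sig[is.na(sig)] <- FALSE
  structure(list(time = times, actual = actual,
                 shuffle_mean = colMeans(shuffles),
                 ci_lower = ci[1, ], ci_upper = ci[2, ],
                 significant = sig, n_shuffles = n_shuffles, delay = delay),
            class = "mp_bootstrap")
}

#' @export
#' @method plot mp_corr_map
plot.mp_corr_map <- function(x, ...) {
  graphics::image(x = x$times, y = x$lags, z = t(x$corr),
                  xlab = "movement time (ms)", ylab = "lag (ms)",
                  main = "activity-kinematics correlation", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
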