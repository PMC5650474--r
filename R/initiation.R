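# Initiation-criterion (threshold) analysis and accumulation-rate-change
# analysis with surrogate pseudo-blink controls.

#' Bin trial-averaged normalised activity around saccade onset
#'
#' Averages a saccade-aligned normalised density within consecutive bins
#' (default: seven 10 ms bins from 50 ms before to 20 ms after onset).
#'
#' @param time ms grid relative to saccade onset.
#' @param density normalised rate on that grid (trial-averaged).
#' @param bin_edges left bin edges, ms; each bin is `[edge, edge + bin_width)`.
#' @param bin_width bin width, ms.
#' @return named numeric vector of per-bin means (NA where the bin lies
#'   outside the available support).
#' @export
binned_activity <- function(time, density, bin_edges = seq(-50, 10, by = 10),
                            bin_width = 10) {
  out <- vapply(bin_edges, function(e) {
    sel <- time >= e & time < e + bin_width
    if (!any(sel)) NA_real_ else mean(density[sel])
  }, numeric(1))
  stats::setNames(out, paste0(bin_edges, "ms"))
}

#' Population comparison of control vs blink activity per bin
#'
#' Per bin: two-sided Wilcoxon signed-rank test on paired per-neuron mean
#' activities, and a least-squares line of the blink-vs-control scatter.
#'
#' @param control_bins,blink_bins matrices (neurons x bins) of per-neuron
#'   per-bin mean normalised activity.
#' @param alpha significance level for the `control_higher` flag.
#' @return data frame with one row per bin: `bin`, `p`, `slope`, `intercept`,
#'   `median_diff` (blink - control) and `control_higher` (significant and
#'   control > blink).
#' @export
population_bin_comparison <- function(control_bins, blink_bins,
                                      alpha = 0.05) {
  stopifnot(identical(dim(control_bins), dim(blink_bins)))
  if (nrow(control_bins) < 6) {
    warning("fewer than 6 neurons with both conditions; tests skipped",
            call. = FALSE)
    return(NULL)
  }
  bins <- colnames(control_bins) %||% as.character(seq_len(ncol(control_bins)))
  rows <- lapply(seq_len(ncol(control_bins)), function(j) {
    x <- blink_bins[, j]; y <- control_bins[, j]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    p <- if (all(x == y)) 1 else
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    fit <- stats::lm(x ~ y)
    data.frame(bin = bins[j], p = p,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               median_diff = stats::median(x - y),
               control_higher = p < alpha & stats::median(x - y) < 0)
  })
  do.call(rbind, rows)
}

#' Classify each neuron's blink-vs-control activity over time
#'
#' Per neuron and time window, a two-sided Wilcoxon rank-sum test across
#' trials at `alpha` (default 0.001) labels the neuron `"lower"`, `"higher"`
#' or `"nodiff"` on blink relative to control trials; windows with fewer than
#' `min_trials` trials in either condition are `"nodiff"` with an
#' insufficient-data flag.
#'
#' @param control_trials,blink_trials lists, one element per neuron, each a
#'   matrix (trials x windows) of per-trial mean normalised activity.
#' @param alpha per-neuron significance level.
#' @param min_trials minimum trials per condition per window.
#' @return list with `classes` (neurons x windows character matrix),
#'   `proportions` (3 x windows matrix of class proportions) and
#'   `insufficient` (logical matrix).
#' @export
classify_neuron_timecourse <- function(control_trials, blink_trials,
                                       alpha = 0.001, min_trials = 3L) {
  stopifnot(length(control_trials) == length(blink_trials))
  n_win <- ncol(control_trials[[1]])
  n_neu <- length(control_trials)
  classes <- matrix("nodiff", n_neu, n_win)
  insufficient <- matrix(FALSE, n_neu, n_win)
  for (i in seq_len(n_neu)) {
    for (j in seq_len(n_win)) {
      x <- blink_trials[[i]][, j]; y <- control_trials[[i]][, j]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < min_trials || length(y) < min_trials) {
        insufficient[i, j] <- TRUE
        next
      }
      if (all(c(x, y) == c(x, y)[1])) next    # identical constant samples
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      if (!is.na(p) && p < alpha) {
        classes[i, j] <- if (stats::median(x) < stats::median(y))
          "lower" else "higher"
      }
    }
  }
  prop <- apply(classes, 2, function(cl) {
    c(higher = mean(cl == "higher"), lower = mean(cl == "lower"),
      nodiff = mean(cl == "nodiff"))
  })
  colnames(prop) <- colnames(control_trials[[1]])
  list(classes = classes, proportions = prop, insufficient = insufficient)
}

#' Surrogate control dataset with pseudo-blink times
#'
#' Each pseudo-trial is a control trial resampled with replacement, assigned a
#' pseudo-blink time drawn from the session's empirical blink-time
#' distribution.  When `min_onset_gap` is set, only pairs whose control
#' saccade onset is at least that many ms after the pseudo-blink are kept,
#' mirroring the onset-delay inclusion applied to real blink trials.
#'
#' @param control_ids vector of control trial identifiers.
#' @param control_sacc_on saccade onset per control trial, ms (same order).
#' @param blink_times the session's empirical blink times (relative to the
#'   same clock as `control_sacc_on`... typically time from GO cue).
#' @param n_pseudo number of pseudo-trials (default 1000).
#' @param seed RNG seed.
#' @param min_onset_gap optional minimum (saccade onset - pseudo-blink), ms.
#' @return data frame of class `mp_surrogate` with `trial_id`,
#'   `pseudo_blink` and `sacc_on`.
#' @export
make_surrogate_control <- function(control_ids, control_sacc_on, blink_times,
                                   n_pseudo = 1000L, seed = 1L,
                                   min_onset_gap = NULL) {
  if (!length(control_ids)) stop("no control trials", call. = FALSE)
  if (!length(blink_times))
    stop("no blink trials in session: cannot build pseudo-blink distribution",
         call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  got <- list(); n_got <- 0L; iter <- 0L
  while (n_got < n_pseudo && iter < 200L) {
    iter <- iter + 1L
    need <- n_pseudo - n_got
    i <- sample.int(length(control_ids), need, replace = TRUE)
    pb <- blink_times[sample.int(length(blink_times), need, replace = TRUE)]
    keep <- if (is.null(min_onset_gap)) rep(TRUE, need) else
      control_sacc_on[i] - pb >= min_onset_gap
    if (any(keep)) {
      got[[length(got) + 1L]] <- data.frame(trial_id = control_ids[i[keep]],
                                            pseudo_blink = pb[keep],
                                            sacc_on = control_sacc_on[i[keep]])
      n_got <- n_got + sum(keep)
    }
  }
  if (n_got < n_pseudo)
    stop("could not draw enough pseudo-trials satisfying the onset gap",
         call. = FALSE)
  out <- do.call(rbind, got)[seq_len(n_pseudo), ]
  rownames(out) <- NULL
  class(out) <- c("mp_surrogate", "data.frame")
  out
}

#' Piecewise-linear accumulation-rate fit around a blink
#'
#' Two independent least-squares lines are fitted to a (trial-averaged)
#' density on `[t_blink - half, t_blink)` and `[t_blink, t_blink + half]`;
#' the slopes are the pre- and post-blink rates of accumulation.
#'
#' @param time ms grid.
#' @param density normalised rate on that grid.
#' @param t_blink (pseudo-)blink time, ms.
#' @param half window half-length, ms (default 20).
#' @return list of class `mp_rate_fit`: `rate_pre`, `rate_post`
#'   (normalised-rate per ms) and `modulation_index`.
#' @export
piecewise_rate_fit <- function(time, density, t_blink, half = 20) {
  pre <- time >= t_blink - half & time < t_blink
  post <- time >= t_blink & time <= t_blink + half
  if (sum(pre & !is.na(density)) < 5 || sum(post & !is.na(density)) < 5)
    stop("fewer than 5 samples on one side of the blink", call. = FALSE)
  slope <- function(sel) {
    unname(stats::coef(stats::lm(density[sel] ~ time[sel]))[2])
  }
  rate_pre <- slope(pre); rate_post <- slope(post)
  structure(list(rate_pre = rate_pre, rate_post = rate_post,
                 modulation_index = rate_modulation_index(rate_pre, rate_post)),
            class = "mp_rate_fit")
}

#' Pre-to-post rate modulation index
#'
#' `(post - pre) / (post + pre)`; undefined (NA) when the denominator is 0.
#'
#' @param rate_pre,rate_post accumulation rates.
#' @return index in `[-1, 1]` for non-negative rates; NA when undefined.
#' @export
rate_modulation_index <- function(rate_pre, rate_post) {
  den <- rate_post + rate_pre
  ifelse(den == 0, NA_real_, (rate_post - rate_pre) / den)
}

#' Compare accumulation-rate statistics between blink and surrogate conditions
#'
#' Paired two-sided Wilcoxon signed-rank tests across neurons on pre-blink
#' rates, post-blink rates and modulation indices.
#'
#' @param blink,surrogate data frames with per-neuron `rate_pre`, `rate_post`,
#'   `modulation_index` (same neuron order).
#' @param min_neurons below this the tests are skipped with a warning.
#' @return data frame with one row per quantity: `p`, `median_blink`,
#'   `median_surrogate`, `blink_higher`.
#' @export
compare_rate_conditions <- function(blink, surrogate, min_neurons = 6L) {
  stopifnot(nrow(blink) == nrow(surrogate))
  if (nrow(blink) < min_neurons) {
    warning("fewer than ", min_neurons, " neurons; tests skipped",
            call. = FALSE)
    return(NULL)
  }
  one <- function(col) {
    x <- blink[[col]]; y <- surrogate[[col]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    p <- if (all(x == y)) 1 else
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    data.frame(quantity = col, p = p,
               median_blink = stats::median(x),
               median_surrogate = stats::median(y),
               blink_higher = stats::median(x - y) > 0)
  }
  do.call(rbind, lapply(c("rate_pre", "rate_post", "modulation_index"), one))
}
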