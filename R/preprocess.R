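# Calibrated velocity traces, spike density functions, velocity-criterion
# movement detection and rate normalisation.

#' Differentiate an eye position trace with zero-phase smoothing
#'
#' Position is low-pass filtered with a zero-phase (forward-backward)
#' Butterworth filter, then differentiated by central differences, so velocity
#' features are not shifted in time.
#'
#' @param position numeric vector, deg, uniformly sampled.
#' @param sampling_rate samples per second (default 1000).
#' @param cutoff low-pass cutoff, Hz.
#' @return velocity in deg/s, same length as `position`.
#' @examples
#' v <- compute_velocity(seq(0, 10, length.out = 101))  # 10 deg over 100 ms
#' round(stats::median(v))  # ~100 deg/s
#' @export
compute_velocity <- function(position, sampling_rate = 1000, cutoff = 50) {
  n <- length(position)
  if (n < 24)
    stop("position trace shorter than the smoothing filter (need >= 24 samples)",
         call. = FALSE)
  bf <- signal::butter(2, cutoff / (sampling_rate / 2), type = "low")
  # odd reflection at both ends suppresses filter edge transients on traces
  # that start or end away from zero
  pad <- min(n - 1L, 100L)
  xp <- c(2 * position[1] - position[(pad + 1):2],
          position,
          2 * position[n] - position[(n - 1):(n - pad)])
  smp <- signal::filtfilt(bf, xp)
  sm <- smp[(pad + 1):(pad + n)]
  v <- numeric(n)
  v[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / 2 * sampling_rate
  v[1] <- (sm[2] - sm[1]) * sampling_rate
  v[n] <- (sm[n] - sm[n - 1]) * sampling_rate
  v
}

#' Spike density function
#'
#' Convolves a spike train with a Gaussian kernel of standard deviation
#' `kernel_width` ms, evaluated on the 1 ms grid spanning `window`
#' (inclusive).  The kernel has unit area, so the time integral of the density
#' (in seconds) equals the number of spikes whose kernels fall inside the
#' window.
#'
#' @param spike_times numeric vector of spike times, ms (may be empty).
#' @param kernel_width Gaussian s.d., ms.
#' @param window length-2 numeric, ms: evaluation window.
#' @return list of class `mp_density` with `time` (ms grid), `rate`
#'   (spikes/s) and `kernel_width`.
#' @examples
#' d <- spike_density(c(50, 60), kernel_width = 3, window = c(0, 100))
#' sum(d$rate) / 1000  # integral = 2 spikes
#' @export
spike_density <- function(spike_times, kernel_width, window) {
  if (kernel_width <= 0) stop("kernel_width must be > 0", call. = FALSE)
  k <- gaussian_kernel(kernel_width)
  pad <- (length(k) - 1L) / 2
  t0 <- window[1] - pad
  tgrid <- t0:(window[2] + pad)
  counts <- numeric(length(tgrid))
  if (length(spike_times)) {
    idx <- floor(spike_times - t0) + 1L
    idx <- idx[idx >= 1L & idx <= length(tgrid)]
    if (length(idx)) {
      tab <- tabulate(idx, nbins = length(tgrid))
      counts <- tab
    }
  }
  rate <- conv_same(counts, k) * 1000   # spikes per ms -> spikes/s
  keep <- tgrid >= window[1] & tgrid <= window[2]
  structure(list(time = tgrid[keep], rate = rate[keep],
                 kernel_width = kernel_width),
            class = "mp_density")
}

#' Detect a movement with standard velocity criteria
#'
#' Onset and offset are found independently on the horizontal and vertical
#' velocity components (first sample with |v| >= `onset_threshold`; first
#' sample after the component peak with |v| < `offset_threshold`).  The
#' overall onset is the minimum of the component onsets and the overall offset
#' the maximum of the component offsets.
#'
#' @param h_vel,v_vel component velocities, deg/s.
#' @param time time stamps, ms (defaults to 0-based sample index).
#' @param onset_threshold,offset_threshold velocity criteria, deg/s.
#' @param search_from ignore samples before this time, ms.
#' @return list of class `mp_movement`: `found`, `onset`, `offset`,
#'   `component_of_onset` ("horizontal"/"vertical"), `peak_velocity` (vectorial).
#'   When neither component crosses the onset criterion, `found` is `FALSE`
#'   (a "no movement detected" result, not an error).
#' @export
detect_movement <- function(h_vel, v_vel, time = seq_along(h_vel) - 1,
                            onset_threshold = 50, offset_threshold = 30,
                            search_from = -Inf) {
  stopifnot(length(h_vel) == length(v_vel))
  none <- list(found = FALSE, onset = NA_real_, offset = NA_real_,
               component_of_onset = NA_character_, peak_velocity = NA_real_)
  class(none) <- "mp_movement"
  comp_detect <- function(v) {
    ok <- which(abs(v) >= onset_threshold & time >= search_from)
    if (!length(ok)) return(NULL)
    on <- ok[1]
    pk <- on - 1L + which.max(abs(v[on:length(v)]))
    below <- which(abs(v) < offset_threshold & seq_along(v) > pk)
    off <- if (length(below)) below[1] else length(v)
    list(on = time[on], off = time[off])
  }
  h <- comp_detect(h_vel)
  v <- comp_detect(v_vel)
  if (is.null(h) && is.null(v)) return(none)
  ons <- c(horizontal = if (!is.null(h)) h$on else Inf,
           vertical   = if (!is.null(v)) v$on else Inf)
  offs <- c(if (!is.null(h)) h$off else -Inf,
            if (!is.null(v)) v$off else -Inf)
  onset <- min(ons)
  offset <- max(offs)
  seg <- time >= onset & time <= offset
  out <- list(found = TRUE, onset = onset, offset = offset,
              component_of_onset = names(ons)[which.min(ons)],
              peak_velocity = max(sqrt(h_vel[seg]^2 + v_vel[seg]^2)))
  class(out) <- "mp_movement"
  out
}

#' Normalise spike densities by the control-derived peak
#'
#' Every trial's density is divided by the peak of the *control* trial-averaged
#' density (the neuron's peak trial-averaged firing rate during normal
#' saccades), so the normalised control average peaks at exactly 1 and blink
#' trials share the same divisor.
#'
#' @param densities list of equal-grid density vectors (or `mp_density`
#'   objects) for all trials to normalise.
#' @param control_average numeric vector: the control trial-averaged density on
#'   its alignment grid.
#' @return list with `normalised` (list of vectors) and `divisor`.
#' @export
normalize_rates <- function(densities, control_average) {
  divisor <- max(control_average, na.rm = TRUE)
  if (!is.finite(divisor) || divisor <= 0)
    stop("normalisation error: control trial-averaged density has zero peak",
         call. = FALSE)
  norm1 <- function(d) {
    if (inherits(d, "mp_density")) d$rate / divisor else d / divisor
  }
  list(normalised = lapply(densities, norm1), divisor = divisor)
}
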