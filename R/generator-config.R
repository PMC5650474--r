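#' Configuration for the synthetic delayed-saccade session generator
#'
#' Builds and validates the full parameter set of the generative model used to
#' emulate a single-neuron recording session of the delayed saccade task with
#' reflex-blink perturbations.  The model has four coupled ingredients:
#'
#' * a *task scaffold*: fixation, peripheral target onset, a variable delay
#'   period, a GO cue, and (on perturbation trials) an air-puff blink delivered
#'   shortly after the GO cue;
#' * a *premotor rate model*: baseline + linear preparatory ramp after the GO
#'   cue (per-trial slope and gain jitter, plus smooth within-trial noise) that
#'   triggers a raised-cosine motor burst when it reaches an initiation level;
#' * an *ocular plant*: eye velocity reads out the delayed firing rate through
#'   an efference delay, gated by omnipause-like inhibition.  On blink trials
#'   the gate opens at blink onset, so preparatory rate "leaks" into a slow
#'   goal-directed drift superimposed on a loop-like blink-related eye movement
#'   (BREM); on control trials the gate opens only with the burst;
#' * a *main-sequence constraint*: saccade peak velocity saturates with
#'   amplitude as `Vp(A) = burst_gain * (1 - exp(-A / main_sequence_a0))`.
#'
#' All times are in milliseconds on a regular grid at `sampling_rate`.
#'
#' @param sampling_rate samples per second of eye traces (default 1000).
#' @param n_control_trials,n_blink_trials,n_brem_fixation_trials trial counts
#'   per session.  Fixation-BREM trials (blink during fixation, no target) are
#'   used to build the session's BREM template.
#' @param delay_range GO-cue delay after target onset, ms (uniform draw).
#' @param blink_window blink time after the GO cue, ms (uniform draw).
#' @param efference_delay delay between a change in firing rate and the
#'   resulting change in eye velocity, ms.
#' @param target_eccentricity,target_direction target location in polar
#'   coordinates (deg, deg; direction 0 = rightward, counter-clockwise).
#' @param rt_mean,rt_sd mean and s.d. of the control saccade reaction time
#'   from the GO cue, ms.  Together with `threshold_level` and
#'   `afferent_delay` these set the preparatory ramp slope distribution.
#' @param afferent_delay time from GO cue to onset of the preparatory ramp, ms.
#' @param threshold_level normalised activity level at which the movement is
#'   triggered on control trials (fraction of burst peak).
#' @param blink_threshold_fraction fraction of the control initiation level at
#'   which blink-perturbed trials launch the saccade (in (0, 1]).
#' @param post_blink_slope_multiplier factor (>= 1) applied to the preparatory
#'   ramp slope after blink-induced disinhibition.
#' @param baseline_rate,peak_rate baseline and burst-peak firing rate, spikes/s.
#' @param burst_gain main-sequence saturation velocity (deg/s); the velocity
#'   scale converting normalised burst rate into eye speed.
#' @param main_sequence_a0 main-sequence amplitude constant (deg).
#' @param leak_gain velocity produced per unit normalised preparatory rate when
#'   the gate is open before the saccade proper ((deg/s) per normalised unit).
#' @param burst_gain_sd per-trial multiplicative jitter (s.d.) of burst size.
#' @param rate_scale_sd per-trial multiplicative jitter (s.d.) of overall
#'   excitability (baseline + ramp).
#' @param rate_noise_sd s.d. of the smooth within-trial modulation of the
#'   motor burst, normalised units.  Most across-trial rate variability is
#'   temporally structured within the trial rather than a uniform gain, which
#'   is what makes the activity-kinematics correlation ridge lag-specific.
#' @param prep_noise_sd s.d. of smooth additive noise on the preparatory
#'   rate, normalised units; this source is suppressed while the burst is
#'   active (the burst generator drive overrides low-frequency preparatory
#'   fluctuations).
#' @param noise_smooth_ms temporal smoothing (s.d., ms) of within-trial noise.
#' @param saccade_rise_fraction fraction of the saccade duration occupied by
#'   the velocity rise (saccadic profiles are skewed: fast acceleration,
#'   slower deceleration).
#' @param perp_noise_sd per-trial directional scatter of the saccade
#'   (fraction of peak velocity orthogonal to the goal).
#' @param position_noise_sd measurement noise on recorded eye position, deg.
#' @param brem_peak_h,brem_peak_v peak horizontal/vertical BREM velocity,
#'   deg/s (negative = nasal/downward).
#' @param brem_gain_sd per-trial multiplicative jitter (s.d.) of BREM size.
#' @param brem_noise_sd s.d. of smooth additive BREM velocity noise, deg/s;
#'   `brem_noise_smooth_ms` its smoothing s.d.
#' @param brem_noise_smooth_ms temporal smoothing of BREM noise, ms.
#' @param brem_duration BREM support, ms.
#' @param spike_regularity gamma-renewal shape of the spike generator
#'   (1 = Poisson; larger = more regular, lower count Fano factor).
#' @param keep_latent if `TRUE`, each trial also stores its latent
#'   normalised rate and noiseless velocities (for parameter-recovery
#'   checks); off by default to keep sessions light.
#' @param seed integer seed; the whole session is a deterministic function of
#'   the configuration including the seed.
#'
#' @return An object of class `mp_config` (a validated named list).
#' @examples
#' cfg <- generator_config(n_control_trials = 5, n_blink_trials = 2, seed = 1)
#' cfg$efference_delay
#' @export
generator_config <- function(sampling_rate = 1000,
                             n_control_trials = 150,
                             n_blink_trials = 45,
                             n_brem_fixation_trials = 20,
                             delay_range = c(500, 1200),
                             blink_window = c(100, 250),
                             efference_delay = 12,
                             target_eccentricity = 12,
                             target_direction = 0,
                             rt_mean = 278,
                             rt_sd = 45,
                             afferent_delay = 40,
                             threshold_level = 0.35,
                             blink_threshold_fraction = 0.8,
                             post_blink_slope_multiplier = 3,
                             baseline_rate = 15,
                             peak_rate = 700,
                             burst_gain = 550,
                             main_sequence_a0 = 8,
                             leak_gain = 80,
                             burst_gain_sd = 0.05,
                             rate_scale_sd = 0.1,
                             rate_noise_sd = 0.15,
                             prep_noise_sd = 0.12,
                             noise_smooth_ms = 3,
                             saccade_rise_fraction = 0.25,
                             perp_noise_sd = 0.05,
                             position_noise_sd = 0.005,
                             brem_peak_h = -110,
                             brem_peak_v = -70,
                             brem_gain_sd = 0.15,
                             brem_noise_sd = 10,
                             brem_noise_smooth_ms = 10,
                             brem_duration = 250,
                             spike_regularity = 2,
                             keep_latent = FALSE,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "mp_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid generator configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field, positive = FALSE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      fail(field, "must be a single number")
    if (positive && x <= 0) fail(field, "must be > 0")
    x
  }
  num1("sampling_rate", positive = TRUE)
  num1("efference_delay", positive = TRUE)
  for (f in c("n_control_trials", "n_blink_trials", "n_brem_fixation_trials")) {
    x <- num1(f)
    if (x < 0 || x != round(x)) fail(f, "must be a non-negative integer")
  }
  for (f in c("delay_range", "blink_window")) {
    x <- cfg[[f]]
    if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2])
      fail(f, "must be an increasing pair of times (ms)")
  }
  f <- num1("blink_threshold_fraction", positive = TRUE)
  if (f > 1) fail("blink_threshold_fraction", "must be in (0, 1]")
  if (num1("post_blink_slope_multiplier") < 1)
    fail("post_blink_slope_multiplier", "must be >= 1")
  num1("threshold_level", positive = TRUE)
  if (cfg$threshold_level >= 1)
    fail("threshold_level", "must be < 1 (fraction of burst peak)")
  num1("peak_rate", positive = TRUE)
  num1("burst_gain", positive = TRUE)
  num1("main_sequence_a0", positive = TRUE)
  num1("target_eccentricity", positive = TRUE)
  num1("rt_mean", positive = TRUE)
  num1("brem_duration", positive = TRUE)
  if (num1("spike_regularity") < 1)
    fail("spike_regularity", "must be >= 1")
  if (cfg$blink_window[1] < cfg$efference_delay)
    fail("blink_window", "must start after the efference delay")
  seed <- cfg$seed
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    fail("seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.mp_config <- function(x, ...) {
  cat("Synthetic session configuration (mp_config)\n")
  cat(sprintf("  trials: %d control, %d blink, %d fixation-BREM\n",
              x$n_control_trials, x$n_blink_trials, x$n_brem_fixation_trials))
  cat(sprintf("  efference delay: %g ms; threshold level: %g (blink fraction %g)\n",
              x$efference_delay, x$threshold_level, x$blink_threshold_fraction))
  cat(sprintf("  target: %g deg at %g deg; seed: %s\n",
              x$target_eccentricity, x$target_direction, format(x$seed)))
  invisible(x)
}
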