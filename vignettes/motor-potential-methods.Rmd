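---
title: "Latent motor potential in saccadic premotor activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent motor potential in saccadic premotor activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorpotential)
```

## The scientific question

Premotor neurons in the intermediate layers of the superior colliculus (SC)
build up low-frequency activity while a saccade is being prepared, then emit
a high-frequency burst when it is executed.  Classical accumulator models
treat the build-up as purely preparatory: only once activity reaches a fixed
initiation criterion does it become a movement command.  An alternative view
is that preparatory activity already *is* a (gated) movement command — it has
"motor potential" — and is normally prevented from reaching the eye muscles
by tonic brainstem inhibition (the omnipause neurons, OPNs).

The trigeminal blink reflex suppresses the OPNs.  Delivering an air puff
shortly after the GO cue of a delayed saccade task therefore removes the
inhibition while the preparatory activity is still sub-threshold.  If that
activity has motor potential, three things should be observable:

1. eye velocity *before* the saccade proper should correlate, across trials,
   with concurrent (delay-shifted) firing rate, at the same efferent delay
   as the saccadic burst does;
2. saccades should launch at activity levels *below* the control initiation
   level, contradicting a fixed threshold;
3. the accumulation rate should accelerate after disinhibition.

This package implements the full analysis chain for these three questions,
plus a synthetic session generator in which all three effects are injected
with known parameters, so that every stage can be validated by parameter
recovery.

## The generative model

A session is one neuron recorded across interleaved trial types: fixation
trials with a blink (used only to estimate the blink-related eye movement,
BREM), control delayed-saccade trials, and blink-perturbed trials.

**Premotor rate.**  In normalised units (1 = burst peak), the rate on a
trial is

$$ r_i(t) = s_i\,[b_0 + \rho_i(t)] + \varepsilon_i(t)
   + (1-\theta)\,B(t - t^{trig}_i)\,[g_i + \nu_i(t)] , $$

where $s_i$ is a per-trial excitability scale (s.d. `rate_scale_sd`),
$b_0$ the baseline, $\rho_i$ a linear ramp that starts `afferent_delay`
ms after the GO cue with a per-trial slope set by the reaction-time
parameters, $\theta$ = `threshold_level` the initiation level,
$B(\cdot)$ an asymmetric raised-cosine burst profile, $g_i$ a per-trial
burst gain (s.d. `burst_gain_sd`), and $\varepsilon_i$, $\nu_i$ smooth
(Gaussian-filtered, s.d. `noise_smooth_ms`) within-trial noises.  Most
across-trial variability is temporally structured ($\nu$, s.d.
`rate_noise_sd`) rather than a uniform gain; this is what makes the
activity–kinematics correlation ridge specific to one lag rather than
spread over all lags.  The preparatory noise $\varepsilon$ is suppressed
while the burst is active — the burst-generator drive overrides
low-frequency preparatory fluctuations.

Spikes are drawn from a time-rescaled gamma renewal process
(`spike_regularity`, default shape 2).  Premotor spiking at these rates is
more regular than Poisson; with Poisson counts, 10 ms windows at realistic
rates are so noisy that no per-trial statistic could reach the
classification power that the analyses require of real data.

**Initiation.**  On control trials the movement triggers when the ramp
reaches $\theta$; the trigger-to-movement lead equals the efference delay.
On blink trials the ramp slope is multiplied by
`post_blink_slope_multiplier` from blink onset and the movement triggers at
`blink_threshold_fraction` $\times\,\theta$.  Trials whose natural
initiation would precede the blink are re-drawn (in the experiment such
movements are not blink-triggered and are excluded).

**Kinematics.**  Eye velocity reads out the delayed rate:
$v(t) \propto r(t - \delta)$ with $\delta$ = `efference_delay` (12 ms).
During the saccade the goal-directed component is the burst profile scaled
by the main-sequence peak velocity
$V_p(A) = V_{max}(1 - e^{-A/A_0})$.  On blink trials the gate is open from
blink onset, so the delayed preparatory rate also "leaks" into a slow
goal-directed drift (`leak_gain`, deg/s per normalised unit), superimposed
on a loop-shaped BREM (difference of two gamma pulses per component, exactly
closing the loop; per-trial gain jitter plus smooth noise).  The
goal-directed amplitude is feedback-compensated for the expected leak
displacement, keeping blink-triggered movements as accurate as control
saccades.  Positions integrate velocity and add measurement noise.

The saccadic profile rises over the first quarter of the movement
(`saccade_rise_fraction` = 0.25) and decays over the rest.  This skewness is
a property of real saccade velocity profiles, and it matters here: both
movement detectors (below) fire during the rise, and a slow symmetric
profile would separate their latencies by several milliseconds, biasing any
comparison of activity aligned by the two detectors.

## The analysis chain

**Preprocessing.**  Positions are low-pass filtered with a zero-phase
(forward–backward) Butterworth filter (~50 Hz cutoff; odd-reflection padding
suppresses edge transients) and differentiated centrally.  Movements are
detected with the standard 50 deg/s onset / 30 deg/s offset criteria applied
per component, taking the earlier (later) component crossing as overall
onset (offset).  Spike densities use a Gaussian kernel of s.d. 3 ms for the
correlation and threshold analyses and 10 ms for the accumulation-rate
analysis; "width" means the standard deviation.  Rates are normalised by
the peak of the control trial-averaged density.

**Embedded-saccade detection.**  Fixation-BREM trials, aligned to their
detected movement onset, give the session template (pointwise mean and
s.d. of each velocity component).  A blink-triggered movement's saccade
onset is the first sample whose velocity leaves the mean ± 2.5 s.d. band of
the template for at least 15 consecutive samples, taken over the earlier of
the two components.  A candidate excursion must additionally be saccade-like
(residual speed reaching 100 deg/s within 40 ms); this replaces the manual
verification step that a human analyst would perform, and without it smooth
BREM variability occasionally sustains 15-sample excursions of its own.
Onset delays below 20 ms are classified "early" (initiation was already
underway), at or above 20 ms "triggered" (released by the disinhibition).

**Inclusion.**  Neurons need at least 7 detected blink trials (threshold
analysis; all blink trials kept) and at least 7 blink trials with onset
delay ≥ 20 ms (motor-potential and accumulation analyses; only those trials
kept).  Control analyses use the same neuron subset.

**Motor potential.**  For each neuron, the across-trial Pearson correlation
$c(t+\Delta, t)$ between activity at $t+\Delta$ and the kinematic variable
at $t$ is computed for lags $\Delta \in [-50, 50]$ ms around saccade onset.
The kinematic variable is the signed projection of the (for blink trials,
BREM-template-subtracted residual) velocity on the goal direction; the raw
unprojected variant is available as a flag.  Maps are averaged across
neurons cell-by-cell (raw coefficients; Fisher-z averaging is a flag, off by
default to match the population-average convention).  For each movement
time, the lag of the population peak gives the optimal efferent delay;
argmax ties break toward the most causal lag; a 5 ms moving average smooths
the trace (window shrinking at the edges).  Significance uses a
trial-shuffled bootstrap: 100 shuffles of the trial pairing within each
neuron, the 95% interval of the (actual − shuffled) difference distribution
per time point, significant where it excludes zero — exactly the quoted
rule, with no multiple-comparison correction.

**Delay-averaging windows.**  The mean efferent delay is taken over
[15, 45] ms after detected onset (and [−30, −15] ms before it for the
pre-onset estimate on blink trials).  The 15 ms guard on both sides was
chosen from a bias analysis of the delay trace on synthetic data: within
~15 ms of the *detected* onset, the argmax is dominated by the covariance
that onset-detection jitter induces between the aligned mean profiles
(both activity and velocity have steep gradients there), not by the
efferent coupling; outside the guard the trace is flat at the injected
delay.  The upper edge, 45 ms, is about the shortest movement duration over
the 9–25 deg amplitude range.  These are package defaults, configurable in
`motor_potential_analysis()`.

**Threshold analysis.**  Saccade-aligned normalised activity is averaged in
seven 10 ms bins from 50 ms before to 20 ms after onset.  Per bin: a paired
two-sided Wilcoxon signed-rank test across neurons and a least-squares line
of the blink-vs-control scatter.  Per neuron and bin, a two-sided rank-sum
test across trials at α = 0.001 classifies the neuron as lower / higher /
no-difference, and the population proportions of the three classes are
reported.  Test levels follow the printed conventions (0.001 per neuron,
0.05 elsewhere, no correction).

**Accumulation rate.**  For blink trials with onset delay ≥ 20 ms, the
trial-averaged 10 ms-kernel normalised density aligned on blink onset is
fitted with two independent least-squares lines over [−20, 0) and [0, 20]
ms; the slopes are the pre/post-blink accumulation rates, and the
modulation index is (post − pre)/(post + pre).  The surrogate control uses
1000 pseudo-trials per neuron: control trials resampled with replacement,
each assigned a pseudo-blink time drawn from the session's empirical
blink-time distribution, pooled into one average before fitting (fitting
pooled rather than per-pseudo-trial is a package decision; the pooled
average is the natural analogue of the blink-trial average).  Pseudo-trials
are kept only if the trial's saccade onset is at least 20 ms after the
pseudo-blink, mirroring the inclusion applied to real blink trials — without
this the blink side is selection-biased and the no-effect calibration below
would be invalid.  Conditions are compared with paired signed-rank tests on
pre-rates, post-rates and indices.

## What the generator emulates, and what it does not

The generator realises the study conditions: 1 kHz eye traces, a 500–1200 ms
delay period, blinks 100–250 ms after the GO cue, a 12 ms efference delay,
main-sequence saccades with response fields spanning all directions and
9–25 deg eccentricities, preparatory ramping to a threshold, sub-threshold
launch (fraction 0.8) with tripled post-blink accumulation on perturbation
trials, and rate-driven kinematics gated by OPN-like inhibition.  Passing
recovery tests shows the *pipeline* estimates these quantities correctly
from data of this structure.  It does not show that real SC data satisfy
the model: real preparatory activity is not linear, real BREMs vary more
richly than a gain-jittered template, bursts are not time-locked to a fixed
lead, and recording artefacts are absent.  Conclusions about real data rest
on the original experiments; the synthetic results validate the estimators.

Default problem sizes used by the recovery checks — 22 sessions of 150
control / 45 blink / 20 fixation trials, 100 bootstrap shuffles, 1000
pseudo-trials, and 20-seed calibration batches of 12 smaller sessions — were
chosen to match the published population scale while keeping a full run in
the minutes range on a single core.

## Numerical choices and degenerate inputs

* Template s.d. values are floored at 10⁻³ deg/s (with a warning) so
  identical BREM repeats cannot produce zero-width bounds.
* Correlation cells with zero variance in either vector are missing, are
  excluded from population averages, and are never "significant".
* Beyond the BREM template support, the last defined bound is used for
  detection and nothing is subtracted from residuals.
* The moving average shrinks its window at trace edges rather than padding.
* Slicing the map at a non-integer delay uses the nearest grid lag.
* Spike-density kernels are discretised with exactly unit mass, so the
  density integral equals the spike count whenever the window covers the
  kernels.
* All stochastic stages (generation, shuffles, surrogate draws) take
  explicit seeds; a session is a deterministic function of its
  configuration.

## Known limitations

* **Two-detector phase offset.**  Control saccade onsets come from the
  50 deg/s criterion, embedded-saccade onsets from the ±2.5 s.d. deviation
  rule.  The two rules fire at slightly different phases of the velocity
  rise (~1–2 ms apart even with a realistic fast-rising profile).  Bins that
  contain the steep burst rise therefore compare activity at slightly
  different true phases across conditions, producing a small but highly
  consistent blink-side deficit that a paired signed-rank test across
  neurons can detect even when the generator injects no threshold effect at
  all.  The injected effect at fraction 0.8 is an order of magnitude larger
  than this bias, but a strict "nothing significant anywhere under the
  null" expectation is not attainable with this (faithful) two-rule
  detection design; the package reports the calibration honestly rather
  than masking it.
* **Endpoint accuracy on blink trials** is measured at the detected
  movement offset, which can fall before the BREM loop has fully closed, so
  generated blink-trial accuracy runs slightly worse than control accuracy
  even though the saccade itself is compensated.
* The per-time bootstrap significance rule is pointwise, as quoted, with no
  multiple-comparison correction; interpretations should treat isolated
  significant samples accordingly.

## A small worked run

```{r example, eval = FALSE}
cfg <- generator_config(n_control_trials = 40, n_blink_trials = 20,
                        n_brem_fixation_trials = 10)
report <- run_full_analysis(cfg, n_neurons = 8, seed = 1,
                            n_shuffles = 50, n_pseudo = 300)
print(report)
```

The report collects the behavioural summary (reaction times, accuracy), the
control and blink motor-potential results (maps, delay traces, bootstrap
time courses), the threshold-bin table and classification proportions, and
the accumulation-rate fits; `scripts/acceptance.R` runs the same pipeline at
the full study scale.
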