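# motorpotential

Tools for asking whether *preparatory* activity of saccadic premotor
neurons already carries a movement command — a latent "motor potential" —
that is normally withheld from the eye muscles by brainstem inhibition.

The package is aimed at sensorimotor electrophysiologists analysing
delayed-saccade sessions with reflex-blink perturbations: per-trial eye
position at 1 kHz, spike times for one neuron per session, and event times
(target onset, GO cue, blink onset).  It implements, end to end:

* **Embedded-saccade detection.**  Blink-triggered gaze shifts mix a
  blink-related eye movement (BREM) with the goal-directed saccade.  A
  session-specific BREM velocity template (pointwise mean and s.d. from
  fixation-blink trials) marks saccade onset as the first sample whose
  velocity leaves the mean ± 2.5 s.d. band for ≥ 15 consecutive samples,
  per component, earliest component wins.
* **Motor-potential estimation.**  For each neuron the across-trial Pearson
  correlation `c(t+Δ, t) = corr(a(t+Δ), v(t))` between spike density `a`
  and goal-projected (residual) velocity `v` over lags Δ ∈ [−50, 50] ms;
  population-averaged maps; the optimal efferent delay as the per-time
  argmax lag (negative = activity leads, causal); trial-shuffled bootstrap
  significance (100 shuffles, 95% interval of the actual − shuffled
  differences).
* **Initiation-threshold analysis.**  Saccade-aligned normalised activity
  compared between blink and control trials in 10 ms bins from −50 to
  +20 ms (population signed-rank tests, per-neuron rank-sum classification
  at α = 0.001).
* **Accumulation-rate analysis.**  Piecewise-linear fits of the 10 ms-kernel
  density 20 ms before/after the blink; rate modulation index
  `(post − pre)/(post + pre)`; surrogate controls built from 1000
  pseudo-trials with blink times resampled from the session's empirical
  blink-time distribution.
* **A synthetic session generator** reproducing the task and the coupling
  structure (preparatory ramp to threshold, rate-driven kinematics through
  a configurable efference delay, OPN-like gating opened early by the
  blink, loop-closing BREMs, main-sequence saccades) with full ground
  truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(motorpotential)

cfg <- generator_config(n_control_trials = 40, n_blink_trials = 20,
                        n_brem_fixation_trials = 10)
report <- run_full_analysis(cfg, n_neurons = 8, seed = 5,
                            n_shuffles = 30, n_pseudo = 200)
print(report)
#> Full pipeline report (8 neurons, seed 5)
#> RT: control 284 ms, blink 176 ms (one-tailed p = 4.11e-81)
#> Accuracy: control 0.093, blink 0.142 (p = 6.35e-12)
#> Control post-onset efferent delay: -12.08 ms
#> Blink post-onset delay: -11.50 ms; pre-onset: -11.11 ms (p = 0.48)
```

Reading the output: blink perturbations trigger movements ~110 ms earlier
than control saccades (the disinhibition releases them before the natural
initiation time).  The efferent delay — the lag at which firing rate best
predicts eye velocity — is recovered near the injected −12 ms both during
control saccades and, crucially, *before* saccade onset on blink trials
(−11.11 ms, statistically indistinguishable from the post-onset estimate,
p = 0.48): the preparatory activity drives the eye as soon as the gate is
open.  Small populations give noisier delay estimates; the study-scale run
below uses 22 sessions.

Session bundles can be written and re-read as plain CSV/JSON
(`write_session_bundle()` / `read_session_bundle()`), so the analysis
half of the package runs equally on recorded data laid out the same way.

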