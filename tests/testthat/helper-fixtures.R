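# Shared fixtures.  Expensive populations are generated once per test run and
# cached; everything is built in code from fixed seeds.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

small_config <- function(...) {
  generator_config(n_control_trials = 10, n_blink_trials = 8,
                   n_brem_fixation_trials = 8,
                   delay_range = c(500, 700), seed = 42, ...)
}

# The study-condition population used by the recovery checks: sessions at the
# generator defaults (150 control / 45 blink / 20 fixation-BREM trials each).
main_population <- function() {
  cached("main_pop", function() {
    generate_population(22, generator_config(), seed = 20251)
  })
}

main_sdata <- function() {
  cached("main_sdata", function() {
    pop <- main_population()
    lapply(seq_along(pop), function(i) {
      preprocess_session(pop[[i]], neuron = sprintf("n%02d", i))
    })
  })
}

main_sdata10 <- function() {
  cached("main_sdata10", function() {
    pop <- main_population()
    lapply(seq_along(pop), function(i) {
      preprocess_session(pop[[i]], kernel_width = 10,
                         neuron = sprintf("n%02d", i))
    })
  })
}

main_inclusion <- function() {
  cached("main_inclusion", function() {
    det <- do.call(rbind, lapply(main_sdata(), `[[`, "detections"))
    list(detections = det, inclusion = apply_inclusion_criteria(det))
  })
}

split_sets <- function(df) split(df$trial_id, df$neuron)

# Complete no-effect reference populations (initiation level, accumulation
# dynamics and gating all unchanged by the blink), analysed once and shared
# by the threshold-null and rate-null calibrations.
null_runs <- function(n_seeds = 20) {
  cached("null_runs", function() {
    lapply(seq_len(n_seeds), function(s) {
      cfg <- generator_config(n_control_trials = 60, n_blink_trials = 30,
                              n_brem_fixation_trials = 15,
                              blink_threshold_fraction = 1,
                              post_blink_slope_multiplier = 1,
                              leak_gain = 0)
      pop <- generate_population(12, cfg, seed = 30000 + s)
      sdat <- lapply(seq_along(pop), function(i)
        preprocess_session(pop[[i]], neuron = sprintf("n%02d", i)))
      det <- do.call(rbind, lapply(sdat, `[[`, "detections"))
      inc <- apply_inclusion_criteria(det)
      th <- threshold_analysis(sdat, trial_sets = split_sets(inc$threshold_set))
      sdat10 <- lapply(seq_along(pop), function(i)
        preprocess_session(pop[[i]], kernel_width = 10,
                           neuron = sprintf("n%02d", i)))
      keep <- vapply(sdat10, function(x) x$neuron %in% inc$motor_neurons,
                     logical(1))
      acc <- accumulation_analysis(sdat10[keep],
                                   trial_sets = split_sets(inc$motor_set),
                                   n_pseudo = 500, seed = s)
      idx <- acc$tests[acc$tests$quantity == "modulation_index", ]
      list(bins = th$bins,
           index_fp = idx$p < 0.05 && idx$blink_higher)
    })
  })
}

# Brute-force Pearson oracle: plain double loop over (time, lag) cells.
brute_force_map <- function(activity, kinematics, activity_time, kin_time,
                            lags, times) {
  out <- matrix(NA_real_, length(lags), length(times))
  for (j in seq_along(times)) {
    for (k in seq_along(lags)) {
      ia <- which(activity_time == times[j] + lags[k])
      iv <- which(kin_time == times[j])
      if (!length(ia) || !length(iv)) next
      a <- activity[, ia]; v <- kinematics[, iv]
      if (stats::sd(a) == 0 || stats::sd(v) == 0) next
      out[k, j] <- stats::cor(a, v)
    }
  }
  out
}

# Flat BREM template (given pointwise mean and s.d.) for constructed
# detection cases; built from two traces whose sample s.d. equals `sd`.
flat_template <- function(n = 150, mean = 0, sd = 1) {
  lo <- rep(mean - sd / sqrt(2), n)
  hi <- rep(mean + sd / sqrt(2), n)
  build_brem_template(rbind(lo, hi), rbind(lo, hi), time = 0:(n - 1))
}
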