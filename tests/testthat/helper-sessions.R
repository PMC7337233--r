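# Scaled-down session configurations used throughout the suite. Sizes are
# reduced (fewer trials/features, shorter blocks) so the suite stays fast;
# the default synth_config() keeps the full study-sized conditions.

small_config <- function(seed = 1, ...) {
  args <- list(
    n_features = 16, n_repeated_trials = 12, n_control_trials = 11,
    per_target_duration = 0.6, rest1_duration = 4, rest2_duration = 4,
    noise_ar_coeff = 0.3, drift_amplitude = 0.5,
    event_rate_rest1 = 0, event_rate_rest2 = 1.5, control_event_rate = 0.3,
    event_compression = 0.1, event_gain = 1, nrem1_fraction = 0.3,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

tiny_config <- function(seed = 1, ...) {
  small_config(seed, n_features = 12, n_repeated_trials = 8,
               rest1_duration = 2.5, rest2_duration = 2.5, ...)
}

# tau used with scaled blocks so burn-in does not swallow the block
small_tau <- 45
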