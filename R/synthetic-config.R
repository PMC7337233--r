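#' Configuration for the synthetic session generator
#'
#' Defaults mirror the structure of the sequence-game study: 66 repeated
#' trials and 22 control trials (11 orderings x 2) of a 4-target game with
#' ~1.1 s per target trajectory, flanked by 23.5 and 26.2 minute rest blocks,
#' 40 neural features in 20 ms bins. Replay events are embedded additively in
#' the rest blocks at controlled compression and rate, with more
#' repeated-template events in Rest2 than Rest1; control-template events occur
#' at the same rate in both blocks so the control class is a flat null.
#'
#' @param n_features Number of neural features (channels).
#' @param bin_width Bin width in seconds.
#' @param n_repeated_trials Repeated-sequence trial count.
#' @param n_control_trials Control trial count; must be divisible by 11
#'   (each of the 11 admissible control orderings appears equally often).
#' @param per_target_duration Nominal single-target trajectory duration (s).
#' @param rest1_duration,rest2_duration Rest block durations in minutes.
#' @param noise_ar_coeff AR(1) coefficient of the per-feature noise, in
#'   `[0, 1)`; the process is scaled to unit stationary variance.
#' @param drift_amplitude Amplitude (z-units) of a slow sinusoidal mean drift
#'   added per feature (random phase, ~10 min period), emulating neural
#'   signal nonstationarity.
#' @param event_rate_rest1,event_rate_rest2 Repeated-template replay event
#'   rates (events/minute) in Rest1 and Rest2.
#' @param control_event_rate Control-template event rate (events/minute),
#'   applied identically in both rest blocks.
#' @param event_compression Timescale factor of embedded events relative to
#'   the native template duration, in (0, 2.5].
#' @param event_gain Multiplicative amplitude of embedded event patterns
#'   (z-units; rest noise has unit stationary SD).
#' @param nrem1_fraction Fraction of rest bins scheduled as true NREM1.
#' @param events_in_nrem1_only If `TRUE`, embedded events are placed entirely
#'   within true NREM1 bins.
#' @param success_rate_repeated,success_rate_control Probability that a
#'   repeated/control trial is completed successfully; failed trials are
#'   truncated after 1-3 targets. Defaults synthesize only successful trials.
#' @param seed Integer seed; identical config + seed gives an identical
#'   session.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_features = 40,
                         bin_width = 0.02,
                         n_repeated_trials = 66,
                         n_control_trials = 22,
                         per_target_duration = 1.1,
                         rest1_duration = 23.5,
                         rest2_duration = 26.2,
                         noise_ar_coeff = 0.3,
                         drift_amplitude = 0.5,
                         event_rate_rest1 = 0.3,
                         event_rate_rest2 = 1.2,
                         control_event_rate = 0.3,
                         event_compression = 0.1,
                         event_gain = 1.0,
                         nrem1_fraction = 0.3,
                         events_in_nrem1_only = FALSE,
                         success_rate_repeated = 1,
                         success_rate_control = 1,
                         seed = 1L) {
  cfg <- list(
    n_features = as.integer(n_features), bin_width = bin_width,
    n_repeated_trials = as.integer(n_repeated_trials),
    n_control_trials = as.integer(n_control_trials),
    per_target_duration = per_target_duration,
    rest1_duration = rest1_duration, rest2_duration = rest2_duration,
    noise_ar_coeff = noise_ar_coeff, drift_amplitude = drift_amplitude,
    event_rate_rest1 = event_rate_rest1, event_rate_rest2 = event_rate_rest2,
    control_event_rate = control_event_rate,
    event_compression = event_compression, event_gain = event_gain,
    nrem1_fraction = nrem1_fraction,
    events_in_nrem1_only = isTRUE(events_in_nrem1_only),
    success_rate_repeated = success_rate_repeated,
    success_rate_control = success_rate_control,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_features >= 1L,
    cfg$bin_width > 0,
    cfg$n_repeated_trials >= 1L,
    cfg$n_control_trials >= 0L,
    cfg$per_target_duration > 0,
    cfg$rest1_duration > 0, cfg$rest2_duration > 0,
    cfg$noise_ar_coeff >= 0, cfg$noise_ar_coeff < 1,
    cfg$drift_amplitude >= 0,
    cfg$event_rate_rest1 >= 0, cfg$event_rate_rest2 >= 0,
    cfg$control_event_rate >= 0,
    cfg$event_compression > 0, cfg$event_compression <= 2.5,
    cfg$event_gain >= 0,
    cfg$nrem1_fraction >= 0, cfg$nrem1_fraction < 1,
    cfg$success_rate_repeated >= 0, cfg$success_rate_repeated <= 1,
    cfg$success_rate_control >= 0, cfg$success_rate_control <= 1
  )
  if (cfg$n_control_trials %% 11L != 0L) {
    stop("`n_control_trials` must be divisible by 11 (11 control orderings)")
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
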