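#' Binned theta-envelope amplitude of an LFP trace
#'
#' Scores light sleep from the averaged intracranial LFP: a 2 Hz high-pass
#' (zero-phase forward-reverse Butterworth, order 6) removes slow deflection
#' artifacts; a zero-phase FIR band-pass isolates
#' 4-7 Hz theta (windowed-sinc design, order = 3 cycles of the 4 Hz low
#' cutoff at 1 kHz, i.e. 750 taps); the analytic-signal magnitude gives the
#' instantaneous envelope; and the median envelope over the samples of each
#' 20 ms bin aligns the theta series with the stored feature bins.
#'
#' @param lfp Numeric LFP samples at 1 kHz.
#' @param fs Sampling rate; must be 1000 Hz (resampling is the caller's job).
#' @param bin_width Feature bin width in seconds.
#'
#' @return A `theta_series` numeric vector, one nonnegative median envelope
#'   amplitude per bin, with attribute `bin_width`.
#' @export
theta_envelope <- function(lfp, fs = 1000, bin_width = 0.02) {
  if (fs != 1000) stop("`lfp` must be sampled at 1 kHz")
  lfp <- as.numeric(lfp)
  if (length(lfp) < 10 * fs) stop("LFP must be at least 10 s long")

  hp <- signal::butter(6, 2 / (fs / 2), type = "high")
  x <- signal::filtfilt(hp, lfp)

  ntaps <- 3 * fs / 4  # 3 cycles of the 4 Hz cutoff
  bp <- signal::fir1(ntaps, c(4, 7) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, x)

  env <- Mod(analytic_signal(x))

  spb <- as.integer(round(bin_width * fs))
  n_bins <- length(env) %/% spb
  m <- matrix(env[seq_len(n_bins * spb)], nrow = spb)
  structure(apply(m, 2L, median), bin_width = bin_width,
            class = "theta_series")
}

# analytic signal via the FFT half-spectrum method
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Delineate putative NREM1 vs putative waking rest bins
#'
#' The threshold is a percentile (default 80th) of the task-block theta
#' amplitudes, treating the sequence game as a waking baseline. Rest bins
#' above the threshold are scored putative NREM1. The used-bin counts are
#' then equalized so neither state has a statistical power advantage: the
#' putative-waking set is the equally many lowest-theta rest bins; when more
#' than 50% of rest bins are scored NREM1, both sets are instead sized to
#' the waking count (the NREM1 set keeping the highest-theta bins). All
#' remaining bins are labeled unused.
#'
#' @param theta_rest Theta series of a rest block ([theta_envelope()]).
#' @param theta_task Theta series of the task block.
#' @param percentile Task-theta percentile defining the threshold.
#'
#' @return A `state_mask` tibble with columns `bin`, `theta`, `label`
#'   (`"NREM1"`, `"waking"`, `"unused"`), and attributes `threshold`,
#'   `n_nrem1_used`, `n_waking_used`.
#' @export
score_states <- function(theta_rest, theta_task, percentile = 80) {
  rest <- as.numeric(theta_rest)
  task <- as.numeric(theta_task)
  if (!length(rest) || !length(task)) stop("theta series must be nonempty")
  threshold <- quantile(task, percentile / 100, type = 7, names = FALSE)
  n <- length(rest)
  above <- which(rest > threshold)
  label <- rep("unused", n)
  ord <- order(rest)  # ascending theta
  if (length(above) > n / 2) {
    size <- n - length(above)
    if (size > 0L) {
      nrem_set <- ord[(n - size + 1L):n]
      wake_set <- ord[seq_len(size)]
      label[nrem_set] <- "NREM1"
      label[wake_set] <- "waking"
    }
  } else if (length(above) > 0L) {
    size <- length(above)
    label[above] <- "NREM1"
    label[ord[seq_len(size)]] <- "waking"
  }
  structure(
    tibble(bin = seq_len(n), theta = rest, label = label),
    threshold = threshold,
    n_nrem1_used = sum(label == "NREM1"),
    n_waking_used = sum(label == "waking"),
    class = c("state_mask", "tbl_df", "tbl", "data.frame")
  )
}

#' Score both rest blocks of a session from its LFP traces
#'
#' Convenience wrapper: theta envelopes for the task block and both rest
#' blocks, then [score_states()] per rest block against the task baseline.
#'
#' @param session A `replay_session` with `lfp_task`, `lfp1`, `lfp2`.
#' @param percentile Task-theta percentile for the threshold.
#' @return `list(Rest1 = mask1, Rest2 = mask2)` of `state_mask` objects.
#' @export
score_session_states <- function(session, percentile = 80) {
  bw <- session$rest1$bin_width
  th_task <- theta_envelope(session$lfp_task, bin_width = bw)
  list(
    Rest1 = score_states(theta_envelope(session$lfp1, bin_width = bw),
                         th_task, percentile),
    Rest2 = score_states(theta_envelope(session$lfp2, bin_width = bw),
                         th_task, percentile)
  )
}

#' State-restricted Replay Index sweep
#'
#' Recomputes the dilation x centile sweep using only CC peaks that fall in
#' used bins of the requested state(s). CC series and non-maximum
#' suppression are computed on the full blocks as usual; restriction happens
#' at the peak level, each peak inheriting the state label of its
#' window-start bin (or majority label over the template span).
#'
#' @param sessions List of `replay_session` objects.
#' @param masks Per-session list of `list(Rest1, Rest2)` state masks, e.g.
#'   from [score_session_states()].
#' @param states States to keep in the output grid
#'   (default `c("NREM1", "waking")`).
#' @inheritParams run_sweep
#'
#' @return A `replay_sweep` tibble restricted to the requested states.
#' @export
state_restricted_replay <- function(sessions, masks,
                                    dilations = c(0.05, 0.075, seq(0.1, 2.5, by = 0.1)),
                                    centiles = c(75, 90, 95, 99, 99.9),
                                    tau = 120,
                                    states = c("NREM1", "waking"),
                                    state_assign = c("start", "majority")) {
  grid <- run_sweep(sessions, dilations, centiles, tau, masks = masks,
                    state_assign = match.arg(state_assign))
  out <- grid[grid$state %in% states, , drop = FALSE]
  structure(out, session_means = attr(grid, "session_means"),
            records = attr(grid, "records"),
            dilations = dilations, centiles = centiles,
            class = class(grid))
}
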