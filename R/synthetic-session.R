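#' Generate the four base target firing-rate motifs
#'
#' Each target is assigned a smooth (temporally low-pass filtered) random
#' spatiotemporal pattern of `round(per_target_duration / bin_width)` bins by
#' `n_features`, standardized to zero mean and unit SD. Patterns are
#' regenerated until all pairwise Pearson correlations of the flattened
#' patterns are below 0.3 in absolute value, so the four targets are
#' discriminable by construction.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of 4 T x F matrices.
#' @export
make_target_patterns <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  T0 <- max(2L, as.integer(round(config$per_target_duration / config$bin_width)))
  with_seed(seed, {
    for (attempt in seq_len(50L)) {
      pats <- lapply(seq_len(4L), function(i) {
        raw <- matrix(rnorm(T0 * config$n_features), T0, config$n_features)
        sm <- apply(raw, 2L, function(v) {
          as.numeric(stats::filter(v, rep(1 / 5, 5), sides = 2, circular = TRUE))
        })
        sm <- matrix(sm, T0, config$n_features)
        (sm - mean(sm)) / sd(as.numeric(sm))
      })
      flat <- vapply(pats, as.numeric, numeric(T0 * config$n_features))
      r <- cor(flat)
      if (max(abs(r[upper.tri(r)])) < 0.3) return(pats)
    }
    stop("could not generate 4 sufficiently uncorrelated target patterns")
  })
}

#' Synthesize a complete session with ground-truth replay events
#'
#' Builds one full synthetic recording session: a task block of repeated and
#' control sequence trials (ordered per-target motifs with per-trial timing
#' jitter, embedded in autocorrelated noise with slow drift), two rest blocks
#' of AR(1) noise plus drift with replay events additively embedded at known
#' times, and 1 kHz LFP traces whose 4-7 Hz theta amplitude is elevated
#' exactly during the scheduled NREM1 bins.
#'
#' Raw feature values are on an arbitrary per-feature scale (baseline +
#' scale x z-signal), so the adaptive z-scoring stage is exercised
#' non-trivially. Events are inserted additively (pattern + noise), keeping
#' noise statistics continuous at event boundaries; each target segment's
#' duration is jittered by a factor uniform in `[0.85, 1.15]`.
#'
#' @param config A [synth_config()].
#' @return An object of class `replay_session`: a list with elements
#'   `config`, `repeated_order`, `control_orders` (11 x 4 matrix), `trials`
#'   (tibble), `task`, `rest1`, `rest2` ([feature_series()]), `lfp_task`,
#'   `lfp1`, `lfp2` (1 kHz numeric vectors), `states1`, `states2` (per-bin
#'   `"NREM1"`/`"waking"` labels), and `truth` (tibble of embedded events).
#' @export
synthesize_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  patterns <- make_target_patterns(config)
  with_seed(config$seed + 1000003L, {
    F <- config$n_features
    bw <- config$bin_width
    baseline <- rnorm(F, 10, 2)
    scale_f <- runif(F, 0.5, 2)
    raw_units <- function(z) sweep(sweep(z, 2L, scale_f, `*`), 2L, baseline, `+`)

    repeated_order <- sample(4L)
    control_orders <- enumerate_control_sequences(repeated_order)

    ## ---- task block ----
    kinds <- c(rep("repeated", config$n_repeated_trials),
               rep("control", config$n_control_trials))
    kinds <- sample(kinds)
    ctl_ids <- sample(rep(seq_len(11L), config$n_control_trials / 11L))
    gap0 <- as.integer(round(2 / bw))
    trial_rows <- list()
    segs_at <- list()   # list of (bin offset, matrix) patterns to add
    pos <- gap0
    ci <- 0L
    for (ti in seq_along(kinds)) {
      kind <- kinds[ti]
      if (kind == "control") {
        ci <- ci + 1L
        ord <- control_orders[ctl_ids[ci], ]
      } else ord <- repeated_order
      p_succ <- if (kind == "repeated") config$success_rate_repeated else config$success_rate_control
      success <- runif(1) < p_succ
      n_targets <- if (success) 4L else sample(1:3, 1L)
      bounds <- rep(NA_integer_, 4L)
      start_bin <- pos + 1L
      for (j in seq_len(n_targets)) {
        len <- max(2L, as.integer(round(nrow(patterns[[ord[j]]]) * runif(1, 0.85, 1.15))))
        segs_at[[length(segs_at) + 1L]] <-
          list(at = pos, pat = resample_pattern(patterns[[ord[j]]], len))
        pos <- pos + len
        bounds[j] <- pos
      }
      trial_rows[[ti]] <- tibble(
        trial_id = ti, kind = kind, order = format_order(ord),
        success = success, start_bin = start_bin, end_bin = pos,
        b1 = bounds[1L], b2 = bounds[2L], b3 = bounds[3L], b4 = bounds[4L]
      )
      pos <- pos + as.integer(round(runif(1, 0.5, 1.5) / bw))
    }
    trials <- dplyr::bind_rows(trial_rows)
    n_task <- pos + gap0
    task_z <- ar1_noise(n_task, F, config$noise_ar_coeff) +
      drift_field(n_task, F, config$drift_amplitude, bw)
    for (s in segs_at) {
      idx <- (s$at + 1L):(s$at + nrow(s$pat))
      task_z[idx, ] <- task_z[idx, ] + s$pat
    }
    task <- feature_series(raw_units(task_z), bw, "task")

    ## ---- event motifs ----
    motif_for <- function(ord) do.call(rbind, patterns[ord])
    rep_motif <- motif_for(repeated_order)

    ## ---- rest blocks ----
    make_rest <- function(minutes, block, rate_rep) {
      n <- as.integer(round(minutes * 60 / bw))
      states <- nrem1_schedule(n, config$nrem1_fraction, bw)
      z <- ar1_noise(n, F, config$noise_ar_coeff) +
        drift_field(n, F, config$drift_amplitude, bw)
      occupied <- integer(0)
      events <- list()
      place_events <- function(n_ev, motif, class, id) {
        if (n_ev == 0L) return(invisible())
        len <- max(2L, as.integer(round(nrow(motif) * config$event_compression)))
        pat <- resample_pattern(motif, len) * config$event_gain
        for (k in seq_len(n_ev)) {
          placed <- FALSE
          for (try in seq_len(500L)) {
            s0 <- sample.int(n - len + 1L, 1L)
            span <- s0:(s0 + len - 1L)
            if (any(span %in% occupied)) next
            if (config$events_in_nrem1_only && any(states[span] != "NREM1")) next
            z[span, ] <<- z[span, ] + pat
            occupied <<- c(occupied, span)
            events[[length(events) + 1L]] <<- tibble(
              rest_block = block, start_bin = s0, template_class = class,
              template_id = id, compression = config$event_compression,
              gain = config$event_gain
            )
            placed <- TRUE
            break
          }
          if (!placed) {
            stop(sprintf(
              "cannot place %s events without overlap in %s (rate too high for block)",
              class, block))
          }
        }
      }
      place_events(rpois(1L, rate_rep * minutes), rep_motif, "repeated", "repeated")
      n_ctl <- rpois(1L, config$control_event_rate * minutes)
      if (n_ctl > 0L) {
        for (k in seq_len(n_ctl)) {
          cid <- sample.int(11L, 1L)
          place_events(1L, motif_for(control_orders[cid, ]), "control",
                       sprintf("control_%02d", cid))
        }
      }
      list(series = feature_series(raw_units(z), bw, block),
           states = states,
           truth = if (length(events)) dplyr::bind_rows(events) else NULL)
    }
    r1 <- make_rest(config$rest1_duration, "Rest1", config$event_rate_rest1)
    r2 <- make_rest(config$rest2_duration, "Rest2", config$event_rate_rest2)

    ## ---- LFP (1 kHz): theta bursts during scheduled NREM1 bins ----
    ## Task-period waking theta drifts over a wide range (movement, arousal);
    ## quiet-rest waking theta sits low and NREM1 theta high, so the
    ## task-derived percentile threshold separates the rest states.
    spb <- as.integer(round(bw * 1000))  # samples per bin
    make_lfp <- function(n_bins, states, task = FALSE) {
      n <- n_bins * spb
      tt <- seq_len(n) / 1000
      wake_amp <- if (task) {
        knots <- runif(max(2L, n %/% 2000 + 1L), 1.5, 6)
        approx(seq(0, 1, length.out = length(knots)), knots,
               seq(0, 1, length.out = n))$y
      } else rep(3, n)
      theta_amp <- ifelse(rep(states == "NREM1", each = spb), 25, wake_amp)
      theta_amp * sin(2 * pi * 5.5 * tt + runif(1, 0, 2 * pi)) +
        rnorm(n, sd = 5)
    }
    lfp1 <- make_lfp(nrow(r1$series$values), r1$states)
    lfp2 <- make_lfp(nrow(r2$series$values), r2$states)
    lfp_task <- make_lfp(n_task, rep("waking", n_task), task = TRUE)

    truth <- dplyr::bind_rows(r1$truth, r2$truth)
    if (is.null(truth)) {
      truth <- tibble(rest_block = character(), start_bin = integer(),
                      template_class = character(), template_id = character(),
                      compression = numeric(), gain = numeric())
    }
    structure(
      list(config = config, repeated_order = repeated_order,
           control_orders = control_orders, trials = trials, task = task,
           rest1 = r1$series, rest2 = r2$series,
           lfp_task = lfp_task, lfp1 = lfp1, lfp2 = lfp2,
           states1 = r1$states, states2 = r2$states, truth = truth),
      class = "replay_session"
    )
  })
}

#' @export
print.replay_session <- function(x, ...) {
  cat(sprintf(
    "<replay_session> seed %d: %d trials (%d repeated, %d control), %d features\n",
    x$config$seed, nrow(x$trials), sum(x$trials$kind == "repeated"),
    sum(x$trials$kind == "control"), x$config$n_features))
  cat(sprintf("  Rest1 %.1f min, Rest2 %.1f min; %d embedded events\n",
              nrow(x$rest1$values) * x$rest1$bin_width / 60,
              nrow(x$rest2$values) * x$rest2$bin_width / 60, nrow(x$truth)))
  invisible(x)
}

# per-feature AR(1) with unit stationary variance
ar1_noise <- function(n, n_features, phi) {
  innov_sd <- sqrt(1 - phi^2)
  out <- matrix(rnorm(n * n_features, sd = innov_sd), n, n_features)
  if (phi > 0) {
    for (f in seq_len(n_features)) {
      out[, f] <- as.numeric(stats::filter(out[, f], phi, method = "recursive",
                                           init = rnorm(1)))
    }
  }
  out
}

# slow sinusoidal mean drift, random phase per feature, ~10 min period
drift_field <- function(n, n_features, amplitude, bin_width, period = 600) {
  if (amplitude == 0) return(matrix(0, n, n_features))
  tt <- seq_len(n) * bin_width
  phases <- runif(n_features, 0, 2 * pi)
  amplitude * sin(outer(tt, rep(2 * pi / period, n_features)) +
                    matrix(phases, n, n_features, byrow = TRUE))
}

# contiguous 30 s epochs, a deterministic-count random subset scheduled NREM1
nrem1_schedule <- function(n_bins, fraction, bin_width, epoch_s = 30) {
  states <- rep("waking", n_bins)
  if (fraction <= 0) return(states)
  epoch_len <- max(1L, as.integer(round(epoch_s / bin_width)))
  n_epochs <- n_bins %/% epoch_len
  n_nrem <- round(fraction * n_epochs)
  if (n_nrem == 0L || n_epochs == 0L) return(states)
  picked <- sample.int(n_epochs, n_nrem)
  for (e in picked) {
    states[((e - 1L) * epoch_len + 1L):(e * epoch_len)] <- "NREM1"
  }
  states
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
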