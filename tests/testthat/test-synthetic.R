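test_that("target patterns have the specified shape and are near-orthogonal", {
  cfg <- synth_config(seed = 1)
  pats <- make_target_patterns(cfg)
  expect_length(pats, 4)
  for (p in pats) expect_equal(dim(p), c(55, 40))
  flat <- sapply(pats, as.numeric)
  r <- cor(flat)
  expect_lt(max(abs(r[upper.tri(r)])), 0.3)
  expect_identical(pats, make_target_patterns(cfg))
})

test_that("the default session structure matches the study design", {
  cfg <- synth_config(seed = 2)
  expect_equal(cfg$n_repeated_trials + cfg$n_control_trials, 88)
  expect_error(synth_config(n_control_trials = 10), "divisible by 11")
  expect_error(synth_config(event_compression = 3), "event_compression")
})

test_that("sessions are reproducible and structurally valid", {
  cfg <- tiny_config(seed = 5, control_event_rate = 0.5,
                     event_rate_rest1 = 0.5)
  s1 <- synthesize_session(cfg)
  s2 <- synthesize_session(cfg)
  expect_identical(s1$task$values, s2$task$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$lfp1, s2$lfp1)

  expect_equal(nrow(s1$trials),
               cfg$n_repeated_trials + cfg$n_control_trials)
  # every control ordering avoids the repeated ordering's transitions
  banned <- paste(s1$repeated_order[-4], s1$repeated_order[-1])
  ctl <- unique(s1$trials$order[s1$trials$kind == "control"])
  for (o in ctl) {
    p <- as.integer(strsplit(o, "-")[[1]])
    expect_false(any(paste(p[-4], p[-1]) %in% banned))
  }
  # LFP length matches bins at 1 kHz
  expect_equal(length(s1$lfp1), nrow(s1$rest1$values) * 20)
  expect_equal(length(s1$states2), nrow(s1$rest2$values))
})

test_that("zero event rates give pure-noise rest blocks", {
  s <- synthesize_session(tiny_config(seed = 6, event_rate_rest1 = 0,
                                      event_rate_rest2 = 0,
                                      control_event_rate = 0))
  expect_equal(nrow(s$truth), 0)
})

test_that("embedded event counts follow the configured rates", {
  counts <- numeric(10)
  for (k in 1:10) {
    s <- synthesize_session(tiny_config(
      seed = 600 + k, event_rate_rest1 = 1, event_rate_rest2 = 1,
      control_event_rate = 1
    ))
    counts[k] <- nrow(s$truth)
  }
  # 2 classes x 2 blocks x 2.5 min x 1/min = 10 expected per session
  total <- sum(counts)
  expect_gt(total, 100 - 4 * sqrt(100))
  expect_lt(total, 100 + 4 * sqrt(100))
})

test_that("embedded events never overlap within a block", {
  cfg <- tiny_config(seed = 7, event_rate_rest1 = 2, event_rate_rest2 = 3,
                     control_event_rate = 2, event_compression = 0.5)
  s <- synthesize_session(cfg)
  T0 <- round(cfg$per_target_duration / cfg$bin_width)
  len <- max(2, round(4 * T0 * cfg$event_compression))
  for (blk in c("Rest1", "Rest2")) {
    starts <- sort(s$truth$start_bin[s$truth$rest_block == blk])
    if (length(starts) > 1) expect_true(all(diff(starts) >= len))
  }
})

test_that("an impossible event rate errors rather than overlapping", {
  expect_error(
    synthesize_session(tiny_config(seed = 8, event_rate_rest2 = 400,
                                   event_compression = 1)),
    "overlap"
  )
})

test_that("embedded events are recoverable at the true compression", {
  cfg <- tiny_config(seed = 9, noise_ar_coeff = 0, drift_amplitude = 0,
                     event_gain = 5, event_compression = 0.5,
                     event_rate_rest2 = 1.5, control_event_rate = 0)
  s <- synthesize_session(cfg)
  pats <- make_target_patterns(cfg)
  motif <- do.call(rbind, pats[s$repeated_order])
  len <- max(2, round(nrow(motif) * cfg$event_compression))
  tmpl <- resample_pattern(motif, len)
  r2z <- adaptive_zscore(s$rest2, small_tau)
  cc <- normalized_xcorr(tmpl, r2z$values)
  hits <- s$truth$start_bin[s$truth$rest_block == "Rest2" &
                              s$truth$template_class == "repeated"]
  expect_gt(length(hits), 0)
  expect_true(all(cc[hits] > 0.9))
})

test_that("failed trials are truncated and flagged", {
  s <- synthesize_session(tiny_config(seed = 10, success_rate_repeated = 0.5,
                                      success_rate_control = 0.5))
  failed <- s$trials[!s$trials$success, ]
  expect_gt(nrow(failed), 0)
  expect_true(all(is.na(failed$b4)))
  ok <- s$trials[s$trials$success, ]
  expect_true(all(!is.na(ok$b4)) && all(ok$b4 == ok$end_bin))
})
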