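# build a minimal trial table + task series from explicit per-target segments
make_task <- function(trials_segments, orders, successes, n_features) {
  rows <- list()
  mat <- matrix(0, 0, n_features)
  pos <- 0L
  for (i in seq_along(trials_segments)) {
    segs <- trials_segments[[i]]
    start <- pos + 1L
    bounds <- rep(NA_integer_, 4L)
    for (j in seq_along(segs)) {
      mat <- rbind(mat, segs[[j]])
      pos <- pos + nrow(segs[[j]])
      bounds[j] <- pos
    }
    rows[[i]] <- tibble::tibble(
      trial_id = i, kind = "repeated",
      order = paste(orders[[i]], collapse = "-"), success = successes[i],
      start_bin = start, end_bin = pos,
      b1 = bounds[1], b2 = bounds[2], b3 = bounds[3], b4 = bounds[4]
    )
    # inter-trial noise gap
    gap <- matrix(rnorm(5 * n_features), 5, n_features)
    mat <- rbind(mat, gap)
    pos <- pos + 5L
  }
  list(trials = dplyr::bind_rows(rows),
       task = feature_series(mat, block = "task"))
}

test_that("identical segments average to the segment itself", {
  set.seed(21)
  segs <- lapply(1:4, function(i) matrix(rnorm(8 * 3), 8, 3))
  built <- make_task(list(segs, segs), list(1:4, 1:4), c(TRUE, TRUE), 3)
  tms <- build_single_target_templates(built$trials, built$task)
  for (i in 1:4) {
    expect_equal(tms[[i]]$pattern, segs[[i]], tolerance = 1e-12)
    expect_equal(tms[[i]]$source, "single_target")
  }
})

test_that("segment lengths 50 and 60 give a 55-bin template", {
  set.seed(22)
  t1a <- list(matrix(rnorm(50 * 2), 50, 2), matrix(rnorm(6 * 2), 6, 2),
              matrix(rnorm(6 * 2), 6, 2), matrix(rnorm(6 * 2), 6, 2))
  t1b <- list(matrix(rnorm(60 * 2), 60, 2), matrix(rnorm(6 * 2), 6, 2),
              matrix(rnorm(6 * 2), 6, 2), matrix(rnorm(6 * 2), 6, 2))
  built <- make_task(list(t1a, t1b), list(1:4, 1:4), c(TRUE, TRUE), 2)
  tms <- build_single_target_templates(built$trials, built$task)
  expect_equal(nrow(tms[[1]]$pattern), 55)
})

test_that("jittered copies of a known motif average back to the motif", {
  set.seed(23)
  motifs <- lapply(1:4, function(i) {
    # smooth band-limited motifs so linear resampling is nearly lossless
    sapply(1:3, function(f) {
      sin(2 * pi * runif(1, 0.5, 2) * (1:40) / 40 + runif(1, 0, 2 * pi))
    })
  })
  trials <- lapply(1:8, function(k) {
    lapply(motifs, function(m) resample_pattern(m, sample(34:46, 1)))
  })
  built <- make_task(trials, rep(list(1:4), 8), rep(TRUE, 8), 3)
  tms <- build_single_target_templates(built$trials, built$task)
  for (i in 1:4) {
    ref <- resample_pattern(motifs[[i]], nrow(tms[[i]]$pattern))
    expect_gt(cor(as.numeric(tms[[i]]$pattern), as.numeric(ref)), 0.99)
  }
})

test_that("targets are collected by ID, not position", {
  set.seed(24)
  segs <- lapply(1:4, function(i) matrix(rnorm(8 * 3) + i, 8, 3))
  # order 3-1-4-2: position 1 holds target 3's trajectory
  built <- make_task(list(segs), list(c(3, 1, 4, 2)), TRUE, 3)
  tms <- build_single_target_templates(built$trials, built$task)
  expect_equal(tms[[3]]$pattern, segs[[1]], tolerance = 1e-12)
  expect_equal(tms[[2]]$pattern, segs[[4]], tolerance = 1e-12)
})

test_that("unsuccessful trials are excluded from trial templates", {
  set.seed(25)
  segs <- lapply(1:4, function(i) matrix(rnorm(8 * 2), 8, 2))
  built <- make_task(list(segs, segs, segs), rep(list(1:4), 3),
                     c(TRUE, FALSE, TRUE), 2)
  tms <- build_trial_templates(built$trials, built$task)
  expect_length(tms, 2)
  expect_setequal(vapply(tms, function(t) t$id, numeric(1)), c(1, 3))
  expect_true(all(vapply(tms, function(t) t$kind, character(1)) == "repeated"))

  built$trials$success <- FALSE
  expect_error(build_trial_templates(built$trials, built$task), "successful")
  expect_error(build_single_target_templates(built$trials, built$task),
               "successful")
})

test_that("a full synthetic session yields one template per successful trial", {
  s <- synthesize_session(small_config(seed = 31))
  task_z <- adaptive_zscore(s$task, small_tau)
  tms <- build_trial_templates(s$trials, task_z)
  expect_length(tms, sum(s$trials$success))
  kinds <- vapply(tms, function(t) t$kind, character(1))
  expect_equal(sum(kinds == "repeated"),
               sum(s$trials$kind == "repeated" & s$trials$success))
})
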