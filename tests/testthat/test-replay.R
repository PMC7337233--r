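test_that("peak interleaving merges and labels by lag then target", {
  ps <- function(lags, ccs, block = "Rest1") {
    structure(tibble::tibble(lag = lags, cc = ccs), rest_block = block)
  }
  st <- interleave_peaks(list(ps(10, 0.9), ps(5, 0.8)), target_ids = 1:2)
  expect_equal(st$lag, c(5, 10))
  expect_equal(st$target_id, c(2, 1))

  st0 <- interleave_peaks(list(ps(integer(0), numeric(0)),
                               ps(integer(0), numeric(0))), 1:2)
  expect_equal(nrow(st0), 0)

  expect_error(interleave_peaks(list(ps(1, 0.5, "Rest1"), ps(2, 0.5, "Rest2")),
                                1:2), "different rest blocks")

  # sort-merge oracle on random sets, including tied lags
  set.seed(41)
  for (rep in 1:30) {
    sets <- lapply(1:4, function(i) {
      n <- sample(0:20, 1)
      ps(sample(1:30, n, replace = TRUE), runif(n))
    })
    st <- interleave_peaks(sets, 1:4)
    all_rows <- do.call(rbind, lapply(1:4, function(i) {
      data.frame(lag = sets[[i]]$lag,
                 target_id = rep(i, nrow(sets[[i]])),
                 cc = sets[[i]]$cc)
    }))
    ord <- order(all_rows$lag, all_rows$target_id)
    expect_equal(st$lag, all_rows$lag[ord])
    expect_equal(st$target_id, all_rows$target_id[ord])
  }
})

test_that("sequence hit counting matches the exhaustive oracle", {
  st <- tibble::tibble(lag = 1:4, target_id = c(1L, 2L, 3L, 4L),
                       cc = rep(0.9, 4))
  hc <- count_sequence_hits(st, 1:4)
  expect_equal(hc$hits, 1)
  expect_equal(hc$windows, 1)

  set.seed(42)
  orders <- rbind(1:4, do.call(rbind, lapply(
    list(c(2,1,4,3), c(4,3,2,1), c(1,3,2,4)), identity)))
  all_perms <- oracle_control_orders(1:4)  # 11 of them; add more below
  for (rep in 1:20) {
    n <- 500
    st <- tibble::tibble(lag = sort(sample(1:5000, n, replace = TRUE)),
                         target_id = sample(1:4, n, replace = TRUE),
                         cc = runif(n))
    expect_equal(count_sequence_hits(st, 1:4)$windows, n - 3)
    total <- 0
    perms24 <- unique(rbind(all_perms, orders,
                            do.call(rbind, neuroreplay:::permutations_of(1:4))))
    for (i in seq_len(nrow(perms24))) {
      o <- perms24[i, ]
      hc <- count_sequence_hits(st, o)
      expect_equal(hc$hits, oracle_hits(st$target_id, o))
      total <- total + hc$hits
    }
    # every window whose 4 labels are a permutation is a hit for exactly
    # one of the 24 orders
    lab <- st$target_id
    n_perm_windows <- sum(vapply(1:(n - 3), function(i) {
      length(unique(lab[i:(i + 3)])) == 4
    }, logical(1)))
    expect_equal(total, n_perm_windows)
  }
})

test_that("the pooled two-proportion chi-square reproduces known statistics", {
  r <- two_proportion_chi2(75, 11033, 34, 8703)
  expect_equal(round(r$chi2, 2), 7.40)
  expect_lt(r$p_value, 0.01)
  r2 <- two_proportion_chi2(606, 95733, 741, 121363)
  expect_equal(round(r2$chi2, 3), 0.437)
  expect_gt(r2$p_value, 0.5)

  eq <- two_proportion_chi2(5, 100, 5, 100)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 1)
  z <- two_proportion_chi2(0, 50, 0, 60)
  expect_equal(z$p_value, 1)

  # identity with the square of the pooled z statistic / prop.test oracle
  set.seed(43)
  for (rep in 1:50) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    a <- rbinom(1, n1, 0.2); b <- rbinom(1, n2, 0.25)
    if (a + b == 0 || a + b == n1 + n2) next
    ours <- two_proportion_chi2(a, n1, b, n2)
    ref <- suppressWarnings(
      prop.test(c(a, b), c(n1, n2), correct = FALSE)
    )
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(two_proportion_chi2(5, 4, 1, 10), "hits")
})

test_that("identical rest blocks give RI = 0 for every template", {
  s <- synthesize_session(tiny_config(seed = 44))
  s$rest2 <- s$rest1
  s$rest2$block <- "Rest2"
  rec <- session_ri_records(s, dilations = c(0.5, 1), centiles = 95,
                            tau = small_tau)
  expect_true(all(rec$valid))
  expect_true(all(rec$ri == 0))
  expect_true(all(rec$m1 == rec$m2))
})

test_that("replay_index handles dilation errors and basic arithmetic", {
  set.seed(45)
  tm <- replay_template(matrix(rnorm(40), 10, 4), "trial", id = 1,
                        kind = "repeated")
  r1 <- feature_series(matrix(rnorm(400 * 4), 400, 4), block = "Rest1")
  r2 <- feature_series(matrix(rnorm(400 * 4), 400, 4), block = "Rest2")
  rec <- replay_index(tm, r1, r2, centile = 90, dilation = 1)
  expect_true(rec$valid)
  expect_equal(rec$ri, (rec$m2 - rec$m1) / rec$m1, tolerance = 1e-12)
  expect_error(replay_index(tm, r1, r2, dilation = 100), "longer than")
})

test_that("the pooled-variance one-tailed t test matches closed form", {
  same <- session_ri_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 0.5)

  r <- session_ri_test(c(1, 2, 3), c(0, 1, 2))
  # pooled sd = 1, se = sqrt(2/3), t = sqrt(3/2)
  expect_equal(r$t, sqrt(1.5), tolerance = 1e-12)
  expect_equal(r$df, 4)
  ref <- t.test(c(1, 2, 3), c(0, 1, 2), var.equal = TRUE,
                alternative = "greater")
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)

  swapped <- session_ri_test(c(0, 1, 2), c(1, 2, 3))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p_value, 1 - r$p_value, tolerance = 1e-12)
  expect_error(session_ri_test(1, c(1, 2)), "at least 2")
})

test_that("the paired across-session test matches the one-sample closed form", {
  zero <- across_session_test(rep(1, 5), rep(1, 5))
  expect_equal(zero$t, 0)
  expect_equal(zero$p_value, 0.5)

  set.seed(46)
  x <- rnorm(10, 0.3)
  y <- rnorm(10)
  r <- across_session_test(x, y)
  d <- x - y
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
  ref <- t.test(x, y, paired = TRUE, alternative = "greater")
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(across_session_test(1:3, 1:4), "equal length")
})

test_that("single-target counts use the 11x control denominator", {
  # native-timescale events so the single-target templates can match them;
  # a high centile keeps weak cross-target correlations out of the stream
  s <- synthesize_session(small_config(seed = 47, event_rate_rest2 = 4,
                                       rest1_duration = 8, rest2_duration = 8,
                                       event_compression = 1, event_gain = 2,
                                       drift_amplitude = 0))
  cnt <- single_target_replay_counts(s, centile = 99.5, tau = small_tau)
  for (blk in c("Rest1", "Rest2")) {
    rep_row <- cnt[cnt$class == "repeated" & cnt$rest_block == blk, ]
    ctl_row <- cnt[cnt$class == "control" & cnt$rest_block == blk, ]
    expect_equal(ctl_row$windows, 11 * rep_row$windows)
  }
  # events embedded in Rest2 only: repeated hit proportion must rise
  rep1 <- cnt[cnt$class == "repeated" & cnt$rest_block == "Rest1", ]
  rep2 <- cnt[cnt$class == "repeated" & cnt$rest_block == "Rest2", ]
  expect_gt(rep2$proportion, rep1$proportion)
  tests <- sequenced_replay_test(cnt)
  expect_setequal(tests$class, c("repeated", "control"))
})

test_that("behavioral summary detects a built-in repeated advantage", {
  fake_session <- function(sr_rep, sr_ctl, seed) {
    set.seed(seed)
    mk <- function(kind, n, sr) {
      success <- runif(n) < sr
      len <- sample(200:260, n, replace = TRUE)
      start <- cumsum(c(1, len[-n] + 10))
      tibble::tibble(trial_id = seq_len(n), kind = kind,
                     order = "1-2-3-4", success = success,
                     start_bin = start, end_bin = start + len - 1,
                     b1 = NA, b2 = NA, b3 = NA, b4 = start + len - 1)
    }
    list(trials = rbind(mk("repeated", 30, sr_rep), mk("control", 22, sr_ctl)),
         task = list(bin_width = 0.02))
  }
  sessions <- lapply(1:10, function(i) fake_session(0.85, 0.62, 500 + i))
  beh <- behavioral_summary(sessions)
  wide <- tidyr::pivot_wider(beh$by_session[, c("session", "kind", "success_rate")],
                             names_from = "kind", values_from = "success_rate")
  expect_true(mean(wide$repeated) > mean(wide$control))
  p_succ <- beh$tests$p_value[beh$tests$measure == "success_rate"]
  # all 10 differences positive -> exact two-tailed signed-rank p = 2/1024
  if (all(wide$repeated > wide$control)) {
    expect_equal(p_succ, 2 / 1024, tolerance = 1e-12)
  }
  same <- lapply(1:4, function(i) fake_session(1, 1, 900 + i))
  expect_equal(
    behavioral_summary(same)$tests$p_value[1], 1
  )
  expect_error(behavioral_summary(sessions[1]), "at least 2")
})
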