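#' Interleave labeled single-target peak sets into one time series
#'
#' Merges the per-target CC peak sets for one rest block into a single
#' time-ordered stream, each peak labeled with its target ID. Equal lags are
#' ordered by ascending target ID.
#'
#' @param peaksets List of peak tibbles (from [extract_peaks()]), one per
#'   target, in target-ID order (or with `target_ids` given).
#' @param target_ids Integer target IDs, one per peak set.
#' @param rest_block Optional block label attached to the stream; if the peak
#'   sets carry a `rest_block` attribute, they must all agree.
#'
#' @return A tibble with columns `lag`, `target_id`, `cc`, sorted by
#'   `(lag, target_id)`, with attribute `rest_block`.
#' @export
interleave_peaks <- function(peaksets, target_ids = seq_along(peaksets),
                             rest_block = NULL) {
  blocks <- unique(unlist(lapply(peaksets, attr, "rest_block")))
  if (length(blocks) > 1L) {
    stop("peak sets come from different rest blocks: ",
         paste(blocks, collapse = ", "))
  }
  if (is.null(rest_block) && length(blocks)) rest_block <- blocks
  parts <- purrr::map2(peaksets, target_ids, function(ps, id) {
    tibble(lag = ps$lag, target_id = rep(as.integer(id), nrow(ps)), cc = ps$cc)
  })
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$lag, out$target_id), , drop = FALSE]
  structure(as_tibble(out), rest_block = rest_block)
}

#' Count sequence hits in a labeled peak stream
#'
#' Slides a window of 4 consecutive peaks (step 1, irrespective of their
#' temporal spacing) over the stream's target labels; a window is a hit iff
#' its labels equal `order` exactly. The number of windows is
#' `max(0, n_peaks - 3)`.
#'
#' @param stream Labeled peak stream from [interleave_peaks()].
#' @param order Integer permutation of `{1, 2, 3, 4}` to test.
#'
#' @return One-row tibble: `order`, `hits`, `windows`.
#' @export
count_sequence_hits <- function(stream, order) {
  order <- as.integer(order)
  if (length(order) != 4L || length(unique(order)) != 4L) {
    stop("`order` must be a permutation of 4 target IDs")
  }
  labels <- stream$target_id
  n <- length(labels)
  windows <- max(0L, n - 3L)
  hits <- 0L
  if (windows > 0L) {
    ok <- labels[1:(n - 3L)] == order[1L] &
      labels[2:(n - 2L)] == order[2L] &
      labels[3:(n - 1L)] == order[3L] &
      labels[4:n] == order[4L]
    hits <- sum(ok)
  }
  tibble(order = format_order(order), hits = as.integer(hits),
         windows = as.integer(windows))
}

#' Sequenced single-target replay counts for one session
#'
#' Runs the full single-target pipeline: adaptive z-scoring, the four
#' per-target average templates, normalized cross-correlation against both
#' rest blocks, pooled centile thresholds, non-maximum suppression with
#' window equal to each template's length, interleaving, and hit counting.
#' The repeated ordering is tested as-is; the 11 admissible control orderings
#' are tested against the same stream and their hits and windows accumulated,
#' so the control denominator is 11 x the per-ordering window count.
#'
#' @param session A `replay_session` (or list with `trials`, `task`, `rest1`,
#'   `rest2` and `repeated_order`).
#' @param centile CC centile threshold (default 95).
#' @param tau Adaptive z-scoring time constant in seconds.
#'
#' @return A tibble with one row per (class, rest block): columns `class`
#'   (`"repeated"`/`"control"`), `rest_block`, `hits`, `windows`,
#'   `proportion`. The interleaved streams are attached as attribute
#'   `streams`.
#' @export
single_target_replay_counts <- function(session, centile = 95, tau = 120) {
  task_z <- adaptive_zscore(session$task, tau)
  r1_z <- adaptive_zscore(session$rest1, tau)
  r2_z <- adaptive_zscore(session$rest2, tau)
  templates <- build_single_target_templates(session$trials, task_z)

  peaks <- lapply(c("Rest1", "Rest2"), function(block) {
    rz <- if (block == "Rest1") r1_z else r2_z
    lapply(templates, function(tm) {
      cc1 <- normalized_xcorr(tm, r1_z)
      cc2 <- normalized_xcorr(tm, r2_z)
      thr <- centile_threshold(cc1, cc2, centile)
      ps <- extract_peaks(if (block == "Rest1") cc1 else cc2, thr,
                          nrow(tm$pattern))
      attr(ps, "rest_block") <- block
      ps
    })
  })
  names(peaks) <- c("Rest1", "Rest2")
  streams <- lapply(names(peaks), function(block) {
    interleave_peaks(peaks[[block]], target_ids = 1:4, rest_block = block)
  })
  names(streams) <- names(peaks)

  rep_order <- session$repeated_order
  ctl_orders <- enumerate_control_sequences(rep_order)
  rows <- purrr::map(names(streams), function(block) {
    st <- streams[[block]]
    rep_counts <- count_sequence_hits(st, rep_order)
    ctl <- purrr::map(seq_len(nrow(ctl_orders)),
                      ~count_sequence_hits(st, ctl_orders[.x, ]))
    ctl <- dplyr::bind_rows(ctl)
    dplyr::bind_rows(
      tibble(class = "repeated", rest_block = block,
             hits = rep_counts$hits, windows = rep_counts$windows),
      tibble(class = "control", rest_block = block,
             hits = sum(ctl$hits), windows = sum(ctl$windows))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$proportion <- ifelse(out$windows > 0, out$hits / out$windows, NA_real_)
  structure(out, streams = streams, class = c("hit_counts", class(out)))
}

#' Pooled two-proportion chi-square test (1 df, no continuity correction)
#'
#' `chi2 = (p1 - p2)^2 / (p(1 - p) (1/n1 + 1/n2))` with `p` the pooled
#' proportion; the p-value is the upper tail of the chi-square distribution
#' with 1 degree of freedom. A degenerate pooled proportion of 0 or 1 gives
#' `chi2 = 0`, `p = 1`.
#'
#' @param a,n1 Hits and windows in the first group.
#' @param b,n2 Hits and windows in the second group.
#'
#' @return One-row tibble: `chi2`, `df`, `p_value`, `prop1`, `prop2`.
#' @export
two_proportion_chi2 <- function(a, n1, b, n2) {
  if (n1 < 1 || n2 < 1) stop("window counts must be >= 1")
  if (a < 0 || a > n1 || b < 0 || b > n2) stop("hits must lie in [0, windows]")
  p1 <- a / n1
  p2 <- b / n2
  pp <- (a + b) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- (p1 - p2)^2 / (pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  tibble(chi2 = chi2, df = 1L, p_value = p, prop1 = p1, prop2 = p2)
}

#' Chi-square tests on accumulated hit counts
#'
#' Compares the Rest2 vs Rest1 hit proportions separately for the repeated
#' ordering and the accumulated control orderings.
#'
#' @param counts Hit-count tibble as returned by
#'   [single_target_replay_counts()] (possibly summed across sessions).
#' @return A tibble with one row per class: `class`, `chi2`, `df`, `p_value`,
#'   `prop_rest1`, `prop_rest2`.
#' @export
sequenced_replay_test <- function(counts) {
  purrr::map_dfr(unique(counts$class), function(cl) {
    r1 <- counts[counts$class == cl & counts$rest_block == "Rest1", ]
    r2 <- counts[counts$class == cl & counts$rest_block == "Rest2", ]
    res <- two_proportion_chi2(sum(r2$hits), sum(r2$windows),
                               sum(r1$hits), sum(r1$windows))
    tibble(class = cl, chi2 = res$chi2, df = res$df, p_value = res$p_value,
           prop_rest1 = res$prop2, prop_rest2 = res$prop1)
  })
}

#' Replay Index of one template at one (dilation, centile) setting
#'
#' Dilates the template, scans both rest blocks, thresholds at the pooled
#' centile, applies non-maximum suppression (window = dilated template
#' length), and computes the mean peak CC in Rest1 (`m1`) and Rest2 (`m2`)
#' and the Replay Index `RI = (m2 - m1) / m1`. A record with zero peaks in
#' either block is marked invalid (`valid = FALSE`, `ri = NA`) and is
#' excluded from downstream distributions.
#'
#' @param template A [replay_template()] (trial or single-target).
#' @param rest1,rest2 Adaptively z-scored rest [feature_series()].
#' @param centile CC centile threshold.
#' @param dilation Timescale factor applied to the native template duration.
#'
#' @return One-row tibble: `template_id`, `kind`, `dilation`, `centile`,
#'   `m1`, `m2`, `ri`, `n_peaks_rest1`, `n_peaks_rest2`, `valid`.
#' @export
replay_index <- function(template, rest1, rest2, centile = 95, dilation = 1) {
  tm <- dilate_template(template, dilation)
  Td <- nrow(tm$pattern)
  if (Td > nrow(rest1$values) || Td > nrow(rest2$values)) {
    stop("dilated template is longer than a rest block")
  }
  cc1 <- normalized_xcorr(tm, rest1)
  cc2 <- normalized_xcorr(tm, rest2)
  thr <- centile_threshold(cc1, cc2, centile)
  p1 <- extract_peaks(cc1, thr, Td)
  p2 <- extract_peaks(cc2, thr, Td)
  ri_row(template, dilation, centile, p1$cc, p2$cc)
}

ri_row <- function(template, dilation, centile, cc1_peaks, cc2_peaks,
                   state = "all") {
  n1 <- length(cc1_peaks)
  n2 <- length(cc2_peaks)
  valid <- n1 >= 1L && n2 >= 1L
  m1 <- if (n1) mean(cc1_peaks) else NA_real_
  m2 <- if (n2) mean(cc2_peaks) else NA_real_
  tibble(
    template_id = as.character(template$id),
    kind = template$kind, dilation = dilation, centile = centile,
    state = state, m1 = m1, m2 = m2,
    ri = if (valid && m1 != 0) (m2 - m1) / m1 else NA_real_,
    n_peaks_rest1 = n1, n_peaks_rest2 = n2,
    valid = valid && m1 != 0
  )
}

#' Per-trial Replay Index records for one session
#'
#' The workhorse behind [run_sweep()] and [state_restricted_replay()]:
#' z-scores the session, builds one template per successful trial, and for
#' every (dilation, centile) computes each template's Replay Index. CC series
#' are computed once per (template, dilation) and shared across centile
#' thresholds and state restrictions. When state masks are supplied, each
#' peak is assigned the state label of its window-start bin (or the majority
#' label over the template span with `state_assign = "majority"`) and
#' additional NREM1-/waking-restricted records are produced.
#'
#' @param session A `replay_session`.
#' @param dilations,centiles Numeric vectors swept over.
#' @param tau Adaptive z-scoring time constant (s).
#' @param masks Optional list `list(Rest1 = mask1, Rest2 = mask2)` of
#'   [score_states()] masks for state-restricted records.
#' @param state_assign How a peak inherits a state label: `"start"` (label of
#'   the window-start bin) or `"majority"` (most frequent label over the
#'   template span, ties to the start bin's label).
#'
#' @return Tibble of Replay Index records with a `state` column (`"all"`, and
#'   `"NREM1"`/`"waking"` when masks are given).
#' @export
session_ri_records <- function(session, dilations = 1, centiles = 95,
                               tau = 120, masks = NULL,
                               state_assign = c("start", "majority")) {
  state_assign <- match.arg(state_assign)
  task_z <- adaptive_zscore(session$task, tau)
  r1_z <- adaptive_zscore(session$rest1, tau)
  r2_z <- adaptive_zscore(session$rest2, tau)
  templates <- build_trial_templates(session$trials, task_z)
  n1 <- nrow(r1_z$values)
  n2 <- nrow(r2_z$values)

  rows <- list()
  for (tm in templates) {
    for (d in dilations) {
      tmd <- dilate_template(tm, d)
      Td <- nrow(tmd$pattern)
      if (Td > n1 || Td > n2) {
        for (ct in centiles) {
          rows[[length(rows) + 1L]] <- ri_row(tm, d, ct, numeric(0), numeric(0))
        }
        next
      }
      cc1 <- normalized_xcorr(tmd, r1_z)
      cc2 <- normalized_xcorr(tmd, r2_z)
      for (ct in centiles) {
        thr <- centile_threshold(cc1, cc2, ct)
        p1 <- extract_peaks(cc1, thr, Td)
        p2 <- extract_peaks(cc2, thr, Td)
        rows[[length(rows) + 1L]] <- ri_row(tm, d, ct, p1$cc, p2$cc)
        if (!is.null(masks)) {
          l1 <- peak_state_labels(masks[[1L]], p1$lag, Td, state_assign)
          l2 <- peak_state_labels(masks[[2L]], p2$lag, Td, state_assign)
          for (st in c("NREM1", "waking")) {
            rows[[length(rows) + 1L]] <-
              ri_row(tm, d, ct, p1$cc[l1 == st], p2$cc[l2 == st], state = st)
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

peak_state_labels <- function(mask, lags, span, assign) {
  if (!length(lags)) return(character(0))
  labels <- mask$label
  if (assign == "start") return(labels[lags])
  vapply(lags, function(l) {
    seg <- labels[l:min(l + span - 1L, length(labels))]
    tab <- table(seg)
    best <- names(tab)[tab == max(tab)]
    if (length(best) == 1L) best else labels[l]
  }, character(1L))
}

#' Pooled-variance two-sample one-tailed t test (repeated > control)
#'
#' Within-session comparison of the repeated-trial RI distribution against
#' the control-trial distribution. Computed in closed form so that identical
#' groups yield `t = 0, p = 0.5` rather than an error.
#'
#' @param repeated_ris,control_ris Numeric vectors of valid Replay Indices.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_repeated`,
#'   `mean_control`.
#' @export
session_ri_test <- function(repeated_ris, control_ris) {
  x <- repeated_ris[is.finite(repeated_ris)]
  y <- control_ris[is.finite(control_ris)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) stop("need at least 2 valid RIs per group")
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  md <- mean(x) - mean(y)
  t <- if (se == 0) {
    if (md == 0) 0 else sign(md) * Inf
  } else md / se
  tibble(t = t, df = df, p_value = pt(t, df, lower.tail = FALSE),
         mean_repeated = mean(x), mean_control = mean(y))
}

#' Paired one-tailed t test across sessions (repeated > control)
#'
#' One-sample t on the per-session differences of mean RIs
#' (repeated - control), alternative: difference > 0. All-zero differences
#' yield `t = 0, p = 0.5`.
#'
#' @param session_means_repeated,session_means_control Equal-length paired
#'   numeric vectors, one entry per session.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_difference`.
#' @export
across_session_test <- function(session_means_repeated, session_means_control) {
  x <- session_means_repeated
  y <- session_means_control
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired sessions")
  s <- sd(d)
  t <- if (s == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (s / sqrt(n))
  tibble(t = t, df = n - 1L, p_value = pt(t, n - 1L, lower.tail = FALSE),
         mean_difference = mean(d))
}

#' Replay Index sweep across dilations and centile thresholds
#'
#' For every (dilation, centile) cell: per-session mean Replay Index of the
#' repeated and of the control trials, the across-session paired one-tailed
#' t test (repeated > control), and the swapped test (control > repeated)
#' that serves as the empirical multiple-comparison null. Cells where fewer
#' than 2 sessions contribute both group means are emitted with `NA` tests.
#'
#' @param sessions List of `replay_session` objects (>= 2 for the
#'   across-session tests).
#' @param dilations Time dilation factors; defaults to the full sweep
#'   `c(0.05, 0.075, seq(0.1, 2.5, by = 0.1))` (27 values).
#' @param centiles Centile thresholds; default `c(75, 90, 95, 99, 99.9)`.
#' @param tau Adaptive z-scoring time constant (s).
#' @param masks Optional per-session list of `list(mask1, mask2)` state masks;
#'   adds NREM1-/waking-restricted cells.
#' @param state_assign Peak state attribution rule, see [session_ri_records()].
#'
#' @return A `replay_sweep` tibble: one row per (dilation, centile, state)
#'   with `n_sessions`, `mean_ri_repeated`, `mean_ri_control`, `t`, `p`,
#'   `t_swapped`, `p_swapped`. Per-session means are attached as attribute
#'   `session_means`, the full record set as attribute `records`.
#' @export
run_sweep <- function(sessions,
                      dilations = c(0.05, 0.075, seq(0.1, 2.5, by = 0.1)),
                      centiles = c(75, 90, 95, 99, 99.9),
                      tau = 120, masks = NULL,
                      state_assign = c("start", "majority")) {
  state_assign <- match.arg(state_assign)
  records <- purrr::imap_dfr(sessions, function(s, i) {
    rec <- session_ri_records(
      s, dilations, centiles, tau,
      masks = if (is.null(masks)) NULL else masks[[i]],
      state_assign = state_assign
    )
    rec$session <- i
    rec
  })
  sweep_from_records(records, dilations, centiles)
}

sweep_from_records <- function(records, dilations, centiles) {
  means <- records |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$session, .data$dilation, .data$centile,
                    .data$state, .data$kind) |>
    dplyr::summarise(mean_ri = mean(.data$ri), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "mean_ri")
  for (col in c("repeated", "control")) {
    if (!col %in% names(means)) means[[col]] <- NA_real_
  }

  cell_row <- function(df, key) {
    ok <- is.finite(df$repeated) & is.finite(df$control)
    n <- sum(ok)
    row <- tibble(
      n_sessions = n,
      mean_ri_repeated = mean(df$repeated[is.finite(df$repeated)]),
      mean_ri_control = mean(df$control[is.finite(df$control)]),
      t = NA_real_, p = NA_real_,
      t_swapped = NA_real_, p_swapped = NA_real_
    )
    if (n >= 2L) {
      direct <- across_session_test(df$repeated, df$control)
      swapped <- across_session_test(df$control, df$repeated)
      row$t <- direct$t
      row$p <- direct$p_value
      row$t_swapped <- swapped$t
      row$p_swapped <- swapped$p_value
    }
    row
  }
  grid <- means |>
    dplyr::group_by(.data$dilation, .data$centile, .data$state) |>
    dplyr::group_modify(cell_row) |>
    dplyr::ungroup() |>
    tidyr::complete(dilation = dilations, centile = centiles,
                    state = unique(records$state),
                    fill = list(n_sessions = 0L)) |>
    dplyr::arrange(.data$state, .data$centile, .data$dilation)
  structure(grid, session_means = means, records = records,
            dilations = dilations, centiles = centiles,
            class = c("replay_sweep", class(grid)))
}

#' Behavioral learning summary across sessions
#'
#' Per session and sequence kind: success rate (% of trials correctly
#' completed) and mean completion time of successful trials. Across sessions,
#' repeated vs control success rates (and times) are compared with an exact
#' two-tailed Wilcoxon signed-rank test (sign-pattern enumeration for
#' n <= 12, the standard exact method).
#'
#' @param sessions List of `replay_session` objects (>= 2).
#' @return A `replay_behavior` list: `$by_session` tibble (session, kind,
#'   n_trials, success_rate, mean_time) and `$tests` tibble (measure, V
#'   statistic, p_value, n).
#' @export
behavioral_summary <- function(sessions) {
  if (length(sessions) < 2L) stop("need at least 2 sessions")
  by_session <- purrr::imap_dfr(sessions, function(s, i) {
    bw <- s$task$bin_width
    s$trials |>
      dplyr::group_by(.data$kind) |>
      dplyr::summarise(
        n_trials = dplyr::n(),
        success_rate = 100 * mean(.data$success),
        mean_time = mean((.data$end_bin[.data$success] -
                            .data$start_bin[.data$success] + 1L) * bw),
        .groups = "drop"
      ) |>
      dplyr::mutate(session = i, .before = 1L)
  })
  wide <- function(col) {
    tidyr::pivot_wider(by_session[, c("session", "kind", col)],
                       names_from = "kind", values_from = dplyr::all_of(col))
  }
  test_on <- function(col, measure) {
    w <- wide(col)
    n <- nrow(w)
    if (all(w$repeated == w$control)) {
      return(tibble(measure = measure, statistic = 0, p_value = 1, n = n))
    }
    wt <- suppressWarnings(
      wilcox.test(w$repeated, w$control, paired = TRUE, exact = n <= 12)
    )
    tibble(measure = measure, statistic = unname(wt$statistic),
           p_value = wt$p.value, n = n)
  }
  structure(
    list(by_session = by_session,
         tests = dplyr::bind_rows(
           test_on("success_rate", "success_rate"),
           test_on("mean_time", "completion_time")
         )),
    class = "replay_behavior"
  )
}

#' @export
print.replay_behavior <- function(x, ...) {
  cat("<replay_behavior>\n")
  print(x$by_session, n = 6)
  cat("Wilcoxon signed-rank (two-tailed, repeated vs control):\n")
  print(x$tests)
  invisible(x)
}
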