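#' Simulate a session and write it to disk
#'
#' @param config A [synth_config()].
#' @param dir Output session directory.
#' @return The session directory path, invisibly.
#' @export
simulate_session <- function(config, dir) {
  session <- synthesize_session(config)
  write_session(session, dir)
  message(sprintf("wrote session (seed %d, %d trials) to %s",
                  config$seed, nrow(session$trials), dir))
  invisible(dir)
}

#' Run the full replay analysis over a set of sessions
#'
#' Orchestrates the complete pipeline: sequenced single-target hit counting
#' with chi-square tests (accumulated across sessions), the per-trial Replay
#' Index sweep over dilations and centile thresholds with the swapped-control
#' null, the behavioral learning summary, and (optionally) theta-scored
#' state-restricted replay. Results are written as TSV/JSON files plus a
#' human-readable summary.
#'
#' @param sessions List of `replay_session` objects, or a character vector
#'   of session directories written by [write_session()].
#' @param out_dir Output directory for result files (created if missing);
#'   `NULL` skips writing.
#' @param dilations,centiles Sweep grids. The default is a reduced sweep
#'   (`full_sweep = TRUE` restores the full 27 x 5 grid).
#' @param centile Default centile for the single-target analysis.
#' @param tau Adaptive z-scoring time constant (s).
#' @param theta_percentile Task-theta percentile for state scoring.
#' @param state If `TRUE`, run the state-restricted analysis.
#' @param full_sweep If `TRUE`, use the full dilation/centile grids.
#'
#' @return A list with elements `hit_counts`, `hit_tests`, `sweep`,
#'   `behavior`, and (if requested) `state_masks`, `state_sweep`; invisibly
#'   when `out_dir` is given.
#' @export
analyze_sessions <- function(sessions, out_dir = NULL,
                             dilations = c(0.05, 0.1, 0.5, 1, 2),
                             centiles = 95,
                             centile = 95, tau = 120,
                             theta_percentile = 80,
                             state = TRUE, full_sweep = FALSE) {
  if (is.character(sessions)) sessions <- lapply(sessions, read_session)
  usable <- vapply(sessions, function(s) any(s$trials$success), logical(1L))
  if (!all(usable)) {
    warning(sprintf("skipping %d session(s) with zero successful trials",
                    sum(!usable)))
    sessions <- sessions[usable]
  }
  if (!length(sessions)) stop("no usable sessions")
  if (full_sweep) {
    dilations <- c(0.05, 0.075, seq(0.1, 2.5, by = 0.1))
    centiles <- c(75, 90, 95, 99, 99.9)
  }

  counts <- purrr::imap_dfr(sessions, function(s, i) {
    dplyr::mutate(single_target_replay_counts(s, centile = centile, tau = tau),
                  session = i, .before = 1L)
  })
  pooled <- counts |>
    dplyr::group_by(.data$class, .data$rest_block) |>
    dplyr::summarise(hits = sum(.data$hits), windows = sum(.data$windows),
                     .groups = "drop")
  hit_tests <- sequenced_replay_test(pooled)

  masks <- NULL
  state_sweep <- NULL
  if (state) {
    masks <- lapply(sessions, score_session_states,
                    percentile = theta_percentile)
    sweep <- run_sweep(sessions, dilations, centiles, tau, masks = masks)
    state_sweep <- sweep[sweep$state != "all", , drop = FALSE]
    sweep <- sweep[sweep$state == "all", , drop = FALSE]
  } else {
    sweep <- run_sweep(sessions, dilations, centiles, tau)
  }

  behavior <- if (length(sessions) >= 2L) behavioral_summary(sessions) else NULL

  res <- list(hit_counts = counts, pooled_counts = pooled,
              hit_tests = hit_tests, sweep = sweep,
              behavior = behavior, state_masks = masks,
              state_sweep = state_sweep,
              settings = list(dilations = dilations, centiles = centiles,
                              centile = centile, tau = tau,
                              theta_percentile = theta_percentile))
  if (is.null(out_dir)) return(res)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- attr(if (state) rbind(sweep) else sweep, "records")
  readr::write_tsv(as_tibble(sweep), file.path(out_dir, "sweep.tsv"),
                   progress = FALSE)
  jsonlite::write_json(as.data.frame(sweep), file.path(out_dir, "sweep.json"),
                       auto_unbox = TRUE, digits = NA)
  rec <- attr(sweep, "records")
  if (!is.null(rec)) {
    readr::write_tsv(rec, file.path(out_dir, "replay_indices.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(counts = as.data.frame(pooled), tests = as.data.frame(hit_tests)),
    file.path(out_dir, "single_target.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(behavior)) {
    jsonlite::write_json(
      list(by_session = as.data.frame(behavior$by_session),
           tests = as.data.frame(behavior$tests)),
      file.path(out_dir, "behavior.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(masks)) {
    mask_tbl <- purrr::imap_dfr(masks, function(m, i) {
      dplyr::bind_rows(
        dplyr::mutate(as_tibble(m$Rest1), session = i, block = "Rest1"),
        dplyr::mutate(as_tibble(m$Rest2), session = i, block = "Rest2")
      )
    })
    readr::write_tsv(mask_tbl, file.path(out_dir, "state_masks.tsv"),
                     progress = FALSE)
    readr::write_tsv(as_tibble(state_sweep),
                     file.path(out_dir, "state_sweep.tsv"), progress = FALSE)
  }
  writeLines(summary_lines(res), file.path(out_dir, "summary.txt"))
  invisible(res)
}

summary_lines <- function(res) {
  c(
    sprintf("neuroreplay analysis (%d session(s))",
            length(unique(res$hit_counts$session))),
    sprintf("settings: centile %s, tau %gs, dilations [%s], centiles [%s]",
            res$settings$centile, res$settings$tau,
            paste(res$settings$dilations, collapse = ", "),
            paste(res$settings$centiles, collapse = ", ")),
    "",
    "Sequenced single-target replay (Rest2 vs Rest1):",
    vapply(seq_len(nrow(res$hit_tests)), function(i) {
      r <- res$hit_tests[i, ]
      sprintf("  %s: %.3g%% -> %.3g%%, chi2(1) = %.3f, p = %.4g",
              r$class, 100 * r$prop_rest1, 100 * r$prop_rest2, r$chi2,
              r$p_value)
    }, character(1L)),
    "",
    "Replay Index sweep (paired one-tailed t, repeated > control):",
    vapply(seq_len(nrow(res$sweep)), function(i) {
      r <- res$sweep[i, ]
      sprintf("  dilation %.3g, centile %s: RI(rep) = %.4f, RI(ctl) = %.4f, t = %.3f, p = %.4g (swapped p = %.4g)",
              r$dilation, r$centile, r$mean_ri_repeated, r$mean_ri_control,
              r$t, r$p, r$p_swapped)
    }, character(1L)),
    if (!is.null(res$behavior)) c(
      "",
      "Behavior (Wilcoxon signed-rank, two-tailed):",
      vapply(seq_len(nrow(res$behavior$tests)), function(i) {
        r <- res$behavior$tests[i, ]
        sprintf("  %s: V = %g, p = %.4g (n = %d)", r$measure, r$statistic,
                r$p_value, r$n)
      }, character(1L))
    ) else character(0)
  )
}
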