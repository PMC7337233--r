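#' Spatiotemporal replay template
#'
#' A template is a fixed T x F firing pattern (in z-units) extracted from
#' task performance and slid against rest blocks. Two kinds are used:
#' per-target averages (`source = "single_target"`) for the sequenced
#' single-target analysis, and whole-trial patterns (`source = "trial"`)
#' for the Replay Index analysis.
#'
#' @param pattern Numeric T x F matrix, T >= 2, with nonzero variance.
#' @param source `"single_target"` or `"trial"`.
#' @param id Target ID (1-4) or trial ID.
#' @param kind For trial templates, `"repeated"` or `"control"`.
#' @param dilation Timescale factor relative to the native duration.
#' @param native_length Native template length in bins (before dilation).
#'
#' @return An object of class `replay_template`.
#' @export
replay_template <- function(pattern, source = c("single_target", "trial"),
                            id, kind = NA_character_, dilation = 1,
                            native_length = nrow(pattern)) {
  source <- match.arg(source)
  pattern <- as.matrix(pattern)
  if (nrow(pattern) < 2L) stop("template must span at least 2 bins")
  if (stats::var(as.numeric(pattern)) == 0) stop("template has zero variance")
  structure(
    list(pattern = pattern, source = source, id = id, kind = kind,
         dilation = dilation, native_length = native_length),
    class = "replay_template"
  )
}

#' @export
print.replay_template <- function(x, ...) {
  cat(sprintf("<replay_template> %s %s: %d x %d bins x features, dilation %.3g\n",
              x$source, as.character(x$id), nrow(x$pattern), ncol(x$pattern),
              x$dilation))
  invisible(x)
}

#' Dilate a replay template by a timescale factor
#'
#' @param template A [replay_template()].
#' @param dilation Multiplicative factor applied to the native duration.
#' @return A `replay_template` resampled to `round(native_length * dilation)`
#'   bins (at least 2).
#' @export
dilate_template <- function(template, dilation) {
  stopifnot(inherits(template, "replay_template"))
  if (dilation == template$dilation) return(template)
  out <- template
  out$pattern <- resample_pattern(
    template$pattern,
    max(2L, as.integer(round(template$native_length * dilation)))
  )
  out$dilation <- dilation
  out
}

#' Build the four single-target average templates
#'
#' For each of the 4 targets: all trajectory segments to that target are
#' collected from successful repeated-sequence trials, each segment is
#' resampled to the mean segment duration (rounded to the nearest bin), and
#' the resampled segments are averaged elementwise.
#'
#' @param trials Trial table (see [synthesize_session()]): columns
#'   `trial_id`, `kind`, `success`, `start_bin`, `end_bin`, `b1`..`b4`
#'   (end bin of each of the 4 target trajectories) and `order` (dash-joined
#'   target IDs, e.g. `"3-1-4-2"`).
#' @param task_series The task-block [feature_series()], normally already
#'   adaptively z-scored.
#'
#' @return A list of 4 `replay_template`s, indexed by target ID.
#' @export
build_single_target_templates <- function(trials, task_series) {
  x <- as_feature_matrix(task_series)
  use <- trials[trials$kind == "repeated" & trials$success, , drop = FALSE]
  if (nrow(use) == 0L) stop("no successful repeated-sequence trials")
  segs <- vector("list", 4L)
  for (i in seq_len(nrow(use))) {
    ord <- parse_order(use$order[i])
    bounds <- c(use$start_bin[i] - 1L, use$b1[i], use$b2[i], use$b3[i], use$b4[i])
    for (j in seq_len(4L)) {
      if (is.na(bounds[j + 1L])) next
      tgt <- ord[j]
      seg <- x[(bounds[j] + 1L):bounds[j + 1L], , drop = FALSE]
      segs[[tgt]] <- c(segs[[tgt]], list(seg))
    }
  }
  lapply(seq_len(4L), function(tgt) {
    ss <- segs[[tgt]]
    if (is.null(ss) || !length(ss)) {
      stop(sprintf("target %d has no successful trajectories", tgt))
    }
    mlen <- max(2L, as.integer(round(mean(vapply(ss, nrow, integer(1L))))))
    avg <- Reduce(`+`, lapply(ss, resample_pattern, new_length = mlen)) / length(ss)
    replay_template(avg, "single_target", id = tgt)
  })
}

#' Build one whole-trial template per successful trial
#'
#' Each correctly completed 4-target trial contributes its full spatiotemporal
#' activity pattern as a separate template, labeled by its sequence kind.
#' Unsuccessful trials are excluded.
#'
#' @inheritParams build_single_target_templates
#' @return A list of `replay_template`s with `source = "trial"`.
#' @export
build_trial_templates <- function(trials, task_series) {
  x <- as_feature_matrix(task_series)
  use <- trials[trials$success, , drop = FALSE]
  if (nrow(use) == 0L) stop("no successful trials")
  lapply(seq_len(nrow(use)), function(i) {
    replay_template(
      x[use$start_bin[i]:use$end_bin[i], , drop = FALSE],
      "trial", id = use$trial_id[i], kind = use$kind[i]
    )
  })
}

parse_order <- function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
format_order <- function(p) paste(p, collapse = "-")
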