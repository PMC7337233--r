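#' Tidy a Replay Index sweep grid
#'
#' @param x A `replay_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return The grid as a plain tibble (one row per dilation x centile x
#'   state cell).
#' @export
tidy.replay_sweep <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a Replay Index sweep
#'
#' @param x A `replay_sweep`.
#' @param ... Unused.
#' @return One-row tibble: number of cells, the minimum-p cell's dilation,
#'   centile and p, and the count of cells significant at p < 0.01 for the
#'   direct and the swapped test.
#' @export
glance.replay_sweep <- function(x, ...) {
  ok <- is.finite(x$p)
  best <- if (any(ok)) which.min(replace(x$p, !ok, Inf)) else NA_integer_
  tibble(
    n_cells = nrow(x),
    best_dilation = if (is.na(best)) NA_real_ else x$dilation[best],
    best_centile = if (is.na(best)) NA_real_ else x$centile[best],
    min_p = if (is.na(best)) NA_real_ else x$p[best],
    n_significant = sum(x$p < 0.01, na.rm = TRUE),
    n_significant_swapped = sum(x$p_swapped < 0.01, na.rm = TRUE)
  )
}

#' Tidy a behavioral summary
#'
#' @param x A `replay_behavior` from [behavioral_summary()].
#' @param ... Unused.
#' @return The per-session tibble.
#' @export
tidy.replay_behavior <- function(x, ...) x$by_session

#' One-row summary of the behavioral tests
#'
#' @param x A `replay_behavior`.
#' @param ... Unused.
#' @return One-row tibble with the success-rate and completion-time
#'   signed-rank p-values.
#' @export
glance.replay_behavior <- function(x, ...) {
  tibble(
    n_sessions = x$tests$n[1L],
    p_success_rate = x$tests$p_value[x$tests$measure == "success_rate"],
    p_completion_time = x$tests$p_value[x$tests$measure == "completion_time"]
  )
}
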