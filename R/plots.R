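#' Plot a Replay Index sweep grid
#'
#' With a single centile, draws the mean RI difference (repeated - control)
#' against time dilation, marking cells significant at p < 0.01; with
#' several centiles, draws a dilation x centile heat map of the paired
#' t score.
#'
#' @param object A `replay_sweep` from [run_sweep()].
#' @param state Which state's cells to show (default `"all"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.replay_sweep <- function(object, state = NULL, ...) {
  df <- as_tibble(as.data.frame(object))
  if (is.null(state)) state <- df$state[1L]
  df <- df[df$state == state, , drop = FALSE]
  if (length(unique(df$centile)) == 1L) {
    df$diff <- df$mean_ri_repeated - df$mean_ri_control
    df$sig <- !is.na(df$p) & df$p < 0.01
    ggplot2::ggplot(df, ggplot2::aes(x = .data$dilation, y = .data$diff)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
      ggplot2::geom_line() +
      ggplot2::geom_point(ggplot2::aes(color = .data$sig)) +
      ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                  name = "p < 0.01") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "time dilation factor",
                    y = "mean RI difference (repeated - control)",
                    title = sprintf("Replay Index sweep (%s, centile %s)",
                                    state, df$centile[1L]))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$dilation),
                                     y = factor(.data$centile),
                                     fill = .data$t)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                    name = "paired t") +
      ggplot2::labs(x = "time dilation factor", y = "CC centile threshold",
                    title = sprintf("Replay Index sweep (%s)", state)) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
  }
}

#' Plot per-trial Replay Index distributions
#'
#' Mirrors the repeated-vs-control RI distribution comparison: one point per
#' trial template, grouped by sequence kind.
#'
#' @param records RI record tibble from [session_ri_records()] (or the
#'   `records` attribute of a sweep), already filtered to one
#'   (dilation, centile) setting if several were swept.
#' @param dilation,centile Optional filters applied to `records`.
#' @return A ggplot object.
#' @export
plot_ri_distributions <- function(records, dilation = NULL, centile = NULL) {
  df <- dplyr::filter(records, .data$valid, .data$state == "all")
  if (!is.null(dilation)) df <- df[df$dilation == dilation, ]
  if (!is.null(centile)) df <- df[df$centile == centile, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = 100 * .data$ri,
                                   color = .data$kind)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, color = "black") +
    ggplot2::scale_color_manual(values = c(repeated = "firebrick",
                                           control = "steelblue"),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "Replay Index (% change Rest1 -> Rest2)")
}

#' Plot a theta state mask
#'
#' @param object A `state_mask` from [score_states()].
#' @param ... Unused.
#' @return A ggplot object showing the binned theta envelope colored by
#'   state label, with the threshold line.
#' @export
autoplot.state_mask <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$theta,
                                   color = .data$label)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::scale_color_manual(values = c(NREM1 = "navy", waking = "orange",
                                           unused = "grey70")) +
    ggplot2::labs(x = "20 ms bin", y = "median theta envelope amplitude")
}
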