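#' Binned neural feature series
#'
#' A `feature_series` holds one block's binned neural features as a numeric
#' matrix (bins x features), together with the bin width and a block label.
#' It is the substrate for all template matching: task blocks supply the
#' templates, rest blocks are scanned for replay.
#'
#' @param values Numeric matrix, one row per time bin, one column per feature.
#'   No missing values are allowed.
#' @param bin_width Bin width in seconds (default 0.02, i.e. 20 ms).
#' @param block Block label, one of `"task"`, `"Rest1"`, `"Rest2"`.
#' @param start_time Time of the first bin's left edge, in seconds.
#'
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, bin_width = 0.02,
                           block = c("task", "Rest1", "Rest2"),
                           start_time = 0) {
  block <- match.arg(block)
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be a finite numeric matrix with no missing entries")
  }
  if (ncol(values) < 1L) stop("`values` needs at least one feature column")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  structure(
    list(values = values, bin_width = bin_width, block = block,
         start_time = start_time, burn_in = 0L),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf(
    "<feature_series> %s: %d bins x %d features, %.0f ms bins (%.1f min)%s\n",
    x$block, nrow(x$values), ncol(x$values), x$bin_width * 1000,
    nrow(x$values) * x$bin_width / 60,
    if (x$burn_in > 0L) sprintf(", %d burn-in bins", x$burn_in) else ""
  ))
  invisible(x)
}

#' @export
dim.feature_series <- function(x) dim(x$values)

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_series")) x$values else as.matrix(x)
}

series_burn_in <- function(x) {
  if (inherits(x, "feature_series")) x$burn_in else 0L
}
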