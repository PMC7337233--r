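#' Adaptive (exponentially weighted) z-scoring of a feature series
#'
#' Normalizes each feature by a causal running mean and standard deviation so
#' that slow nonstationarities in feature baselines and scales do not
#' spuriously inflate or deflate correlations across a block. With smoothing
#' factor `alpha = exp(-bin_width / tau)`, the running moments are
#' `mu_t = alpha * mu_{t-1} + (1 - alpha) * x_t` and the running variance is
#' updated with the same `alpha` from squared deviations. The output at bin t
#' uses only moments from bins before t:
#' `z_t = (x_t - mu_{t-1}) / max(sigma_{t-1}, 1e-6)`.
#'
#' The first `ceiling(tau / bin_width)` bins are flagged as burn-in: they are
#' retained in the output but excluded downstream when centile thresholds are
#' computed, because the running moments have not yet converged there.
#'
#' @param series A [feature_series()] (or bare matrix, in which case
#'   `bin_width` must be supplied via attributes-free default 0.02).
#' @param tau Time constant of the exponential window, in seconds.
#'
#' @return A `feature_series` of the same shape in z-units, with the burn-in
#'   length recorded in the `burn_in` field.
#' @export
adaptive_zscore <- function(series, tau = 120) {
  plain <- !inherits(series, "feature_series")
  if (plain) series <- feature_series(series)
  x <- series$values
  n <- nrow(x)
  if (n < 2L) stop("series must have at least 2 bins")
  if (tau <= 0) stop("`tau` must be positive")
  alpha <- exp(-series$bin_width / tau)
  eps <- 1e-6

  const_cols <- apply(x, 2L, function(v) max(v) == min(v))
  if (any(const_cols)) {
    warning(sprintf("%d constant feature(s) emitted as zeros", sum(const_cols)))
  }

  out <- matrix(0, n, ncol(x))
  for (f in seq_len(ncol(x))) {
    v <- x[, f]
    # running mean via the linear recursion mu_t = alpha mu_{t-1} + (1-alpha) x_t
    mu <- as.numeric(stats::filter((1 - alpha) * v, alpha,
                                   method = "recursive", init = v[1L]))
    mu_prev <- c(v[1L], mu[-n])
    dev <- v - mu_prev
    var_run <- as.numeric(stats::filter((1 - alpha) * dev^2, alpha,
                                        method = "recursive", init = 1))
    sd_prev <- sqrt(pmax(c(1, var_run[-n]), 0))
    out[, f] <- dev / pmax(sd_prev, eps)
  }
  out[, const_cols] <- 0

  res <- series
  res$values <- out
  res$burn_in <- min(n, as.integer(ceiling(tau / series$bin_width)))
  res
}

#' Temporally resample a spatiotemporal pattern
#'
#' Linearly interpolates each feature column of a T x F pattern onto
#' `new_length` uniformly spaced time points spanning the original support.
#' Used both to bring variable-duration target trajectories to a common
#' length before averaging, and to dilate/compress templates for the
#' replay timescale sweep.
#'
#' @param pattern Numeric matrix (time bins x features), T >= 2.
#' @param new_length Target number of bins, >= 2. `new_length == T` returns
#'   the input unchanged.
#'
#' @return A `new_length` x F numeric matrix.
#' @export
resample_pattern <- function(pattern, new_length) {
  pattern <- as.matrix(pattern)
  T0 <- nrow(pattern)
  if (T0 < 2L) stop("pattern must have at least 2 time bins")
  new_length <- as.integer(new_length)
  if (is.na(new_length) || new_length < 2L) {
    stop("`new_length` must be an integer >= 2")
  }
  if (new_length == T0) return(pattern)
  xout <- seq(1, T0, length.out = new_length)
  apply(pattern, 2L, function(col) approx(seq_len(T0), col, xout)$y)
}

#' Dilate a pattern by a multiplicative timescale factor
#'
#' @param pattern Numeric matrix (bins x features).
#' @param dilation Multiplicative factor applied to the native duration
#'   (e.g. 0.1 probes 10x time-compressed replay).
#' @return Resampled matrix of `max(2, round(T * dilation))` bins.
#' @export
dilate_pattern <- function(pattern, dilation) {
  if (dilation <= 0) stop("`dilation` must be positive")
  resample_pattern(pattern, max(2L, as.integer(round(nrow(pattern) * dilation))))
}
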