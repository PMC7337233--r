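#' Normalized 2D cross-correlation of a template against a rest block
#'
#' Slides a T x F spatiotemporal template along an N x F feature series and,
#' at each lag, computes the Pearson correlation between the flattened
#' template and the flattened T x F window starting at that lag (both
#' mean-subtracted over all T*F entries and normalized by their root sums of
#' squares). Lag l is the bin index of the window start; there are
#' `N - T + 1` valid lags. A window with zero variance yields CC = 0 (it
#' cannot match anything) rather than NaN, with a warning.
#'
#' Window means and norms are computed from prefix sums and the cross term
#' by a direct per-lag dot product in compiled code, so a full-length rest
#' block (tens of thousands of bins, 40 features) scans in well under a
#' second.
#'
#' @param template A [replay_template()] or bare T x F matrix (z-units).
#' @param rest A [feature_series()] or bare N x F matrix, N >= T.
#'
#' @return A `cc_series`: numeric vector of length `N - T + 1` in `[-1, 1]`,
#'   with attributes `template_length` and `burn_in` (burn-in lags are those
#'   whose window starts inside the rest series' normalization burn-in).
#' @export
normalized_xcorr <- function(template, rest) {
  tm <- if (inherits(template, "replay_template")) template$pattern else as.matrix(template)
  rm_ <- as_feature_matrix(rest)
  if (ncol(tm) != ncol(rm_)) {
    stop(sprintf("feature count mismatch: template has %d, rest has %d",
                 ncol(tm), ncol(rm_)))
  }
  if (nrow(rm_) < nrow(tm)) {
    stop("rest block is shorter than the template")
  }
  res <- cc_core(rm_, tm)
  if (res$n_zero_var > 0L) {
    warning(sprintf("%d zero-variance window(s) set to CC = 0", res$n_zero_var))
  }
  structure(res$cc,
            template_length = nrow(tm),
            burn_in = min(series_burn_in(rest), length(res$cc)),
            class = "cc_series")
}

#' Pooled centile threshold over both rest blocks
#'
#' Candidate replay events are CC peaks above a centile of the template's own
#' CC distribution. The threshold is taken over the pooled CC values of Rest1
#' and Rest2 (burn-in lags excluded) so that the peak-selection criterion is
#' identical in both blocks and the Replay Index reflects CC magnitude
#' differences rather than threshold differences. Linear-interpolation
#' percentile convention (R type 7).
#'
#' @param cc_rest1,cc_rest2 `cc_series` from [normalized_xcorr()] for the
#'   same template against Rest1 and Rest2.
#' @param centile Percentile in (0, 100].
#'
#' @return The pooled CC threshold (scalar).
#' @export
centile_threshold <- function(cc_rest1, cc_rest2, centile = 95) {
  if (centile <= 0 || centile > 100) stop("`centile` must be in (0, 100]")
  drop_burnin <- function(cc) {
    b <- attr(cc, "burn_in") %||% 0L
    if (b > 0L) cc[-seq_len(min(b, length(cc)))] else as.numeric(cc)
  }
  pooled <- c(drop_burnin(cc_rest1), drop_burnin(cc_rest2))
  if (length(pooled) == 0L) stop("no CC values left after burn-in exclusion")
  quantile(pooled, centile / 100, type = 7, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract non-overlapping CC peaks by non-maximum suppression
#'
#' Candidates are strict local maxima of the CC series above `threshold`
#' (the leftmost bin of a maximal plateau; a boundary bin qualifies when it
#' exceeds its single neighbor). Candidates are then accepted greedily in
#' descending CC order (ties broken toward the earlier lag); a candidate is
#' suppressed if its lag lies within `window - 1` bins of an already accepted
#' lag. With `window` equal to the template length this enforces 0% overlap
#' between accepted template spans: at most one peak per template length,
#' spans separated by exactly the template length are allowed.
#'
#' @param cc A `cc_series` (or numeric vector) of correlation values.
#' @param threshold CC threshold; only candidates strictly above it survive.
#' @param window Suppression window in bins (normally the template length).
#'
#' @return A tibble with columns `lag` (bin index of window start) and `cc`,
#'   sorted by lag, with attributes `threshold` and `window`. May be empty.
#' @export
extract_peaks <- function(cc, threshold, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be >= 1")
  v <- as.numeric(cc)
  cand <- local_maxima(v)
  cand <- cand[v[cand] > threshold]
  acc <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-v[cand], cand)]
    for (l in ord) {
      if (!length(acc) || all(abs(acc - l) >= window)) acc <- c(acc, l)
    }
    acc <- sort(acc)
  }
  structure(
    tibble(lag = acc, cc = v[acc]),
    threshold = threshold, window = window
  )
}

# strict local maxima; a maximal plateau contributes its leftmost bin;
# boundary runs qualify when they exceed their single inner neighbor
local_maxima <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  r <- rle(v)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  up <- c(TRUE, diff(r$values) > 0)     # run higher than previous run
  down <- c(diff(r$values) < 0, TRUE)   # run higher than next run
  starts[up & down]
}
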