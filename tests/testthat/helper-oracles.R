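# Independent brute-force oracles. These deliberately share no code with the
# implementation: naive loops, stats::cor, full sorts.

# per-lag Pearson correlation of flattened template vs flattened window
oracle_xcorr <- function(tmpl, rest) {
  T0 <- nrow(tmpl)
  n_lags <- nrow(rest) - T0 + 1
  vapply(seq_len(n_lags), function(l) {
    win <- rest[l:(l + T0 - 1), , drop = FALSE]
    if (stats::sd(as.numeric(win)) == 0) return(0)
    stats::cor(as.numeric(win), as.numeric(tmpl))
  }, numeric(1))
}

# greedy non-maximum suppression that rescans all remaining candidates
# after each acceptance
oracle_nms <- function(v, threshold, window) {
  n <- length(v)
  cand <- which(vapply(seq_len(n), function(i) {
    v[i] > threshold &&
      (i == 1 || v[i] > v[i - 1]) &&
      (i == n || v[i] > v[i + 1])
  }, logical(1)))
  acc <- integer(0)
  while (length(cand)) {
    best <- cand[order(-v[cand], cand)][1]
    acc <- c(acc, best)
    cand <- cand[abs(cand - best) >= window]
  }
  sort(acc)
}

# linear-interpolation percentile computed from the sorted sample
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# exhaustive sliding-window scan for sequence hits
oracle_hits <- function(labels, ord) {
  n <- length(labels)
  if (n < 4) return(0L)
  sum(vapply(seq_len(n - 3), function(i) {
    all(labels[i:(i + 3)] == ord)
  }, logical(1)))
}

# brute-force control-ordering enumeration over all 24 permutations
oracle_control_orders <- function(rep_ord) {
  g <- expand.grid(a = rep_ord, b = rep_ord, c = rep_ord, d = rep_ord)
  g <- g[apply(g, 1, function(r) length(unique(r)) == 4), ]
  banned <- paste(rep_ord[-4], rep_ord[-1])
  ok <- apply(g, 1, function(r) {
    !any(paste(r[-4], r[-1]) %in% banned)
  })
  m <- as.matrix(g[ok, ])
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}
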