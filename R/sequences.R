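#' Enumerate control orderings sharing no transition with a repeated sequence
#'
#' The sequence game presents one "repeated" 4-target ordering many times,
#' interleaved with "control" orderings chosen so that no control contains any
#' of the repeated ordering's three target-to-target transitions. For any
#' repeated ordering of 4 distinct targets, exactly 11 of the 24 permutations
#' satisfy this constraint; they serve as the veridical within-task null for
#' the replay statistics.
#'
#' @param repeated_order Integer vector: a permutation of 4 distinct target
#'   IDs, e.g. `c(1, 2, 3, 4)`.
#'
#' @return An 11 x 4 integer matrix, one control ordering per row, sorted
#'   lexicographically.
#' @export
#'
#' @examples
#' enumerate_control_sequences(c(1, 2, 3, 4))
enumerate_control_sequences <- function(repeated_order) {
  repeated_order <- as.integer(repeated_order)
  if (length(repeated_order) != 4L || anyNA(repeated_order) ||
      length(unique(repeated_order)) != 4L) {
    stop("`repeated_order` must be a permutation of 4 distinct target IDs")
  }
  transitions <- function(p) paste(p[-length(p)], p[-1L], sep = ">")
  banned <- transitions(repeated_order)
  cand <- permutations_of(sort(repeated_order))
  kept <- Filter(function(p) !any(transitions(p) %in% banned), cand)
  key <- vapply(kept, function(p) paste(sprintf("%06d", p), collapse = ""),
                character(1L))
  do.call(rbind, kept[order(key)])
}

# all permutations of a vector (n! small; only ever called with n = 4)
permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}
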