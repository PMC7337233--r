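#' Write a synthetic session to a directory of plain-text files
#'
#' Layout: `task.tsv`, `rest1.tsv`, `rest2.tsv` (one row per 20 ms bin, one
#' column per feature, no header), `trials.tsv` (trial annotations),
#' `lfp_task.tsv`, `lfp1.tsv`, `lfp2.tsv` (1 kHz, single column),
#' `truth.json` (embedded events + true state schedule, run-length encoded)
#' and `meta.json` (bin width, feature count, seed, config echo).
#'
#' @param session A `replay_session` from [synthesize_session()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "replay_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wmat <- function(m, f) {
    readr::write_tsv(as.data.frame(m), file.path(dir, f), col_names = FALSE,
                     progress = FALSE)
  }
  wmat(session$task$values, "task.tsv")
  wmat(session$rest1$values, "rest1.tsv")
  wmat(session$rest2$values, "rest2.tsv")
  readr::write_tsv(session$trials, file.path(dir, "trials.tsv"), progress = FALSE)
  wmat(matrix(session$lfp_task, ncol = 1L), "lfp_task.tsv")
  wmat(matrix(session$lfp1, ncol = 1L), "lfp1.tsv")
  wmat(matrix(session$lfp2, ncol = 1L), "lfp2.tsv")
  jsonlite::write_json(
    list(events = session$truth,
         states1 = rle_encode(session$states1),
         states2 = rle_encode(session$states2)),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE
  )
  jsonlite::write_json(
    list(bin_width = session$config$bin_width,
         n_features = session$config$n_features,
         seed = session$config$seed,
         repeated_order = session$repeated_order,
         config = unclass(session$config)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory path.
#' @return A `replay_session`.
#' @export
read_session <- function(dir) {
  need <- c("task.tsv", "rest1.tsv", "rest2.tsv", "trials.tsv",
            "lfp_task.tsv", "lfp1.tsv", "lfp2.tsv", "truth.json", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop(sprintf("session directory %s is missing: %s", dir,
                 paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- do.call(synth_config, meta$config[setdiff(names(meta$config), NULL)])
  rmat <- function(f) {
    as.matrix(readr::read_tsv(file.path(dir, f), col_names = FALSE,
                              col_types = readr::cols(.default = "d"),
                              progress = FALSE))
  }
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  truth <- as_tibble(truth_raw$events)
  bw <- meta$bin_width
  structure(
    list(config = cfg,
         repeated_order = as.integer(meta$repeated_order),
         control_orders = enumerate_control_sequences(as.integer(meta$repeated_order)),
         trials = readr::read_tsv(file.path(dir, "trials.tsv"),
                                  col_types = readr::cols(
                                    kind = "c", order = "c", success = "l",
                                    .default = "i"),
                                  progress = FALSE),
         task = feature_series(rmat("task.tsv"), bw, "task"),
         rest1 = feature_series(rmat("rest1.tsv"), bw, "Rest1"),
         rest2 = feature_series(rmat("rest2.tsv"), bw, "Rest2"),
         lfp_task = rmat("lfp_task.tsv")[, 1L],
         lfp1 = rmat("lfp1.tsv")[, 1L],
         lfp2 = rmat("lfp2.tsv")[, 1L],
         states1 = rle_decode(truth_raw$states1),
         states2 = rle_decode(truth_raw$states2),
         truth = truth),
    class = "replay_session"
  )
}

rle_encode <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  tibble(label = r$values, start = ends - r$lengths + 1L, end = ends)
}

rle_decode <- function(df) {
  out <- character(max(df$end))
  for (i in seq_len(nrow(df))) out[df$start[i]:df$end[i]] <- df$label[i]
  out
}
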