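# Plain-text serialization of trial datasets: one long-format CSV of traces
# plus a JSON sidecar of per-trial metadata.

#' Write a set of trials to disk
#'
#' Traces go to `<stem>_traces.csv` in long format (`participant`, `trial`,
#' `time_ms`, `force_n`, `orientation_deg`); metadata to `<stem>_meta.json`.
#'
#' @param trials list of `trial_record`s.
#' @param stem output path stem (no extension).
#' @return the two paths, invisibly.
#' @export
write_trials <- function(trials, stem) {
  traces <- dplyr::bind_rows(lapply(trials, function(tr) {
    tibble::tibble(
      participant = tr$meta$participant %||% NA_integer_,
      trial = tr$meta$trial %||% NA_integer_,
      time_ms = tr$time, force_n = tr$force, orientation_deg = tr$orientation)
  }))
  meta <- lapply(trials, function(tr) tr$meta)
  p1 <- paste0(stem, "_traces.csv")
  p2 <- paste0(stem, "_meta.json")
  utils::write.csv(traces, p1, row.names = FALSE)
  jsonlite::write_json(meta, p2, digits = NA, auto_unbox = TRUE)
  invisible(c(p1, p2))
}

#' Read trials written by [write_trials()]
#'
#' Validates the uniform 1 kHz grid of every trial.
#'
#' @param stem path stem used when writing.
#' @return list of `trial_record`s.
#' @export
read_trials <- function(stem) {
  traces <- utils::read.csv(paste0(stem, "_traces.csv"))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = FALSE)
  key <- paste(traces$participant, traces$trial)
  split_idx <- split(seq_len(nrow(traces)), factor(key, levels = unique(key)))
  if (length(split_idx) != length(meta))
    stop("read_trials: metadata and trace trial counts differ")
  Map(function(idx, m) {
    # JSON reads Inf as the string "Inf" when boxed; normalize numerics
    m$edge_length <- as.numeric(m$edge_length)
    trial_record(traces$time_ms[idx], traces$force_n[idx],
                 traces$orientation_deg[idx], m)
  }, split_idx, meta)
}
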