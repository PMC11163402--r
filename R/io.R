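# Readers and writers for the pipeline's delimited-text interfaces.

#' Read a parcel time-series file
#'
#' Tab-separated, T rows by R columns, with a header row of ROI ids.
#'
#' @param path file path.
#' @param ... unit labels and TR, passed to [roi_timeseries()].
#' @return a [roi_timeseries()].
#' @export
read_timeseries <- function(path, ...) {
  d <- utils::read.delim(path, check.names = FALSE)
  roi_timeseries(as.matrix(d), ...)
}

#' Read a BIDS-style events file
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`
#' (seconds).
#'
#' @param path file path.
#' @return an [event_table()].
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(d))) {
    stop_fc(path, " must have columns ", paste(need, collapse = ", "))
  }
  event_table(d$onset, d$duration, d$trial_type)
}

#' Read a study manifest
#'
#' Comma-separated with columns `subject_id`, `session`, `task`, `path`,
#' `diagnosis`, `sex`, `responder` (and optionally `site`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
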