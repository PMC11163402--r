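# Time-series preparation: parcel extraction, FIR task regression,
# demeaning, and run concatenation. All operations are deterministic.

#' Average voxel time courses into parcels
#'
#' Each parcel's time course is the unweighted mean over its voxels at
#' each time point; parcels are ordered by ascending parcel id.
#'
#' @param voxel_data numeric T x V matrix (time x voxels).
#' @param labels per-voxel parcel id, length V.
#' @param parcel_ids optional vector of expected parcel ids; any id with
#'   no voxels raises an error naming it. Defaults to the ids present.
#' @param ... passed to [roi_timeseries()] (unit labels, TR).
#' @return a [roi_timeseries()] with one column per parcel.
#' @export
extract_parcel_timeseries <- function(voxel_data, labels, parcel_ids = NULL,
                                      ...) {
  voxel_data <- as.matrix(voxel_data)
  if (length(labels) != ncol(voxel_data)) {
    stop_fc("labels length (", length(labels),
            ") must equal the number of voxels (", ncol(voxel_data), ")")
  }
  ids <- sort(unique(parcel_ids %||% labels))
  counts <- vapply(ids, function(id) sum(labels == id), integer(1))
  if (any(counts == 0)) {
    stop_fc("empty parcel(s): ", paste(ids[counts == 0], collapse = ", "))
  }
  out <- vapply(ids, function(id) {
    rowMeans(voxel_data[, labels == id, drop = FALSE])
  }, numeric(nrow(voxel_data)))
  colnames(out) <- as.character(ids)
  roi_timeseries(out, ...)
}

#' Filter out parcels with too few voxels
#'
#' Keeps parcels whose voxel count is at least `min_voxels`; parcels with
#' strictly fewer voxels are excluded.
#'
#' @param parcel_sizes named vector, parcel id -> voxel count.
#' @param min_voxels minimum size, >= 1.
#' @return the kept parcel ids (names of `parcel_sizes`).
#' @export
#' @examples
#' filter_small_parcels(c(a = 7, b = 8, c = 9), min_voxels = 8)
filter_small_parcels <- function(parcel_sizes, min_voxels) {
  if (min_voxels < 1) stop_fc("min_voxels must be >= 1")
  if (is.null(names(parcel_sizes))) stop_fc("parcel_sizes must be named")
  names(parcel_sizes)[parcel_sizes >= min_voxels]
}

#' Construct an event table
#'
#' @param onset event onsets in seconds, non-negative and non-decreasing.
#' @param duration event durations in seconds, non-negative.
#' @param trial_type event-type labels.
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(onset, duration, trial_type) {
  if (any(onset < 0)) stop_fc("event onsets must be >= 0")
  if (is.unsorted(onset)) stop_fc("event onsets must be non-decreasing")
  if (any(duration < 0)) stop_fc("event durations must be >= 0")
  structure(data.frame(onset = onset, duration = duration,
                       trial_type = as.character(trial_type),
                       stringsAsFactors = FALSE),
            class = c("event_table", "data.frame"))
}

#' Build a finite-impulse-response task design matrix
#'
#' For each event of type k with onset sample o = floor(onset / TR)
#' (0-based), the lag-l column of type k is set to 1 at row o + l for
#' l = 0, ..., L-1, truncated at the run end. One block of L columns per
#' declared event type; L around 10 samples (~20 s at TR = 2 s) leaves the
#' haemodynamic response shape unconstrained per event type. Event
#' durations are not used: block/trial extent is absorbed by the lag
#' window.
#'
#' @param events an [event_table()] (or data.frame with `onset`,
#'   `duration`, `trial_type`).
#' @param n_timepoints run length in samples.
#' @param tr_seconds sampling interval.
#' @param lag_samples FIR window length L in samples, >= 1.
#' @param trial_types declared event-type list (column-block order). When
#'   given, events with types outside the list raise an error. Defaults
#'   to the sorted types present.
#' @return T x (K*L) 0/1 matrix with `dimnames` `type.lagNN` and attribute
#'   `labels` (data.frame of type/lag per column).
#' @export
#' @examples
#' ev <- event_table(onset = 10, duration = 2, trial_type = "go")
#' d <- build_fir_design(ev, n_timepoints = 12, tr_seconds = 2,
#'                       lag_samples = 3)
#' which(d[, 1] == 1)  # onset sample 5 (0-based) -> row 6
build_fir_design <- function(events, n_timepoints, tr_seconds,
                             lag_samples = 10, trial_types = NULL) {
  if (lag_samples < 1) stop_fc("lag_samples must be >= 1")
  events <- as.data.frame(events)
  types <- trial_types %||% sort(unique(events$trial_type))
  unknown <- setdiff(events$trial_type, types)
  if (length(unknown)) {
    stop_fc("event type(s) not in declared list: ",
            paste(unique(unknown), collapse = ", "))
  }
  onset_sample <- floor(events$onset / tr_seconds)  # 0-based
  if (any(onset_sample >= n_timepoints)) {
    stop_fc("event onset(s) beyond the end of the run (",
            n_timepoints, " samples)")
  }
  K <- length(types)
  L <- as.integer(lag_samples)
  X <- matrix(0, nrow = n_timepoints, ncol = K * L)
  labels <- data.frame(
    type = rep(types, each = L),
    lag = rep(seq_len(L) - 1L, times = K),
    stringsAsFactors = FALSE
  )
  colnames(X) <- paste0(labels$type, ".lag", sprintf("%02d", labels$lag))
  for (e in seq_len(nrow(events))) {
    k <- match(events$trial_type[e], types)
    for (l in seq_len(L) - 1L) {
      row <- onset_sample[e] + l + 1L  # to 1-based row index
      if (row <= n_timepoints) X[row, (k - 1L) * L + l + 1L] <- 1
    }
  }
  attr(X, "labels") <- labels
  X
}

#' Regress task-evoked activity out of ROI time series
#'
#' Ordinary least-squares residuals of every ROI column on the FIR design.
#' Collinearity is handled by dropping rank-deficient design columns,
#' identified with a pivoted orthogonal (QR) decomposition at relative
#' tolerance 1e-8; the dropped column names are recorded in the
#' `dropped_columns` attribute of the result. No intercept is added --
#' demeaning is a separate, explicit step ([demean_timeseries()]).
#'
#' @param ts a [roi_timeseries()].
#' @param design design matrix with `nrow(design) == T`.
#' @return a [roi_timeseries()] of residuals, with attribute
#'   `dropped_columns`.
#' @export
regress_out_task <- function(ts, design) {
  stopifnot(inherits(ts, "roi_timeseries"))
  design <- as.matrix(design)
  if (nrow(design) != nrow(ts$data)) {
    stop_fc("design has ", nrow(design), " rows but the series has ",
            nrow(ts$data), " time points")
  }
  if (is.null(colnames(design))) {
    colnames(design) <- sprintf("x%03d", seq_len(ncol(design)))
  }
  dec <- qr(design, tol = 1e-8)
  rank <- dec$rank
  dropped <- if (rank < ncol(design)) {
    colnames(design)[dec$pivot[(rank + 1L):ncol(design)]]
  } else {
    character(0)
  }
  if (rank == 0) {
    out <- ts
  } else {
    if (rank >= nrow(design)) {
      stop_fc("design retains ", rank, " independent columns for only ",
              nrow(design), " rows; residuals would be degenerate")
    }
    kept <- qr(design[, dec$pivot[seq_len(rank)], drop = FALSE])
    res <- qr.resid(kept, ts$data)
    colnames(res) <- colnames(ts$data)
    out <- roi_timeseries(res, ts$subject_id, ts$session, ts$task,
                          ts$tr_seconds)
  }
  attr(out, "dropped_columns") <- dropped
  out
}

#' Remove each ROI's mean signal level
#'
#' @param ts a [roi_timeseries()].
#' @return the series with every ROI column centered at mean zero.
#' @export
demean_timeseries <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  d <- scale(ts$data, center = TRUE, scale = FALSE)
  attr(d, "scaled:center") <- NULL
  colnames(d) <- colnames(ts$data)
  roi_timeseries(d, ts$subject_id, ts$session, ts$task, ts$tr_seconds)
}

#' Concatenate a session's runs into one series
#'
#' Row-wise concatenation of the runs of one participant-session in a
#' fixed task order (default rest, go/no-go, anhedonia; runs with other
#' labels keep their input order after these). All runs must share the
#' ROI set and ordering, participant and session.
#'
#' @param runs list of [roi_timeseries()] for one participant-session.
#' @param task_order preferred task order for the concatenation.
#' @return a single [roi_timeseries()] with `task = "pooled"`.
#' @export
concatenate_runs <- function(runs,
                             task_order = c("rest", "gonogo", "anhedonia")) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, logical(1),
                                          "roi_timeseries")))
  first <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(colnames(r$data), colnames(first$data))) {
      stop_fc("runs differ in ROI set or ordering")
    }
    if (!identical(r$subject_id, first$subject_id) ||
        !identical(r$session, first$session)) {
      stop_fc("runs belong to different participants or sessions")
    }
    if (!identical(r$tr_seconds, first$tr_seconds)) {
      stop_fc("runs differ in TR")
    }
  }
  tasks <- vapply(runs, function(r) r$task, character(1))
  ord <- order(match(tasks, task_order, nomatch = length(task_order) + 1L),
               seq_along(runs))
  data <- do.call(rbind, lapply(runs[ord], function(r) r$data))
  roi_timeseries(data, first$subject_id, first$session, "pooled",
                 first$tr_seconds)
}
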