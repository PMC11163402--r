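# Split-half reliability of FC as a function of data amount, from ~2.5
# minute epochs pseudorandomly mixed across tasks and session halves.

#' Split one participant's runs into two disjoint segment pools
#'
#' Each run is cut into non-overlapping whole segments of 150 s
#' (`floor(150 / TR)` samples, 75 at TR = 2 s); trailing remainder
#' samples are discarded. Segments are split between a reference pool and
#' a test pool, as evenly as possible within each run, under the
#' constraint that both pools contain at least one segment from every
#' task and from both temporal halves (first / second) of the recordings.
#' The split is pseudorandom and reproducible under `seed`.
#'
#' @param runs named list of [roi_timeseries()] for one participant (all
#'   sessions and tasks).
#' @param tr_seconds sampling interval.
#' @param seed integer seed.
#' @param segment_seconds epoch length (default 150 s, i.e. ~2.5 min).
#' @return list of class `segment_pools` with `reference` and `test`
#'   data.frames (`run`, `session`, `task`, `half`, `start`, `length`)
#'   and `segment_samples`.
#' @export
make_segments <- function(runs, tr_seconds = 2, seed = 1L,
                          segment_seconds = 150) {
  seg_len <- floor(segment_seconds / tr_seconds)
  segs <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    n_seg <- floor(nrow(r$data) / seg_len)
    if (n_seg < 2) {
      stop_fc("run ", names(runs)[i] %||% i, " has only ", n_seg,
              " whole segment(s); need at least 2 per run")
    }
    idx <- seq_len(n_seg)
    data.frame(run = i, session = r$session, task = r$task,
               half = ifelse(idx <= n_seg / 2, "first", "second"),
               start = (idx - 1L) * seg_len + 1L, length = seg_len,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)

  ok_pools <- function(assign) {
    all(vapply(c("reference", "test"), function(p) {
      s <- segs[assign == p, ]
      nrow(s) > 0 &&
        setequal(unique(s$task), unique(segs$task)) &&
        setequal(unique(s$half), c("first", "second"))
    }, logical(1)))
  }
  assign <- with_seed(seed, {
    a <- NULL
    for (try in 1:100) {
      cand <- character(nrow(segs))
      counts <- c(reference = 0L, test = 0L)
      for (ix in split(seq_len(nrow(segs)), segs$run)) {
        # split the run as evenly as possible; an odd segment goes to
        # whichever pool is currently smaller so the pools stay balanced
        half <- length(ix) %/% 2L
        lab <- c(rep(c("reference", "test"), half),
                 if (length(ix) %% 2L) names(counts)[which.min(counts)])
        cand[ix] <- sample(lab)
        counts <- counts + table(factor(lab, names(counts)))
      }
      if (ok_pools(cand)) {
        a <- cand
        break
      }
    }
    a
  })
  if (is.null(assign)) {
    stop_fc("could not build balanced segment pools ",
            "(insufficient data across tasks/halves)")
  }
  structure(list(reference = segs[assign == "reference", ],
                 test = segs[assign == "test", ],
                 segment_samples = seg_len),
            class = "segment_pools")
}

# concatenate the rows of the selected segments into one data matrix
segment_data <- function(pool_rows, runs) {
  do.call(rbind, lapply(seq_len(nrow(pool_rows)), function(i) {
    r <- runs[[pool_rows$run[i]]]
    r$data[pool_rows$start[i] + seq_len(pool_rows$length[i]) - 1L, ,
           drop = FALSE]
  }))
}

#' Split-half reliability curve for one participant
#'
#' The reference FC is computed from the full reference pool; for each
#' target length, FC is computed from that many test-pool segments
#' (segments taken in a seeded random order, nested so longer estimates
#' extend shorter ones) and correlated (Pearson) with the reference FC
#' vector.
#'
#' @param pools from [make_segments()].
#' @param runs the same named list of runs.
#' @param grid_minutes increasing target lengths in minutes; each must be
#'   a multiple of the segment length covered by the test pool.
#' @param seed integer seed for the test-segment order.
#' @param tr_seconds sampling interval.
#' @return data.frame with `minutes` and `r`.
#' @export
split_half_curve <- function(pools, runs, grid_minutes = seq(5, 35, by = 5),
                             seed = 1L, tr_seconds = 2) {
  stopifnot(inherits(pools, "segment_pools"))
  if (is.unsorted(grid_minutes, strictly = TRUE)) {
    stop_fc("grid_minutes must be strictly increasing")
  }
  seg_min <- pools$segment_samples * tr_seconds / 60
  k_needed <- round(grid_minutes / seg_min)
  if (max(k_needed) > nrow(pools$test)) {
    stop_fc("grid length ", max(grid_minutes), " min needs ",
            max(k_needed), " segments but the test pool has ",
            nrow(pools$test))
  }
  ref_fc <- vectorize_upper(compute_fc(roi_timeseries(
    segment_data(pools$reference, runs), tr_seconds = tr_seconds)))
  test_order <- with_seed(seed, sample(nrow(pools$test)))
  r <- vapply(k_needed, function(k) {
    rows <- pools$test[test_order[seq_len(k)], , drop = FALSE]
    fc <- vectorize_upper(compute_fc(roi_timeseries(
      segment_data(rows, runs), tr_seconds = tr_seconds)))
    stats::cor(ref_fc$z, fc$z)
  }, numeric(1))
  data.frame(minutes = grid_minutes, r = r)
}

#' Reliability curves across the participants of a dataset
#'
#' Runs [make_segments()] and [split_half_curve()] for every participant
#' in the requested sample (controls by default: patients' connectivity is
#' expected to change with treatment, which would depress a reliability
#' estimate).
#'
#' @param dataset a `timeseries_dataset` (or list with `runs` +
#'   `manifest` in the same layout).
#' @param grid_minutes target lengths in minutes.
#' @param seed integer seed; each participant uses a derived seed.
#' @param sample `"controls"`, `"patients"`, or `"all"`.
#' @return list with `curves` (long data.frame: `subject_id`, `minutes`,
#'   `r`) and `mean_curve` (`minutes`, `mean_r`).
#' @export
reliability_curve <- function(dataset, grid_minutes = seq(5, 35, by = 5),
                              seed = 1L, sample = "controls") {
  manifest <- dataset$manifest
  keep <- switch(sample,
                 controls = manifest$diagnosis == "control",
                 patients = manifest$diagnosis == "MD",
                 all = rep(TRUE, nrow(manifest)))
  subjects <- unique(manifest$subject_id[keep])
  if (!length(subjects)) stop_fc("no participants in sample '", sample, "'")
  tr <- dataset$runs[[1]]$tr_seconds
  curves <- lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    runs <- dataset$runs[manifest$subject_id == s]
    pools <- make_segments(runs, tr_seconds = tr, seed = seed + 7L * i)
    cv <- split_half_curve(pools, runs, grid_minutes,
                           seed = seed + 7L * i + 1L, tr_seconds = tr)
    cbind(subject_id = s, cv, stringsAsFactors = FALSE)
  })
  curves <- do.call(rbind, curves)
  mean_curve <- stats::aggregate(r ~ minutes, curves, mean)
  names(mean_curve)[2] <- "mean_r"
  list(curves = curves, mean_curve = mean_curve)
}
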