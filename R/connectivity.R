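# Fisher-z functional connectivity per analysis unit.

#' Construct an ROI time-series object
#'
#' @param data numeric T x R matrix (time points x regions); column names
#'   are ROI ids (generated if absent).
#' @param subject_id,session,task unit labels.
#' @param tr_seconds sampling interval.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, subject_id = NA_character_,
                           session = NA_character_, task = NA_character_,
                           tr_seconds = 2) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop_fc("time series needs at least 2 time points")
  if (ncol(data) < 1) stop_fc("time series needs at least 1 ROI")
  if (!all(is.finite(data))) stop_fc("time series contains non-finite values")
  if (is.null(colnames(data))) colnames(data) <- sprintf("roi%03d", seq_len(ncol(data)))
  structure(list(data = data, subject_id = subject_id, session = session,
                 task = task, tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series:", x$subject_id, "/", x$session, "/", x$task, "-",
      nrow(x$data), "samples x", ncol(x$data), "ROIs, TR =",
      x$tr_seconds, "s\n")
  invisible(x)
}

#' Compute a Fisher-z connectivity matrix
#'
#' Pairwise Pearson product-moment correlations between ROI time courses,
#' Fisher z-transformed with the correlation clipped to
#' +/- (1 - 1e-7) (see [fisher_z()]). The diagonal is undefined and stored
#' as `NA`; it is excluded from all downstream use.
#'
#' @param ts a [roi_timeseries()] (or a bare T x R matrix).
#' @return object of class `fc_matrix`: list with `z` (R x R symmetric
#'   matrix, `NA` diagonal) and `meta` (subject/session/task labels).
#' @export
#' @examples
#' set.seed(1)
#' ts <- roi_timeseries(matrix(rnorm(200), 50, 4))
#' fc <- compute_fc(ts)
#' fc$z[1, 2] == fc$z[2, 1]
compute_fc <- function(ts) {
  if (is.matrix(ts)) ts <- roi_timeseries(ts)
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  if (nrow(x) < 3) stop_fc("need at least 3 time points to estimate FC")
  if (ncol(x) < 3) stop_fc("need at least 3 ROIs to estimate FC")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop_fc("zero-variance ROI(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
  }
  z <- fisher_z(stats::cor(x))
  diag(z) <- NA_real_
  structure(list(z = z,
                 meta = list(subject_id = ts$subject_id, session = ts$session,
                             task = ts$task)),
            class = "fc_matrix")
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Returns the P = R(R-1)/2 off-diagonal values in row-major upper-triangle
#' order: (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R). The ordering is a
#' convention; it round-trips losslessly with [matrix_from_fc_vector()].
#'
#' @param fc an `fc_matrix` from [compute_fc()] (or a bare symmetric matrix).
#' @return object of class `fc_vector`: list with `z` (length P numeric),
#'   `n_rois`, and `meta`.
#' @export
vectorize_upper <- function(fc) {
  if (is.matrix(fc)) fc <- structure(list(z = fc, meta = list()), class = "fc_matrix")
  stopifnot(inherits(fc, "fc_matrix"))
  m <- fc$z
  v <- t(m)[lower.tri(m)]  # row-major traversal of the upper triangle
  structure(list(z = v, n_rois = ncol(m), meta = fc$meta),
            class = "fc_vector")
}

#' Rebuild a symmetric matrix from an upper-triangle FC vector
#'
#' @param v an `fc_vector` (or bare numeric of length R(R-1)/2).
#' @param n_rois required when `v` is a bare numeric.
#' @return symmetric R x R matrix with `NA` diagonal.
#' @export
matrix_from_fc_vector <- function(v, n_rois = NULL) {
  if (inherits(v, "fc_vector")) {
    n_rois <- v$n_rois
    v <- v$z
  }
  if (is.null(n_rois)) stop_fc("n_rois required for a bare vector")
  if (length(v) != n_pairs(n_rois)) {
    stop_fc("vector length ", length(v), " does not match n_rois = ", n_rois)
  }
  m <- matrix(NA_real_, n_rois, n_rois)
  m[lower.tri(m)] <- v   # row-major upper triangle == column-major lower
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Connectivity profile of a single region
#'
#' The region's connectivity with every other region, in ascending partner
#' order, self-connection excluded. These length R-1 profiles feed the
#' per-region localization analysis.
#'
#' @param fc an `fc_matrix`.
#' @param roi_index region index in 1..R.
#' @return numeric vector of length R-1.
#' @export
roi_profile <- function(fc, roi_index) {
  stopifnot(inherits(fc, "fc_matrix"))
  R <- ncol(fc$z)
  if (roi_index < 1 || roi_index > R) {
    stop_fc("roi_index ", roi_index, " out of range 1..", R)
  }
  fc$z[roi_index, -roi_index]
}
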