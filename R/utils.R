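#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Fisher z-transformation with clipping
#'
#' Correlations are clipped to +/- (1 - 1e-7) before `atanh` so that exact
#' unit correlations (e.g. a unit with itself, or duplicated series) map to
#' a large finite value instead of infinity, which would poison downstream
#' averages.
#'
#' @param r correlation value(s).
#' @param clip clipping bound, strictly below 1.
#' @return Fisher z value(s), `atanh` of the clipped correlations.
#' @export
#' @examples
#' fisher_z(c(0, 0.5, 1))
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Maximum representable Fisher z under the default clipping
#' @return `atanh(1 - 1e-7)`.
#' @export
z_clip <- function() atanh(1 - 1e-7)

# Upper-triangle (i < j) index pairs in row-major order:
# (1,2),(1,3),...,(1,R),(2,3),...,(R-1,R).
upper_pairs <- function(n_rois) {
  stopifnot(n_rois >= 2)
  i <- rep.int(seq_len(n_rois - 1L), times = (n_rois - 1L):1L)
  j <- unlist(lapply(seq_len(n_rois - 1L), function(k) (k + 1L):n_rois))
  cbind(i = i, j = j)
}

# number of distinct ROI pairs
n_pairs <- function(n_rois) as.integer(n_rois * (n_rois - 1L) / 2L)

stop_fc <- function(...) stop(..., call. = FALSE)
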