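# The decomposition core: similarity matrix, effect masks, mask averages,
# and normalized relative effect magnitudes.

#' Restrict unit metadata to an analysis sample
#'
#' @param meta unit metadata (see [make_unit_metadata()]).
#' @param sample `"all"`, `"controls"`, or `"patients"`.
#' @return the matching metadata rows.
#' @export
subset_sample <- function(meta, sample = c("all", "controls", "patients")) {
  sample <- match.arg(sample)
  keep <- switch(sample,
                 all = rep(TRUE, nrow(meta)),
                 controls = meta$diagnosis == "control",
                 patients = meta$diagnosis == "MD")
  meta[keep, , drop = FALSE]
}

#' Build the unit-by-unit similarity matrix
#'
#' Entry (u, v) is the Fisher z of the Pearson correlation between the two
#' units' whole-brain FC vectors (clipped before `atanh`). The diagonal --
#' each unit with itself, all ones by definition -- is stored as `NA` and
#' excluded from every downstream average.
#'
#' @param x an `fc_dataset` (list with `vectors` P x N matrix and `meta`),
#'   or a list of `fc_vector` objects.
#' @param meta unit metadata, required when `x` is a bare matrix.
#' @return object of class `similarity_matrix`: list with `z` (N x N) and
#'   `meta`.
#' @export
build_similarity_matrix <- function(x, meta = NULL) {
  if (inherits(x, "fc_dataset")) {
    V <- x$vectors
    meta <- x$meta
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "fc_vector"))) {
    V <- vapply(x, function(v) v$z, numeric(length(x[[1]]$z)))
    if (is.null(meta)) {
      meta <- do.call(rbind, lapply(x, function(v) {
        as.data.frame(v$meta[c("subject_id", "session", "task")],
                      stringsAsFactors = FALSE)
      }))
    }
  } else if (is.matrix(x)) {
    V <- x
    if (is.null(meta)) stop_fc("meta is required with a bare vector matrix")
  } else {
    stop_fc("cannot interpret input as a collection of FC vectors")
  }
  if (ncol(V) < 2) stop_fc("need at least 2 units")
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(V)[sds == 0] %||% which(sds == 0)
    stop_fc("zero-variance FC vector for unit(s): ",
            paste(bad, collapse = ", "))
  }
  z <- fisher_z(stats::cor(V))
  diag(z) <- NA_real_
  structure(list(z = z, meta = meta), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Similarity matrix:", ncol(x$z), "units (",
      length(unique(x$meta$subject_id)), "participants )\n")
  invisible(x)
}

# canonical effect names for each sample x mode analysis
effects_for <- function(sample, mode) {
  group <- switch(sample, all = "diagnosis", patients = "response",
                  controls = NULL)
  eff <- "common"
  if (!is.null(group)) eff <- c(eff, group)
  eff <- c(eff, "session", "sex")
  if (!is.null(group)) {
    eff <- c(eff, paste0(group, "_x_session"), paste0(group, "_x_sex"))
  }
  eff <- c(eff, "individual")
  if (mode == "per-task") {
    eff <- c(eff, "individual_x_session", "individual_x_task")
  }
  eff
}

#' Define the effect masks over a similarity matrix
#'
#' Each mask is a symmetric N x N logical matrix (diagonal `FALSE`)
#' selecting the similarity cells whose average quantifies one source of
#' variance:
#' * `common`: every off-diagonal cell.
#' * `session`: same session, different participant.
#' * `sex` / `diagnosis` / `response`: same level, different participant.
#' * two-way group interactions (e.g. `diagnosis_x_sex`): same level on
#'   both factors, different participant.
#' * `individual` (pooled mode): same participant, different session.
#' * per-task mode: `individual` = same participant, different session
#'   and different task; `individual_x_session` = same participant and
#'   session, different task; `individual_x_task` = same participant and
#'   task, different session. These three partition the within-participant
#'   off-diagonal block.
#'
#' The diagnosis effects appear in the combined sample and are replaced by
#' response effects in the patients-only sample. A factor with a single
#' level in the sample is omitted with a warning, along with its
#' interactions.
#'
#' @param meta unit metadata, already restricted to the sample.
#' @param sample `"all"`, `"controls"` or `"patients"`.
#' @param mode `"pooled"` or `"per-task"`.
#' @param include_within_individual_in_group_masks when `TRUE`, group main
#'   and interaction masks keep within-participant cells (like the common
#'   mask) instead of restricting to different-participant pairs.
#' @return named list of logical matrices, class `effect_masks`.
#' @export
make_effect_masks <- function(meta, sample = c("all", "controls", "patients"),
                              mode = c("pooled", "per-task"),
                              include_within_individual_in_group_masks = FALSE) {
  sample <- match.arg(sample)
  mode <- match.arg(mode)
  if (sample == "controls" && any(meta$diagnosis != "control")) {
    stop_fc("metadata contains non-controls for a controls-only analysis")
  }
  if (sample == "patients" && any(meta$diagnosis != "MD")) {
    stop_fc("metadata contains non-patients for a patients-only analysis")
  }
  if (mode == "per-task" && any(meta$task == "pooled")) {
    stop_fc("per-task masks need per-task units, not pooled units")
  }
  n <- nrow(meta)
  same <- function(col) outer(meta[[col]], meta[[col]], "==")
  offdiag <- !diag(TRUE, n)
  same_sub <- same("subject_id")
  diff_sub <- if (include_within_individual_in_group_masks) offdiag else {
    !same_sub
  }
  factor_col <- c(diagnosis = "diagnosis", response = "responder",
                  sex = "sex", session = "session")

  masks <- list(common = offdiag)
  wanted <- effects_for(sample, mode)
  multi <- function(col) length(unique(meta[[col]])) > 1
  dropped <- character(0)
  for (eff in setdiff(wanted, "common")) {
    parts <- strsplit(eff, "_x_", fixed = TRUE)[[1]]
    if (identical(parts[1], "individual")) {
      masks[[eff]] <- switch(
        eff,
        individual = if (mode == "pooled") {
          same_sub & !same("session") & offdiag
        } else {
          same_sub & !same("session") & !same("task")
        },
        individual_x_session = same_sub & same("session") & !same("task"),
        individual_x_task = same_sub & same("task") & !same("session")
      )
      next
    }
    cols <- factor_col[parts]
    if (!all(vapply(cols, multi, logical(1)))) {
      dropped <- c(dropped, eff)
      next
    }
    # the session main effect always excludes within-participant cells
    # (time-specific similarity is across participants); the group-mask
    # switch applies to group mains and their interactions only
    m <- if (identical(eff, "session")) !same_sub else diff_sub
    for (col in cols) m <- m & same(col)
    masks[[eff]] <- m & offdiag
  }
  if (length(dropped)) {
    warning("effect(s) omitted (single-level factor in this sample): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(masks, meta = meta, sample = sample, mode = mode,
            class = "effect_masks")
}

#' Average similarity over an effect mask
#'
#' Arithmetic mean of the selected cells, counting each unordered unit
#' pair once (the masks are symmetric, so counting both orientations
#' would give the same value).
#'
#' @param simmat a `similarity_matrix`.
#' @param mask logical N x N mask (one element of [make_effect_masks()]).
#' @return mean Fisher z over the mask.
#' @export
effect_average <- function(simmat, mask) {
  z <- if (inherits(simmat, "similarity_matrix")) simmat$z else simmat
  stopifnot(identical(dim(z), dim(mask)))
  cells <- z[mask & upper.tri(z)]
  if (!length(cells)) stop_fc("empty effect mask")
  mean(cells)
}

#' Participant-specific average similarity for one effect
#'
#' The mean of the mask cells within the rows that represent the
#' participant's units (each cell in the row band counted once, as
#' displayed in the similarity matrix). Group-effect masks exclude cells
#' pairing a participant with itself by construction, so a participant's
#' group average reflects their similarity to *other* members of their
#' group.
#'
#' @param simmat a `similarity_matrix`.
#' @param mask logical N x N mask.
#' @param subject_id participant whose rows to average over.
#' @return mean Fisher z, or `NA` (with a warning) when no mask cells fall
#'   in the participant's rows.
#' @export
participant_effect_average <- function(simmat, mask, subject_id) {
  stopifnot(inherits(simmat, "similarity_matrix"))
  rows <- simmat$meta$subject_id == subject_id
  if (!any(rows)) stop_fc("unknown subject_id: ", subject_id)
  cells <- simmat$z[rows, , drop = FALSE][mask[rows, , drop = FALSE]]
  if (!length(cells)) {
    warning("no mask cells in the rows of ", subject_id, call. = FALSE)
    return(NA_real_)
  }
  mean(cells)
}

#' Per-participant averages for every effect
#'
#' @param simmat a `similarity_matrix`.
#' @param masks an `effect_masks` list.
#' @return long data.frame with `subject_id`, `effect`, `mean_z`.
#' @export
participant_effect_table <- function(simmat, masks) {
  subjects <- unique(simmat$meta$subject_id)
  out <- expand.grid(subject_id = subjects, effect = names(masks),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_z <- mapply(function(s, e) {
    participant_effect_average(simmat, masks[[e]], s)
  }, out$subject_id, out$effect)
  rownames(out) <- NULL
  out
}

# the baseline ladder: which raw average each effect is measured against
baseline_values <- function(raw) {
  effects <- names(raw)
  mains <- intersect(c("session", "sex", "diagnosis", "response"), effects)
  interactions <- grep("^(diagnosis|response)_x_", effects, value = TRUE)
  base <- setNames(numeric(length(effects)), effects)
  for (eff in effects) {
    base[eff] <-
      if (eff == "common") {
        0
      } else if (eff %in% mains) {
        raw[["common"]]
      } else if (eff %in% interactions) {
        parts <- strsplit(eff, "_x_", fixed = TRUE)[[1]]
        max(raw[intersect(parts, effects)])
      } else if (eff == "individual") {
        cands <- c(mains, interactions)
        if (length(cands)) max(raw[cands]) else raw[["common"]]
      } else if (eff %in% c("individual_x_session", "individual_x_task")) {
        raw[["individual"]]
      } else {
        stop_fc("no baseline rule for effect '", eff, "'")
      }
  }
  base
}

#' Baseline-corrected, normalized relative effect magnitudes
#'
#' Applies the baseline ladder: the common effect is measured against
#' zero; session and group main effects against the common effect; each
#' two-way group interaction against the larger of its constituent main
#' effects; the individual effect against the largest of all session,
#' group main, and group interaction effects present; and the
#' individual-session / individual-task interactions against the
#' individual effect. Corrected magnitudes are floored at zero, and the
#' normalized magnitude is each corrected magnitude as a percentage of
#' their sum -- the proportion of explained similarity unique to that
#' effect.
#'
#' @param raw named numeric vector of raw mask-average Fisher z values
#'   (must include `"common"`; typically from [effect_average()]).
#' @return data.frame of class `effect_magnitude_table` with columns
#'   `effect`, `raw_mean_z`, `baseline_z`, `corrected`, `normalized_pct`.
#'   When every corrected magnitude is zero the normalized column is `NA`.
#' @export
#' @examples
#' raw <- c(common = 0.30, session = 0.28, sex = 0.32, individual = 0.58)
#' normalized_magnitudes(raw)
normalized_magnitudes <- function(raw) {
  if (!"common" %in% names(raw)) stop_fc("raw magnitudes must include 'common'")
  base <- baseline_values(raw)
  corrected <- pmax(raw - base, 0)
  total <- sum(corrected)
  normalized <- if (total > 0) 100 * corrected / total else {
    rep(NA_real_, length(corrected))
  }
  out <- data.frame(effect = names(raw), raw_mean_z = unname(raw),
                    baseline_z = unname(base), corrected = unname(corrected),
                    normalized_pct = unname(normalized),
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_magnitude_table", "data.frame")
  out
}

#' Full whole-brain effect magnitudes for a similarity matrix
#'
#' Convenience wrapper: mask averages for every effect, then
#' [normalized_magnitudes()].
#'
#' @param simmat a `similarity_matrix`.
#' @param masks an `effect_masks` list.
#' @return an `effect_magnitude_table`.
#' @export
effect_magnitudes <- function(simmat, masks) {
  raw <- vapply(masks, function(m) effect_average(simmat, m), numeric(1))
  normalized_magnitudes(raw)
}

#' Per-region effect magnitudes (localization)
#'
#' Runs the identical decomposition pipeline on each region's
#' connectivity profile (its row of the FC matrix, self-connection
#' excluded) instead of the whole-brain upper triangle, yielding one
#' normalized magnitude table per region. No inference is performed on
#' these region-specific estimates.
#'
#' @param fc_list list of `fc_matrix` objects, one per unit, aligned with
#'   `meta` rows.
#' @param meta unit metadata (already restricted to the sample).
#' @param sample,mode,include_within_individual_in_group_masks passed to
#'   [make_effect_masks()].
#' @return long data.frame: `roi_id`, `effect`, `raw_mean_z`,
#'   `normalized_pct`.
#' @export
roi_effect_magnitudes <- function(fc_list, meta, sample = "all",
                                  mode = "pooled",
                                  include_within_individual_in_group_masks = FALSE) {
  stopifnot(length(fc_list) == nrow(meta), length(fc_list) >= 2)
  R <- ncol(fc_list[[1]]$z)
  if (R < 3) stop_fc("need at least 3 ROIs for per-region profiles")
  masks <- make_effect_masks(meta, sample, mode,
                             include_within_individual_in_group_masks)
  roi_ids <- colnames(fc_list[[1]]$z) %||% as.character(seq_len(R))
  out <- vector("list", R)
  for (roi in seq_len(R)) {
    profiles <- vapply(fc_list, function(fc) roi_profile(fc, roi),
                       numeric(R - 1L))
    simmat <- build_similarity_matrix(profiles, meta = meta)
    tab <- effect_magnitudes(simmat, masks)
    out[[roi]] <- data.frame(roi_id = roi_ids[roi], effect = tab$effect,
                             raw_mean_z = tab$raw_mean_z,
                             normalized_pct = tab$normalized_pct,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monte-Carlo standard error of mask averages via block jackknife
#'
#' Estimates the sampling uncertainty of each effect's mask-average
#' Fisher z attributable to the finite FC-vector length P. Because every
#' source of randomness in the generator (latent patterns and unit noise)
#' is independent across the P ROI pairs, deleting interleaved blocks of
#' pairs and recomputing the similarity matrix gives a jackknife that
#' captures both the pattern-norm fluctuation shared across cells and the
#' per-cell correlation noise -- unlike a jackknife over participants,
#' which misses the former.
#'
#' @param x an `fc_dataset`, or a P x N matrix of FC vectors.
#' @param masks an `effect_masks` list.
#' @param n_blocks number of jackknife blocks over the pair dimension.
#' @return data.frame with `effect`, `mean_z` (full-data mask average),
#'   and `se` (jackknife Monte-Carlo standard error).
#' @export
effect_average_mc_se <- function(x, masks, n_blocks = 50) {
  V <- if (inherits(x, "fc_dataset")) x$vectors else as.matrix(x)
  P <- nrow(V)
  N <- ncol(V)
  if (n_blocks < 2 || n_blocks > P) stop_fc("invalid n_blocks")
  blk <- rep(seq_len(n_blocks), length.out = P)
  Sb <- array(0, c(N, N, n_blocks))
  sb <- matrix(0, N, n_blocks)
  nb <- tabulate(blk, n_blocks)
  for (b in seq_len(n_blocks)) {
    Vb <- V[blk == b, , drop = FALSE]
    Sb[, , b] <- crossprod(Vb)
    sb[, b] <- colSums(Vb)
  }
  S <- rowSums(Sb, dims = 2)
  s <- rowSums(sb)
  mask_mean <- function(Sm, sm, n, mask) {
    cv <- Sm - outer(sm, sm) / n
    d <- sqrt(diag(cv))
    z <- fisher_z(cv / outer(d, d))
    diag(z) <- NA_real_
    mean(z[mask & upper.tri(z)])
  }
  out <- lapply(names(masks), function(eff) {
    m <- masks[[eff]]
    theta <- vapply(seq_len(n_blocks), function(b) {
      mask_mean(S - Sb[, , b], s - sb[, b], P - nb[b], m)
    }, numeric(1))
    data.frame(effect = eff, mean_z = mask_mean(S, s, P, m),
               se = sqrt((n_blocks - 1) / n_blocks *
                           sum((theta - mean(theta))^2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
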