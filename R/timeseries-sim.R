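# Synthetic ROI time series whose correlation structure matches each
# unit's latent FC vector, with optional injected task-locked activity.

#' Project a symmetric matrix to the nearest positive-definite correlation
#' matrix
#'
#' Eigenvalues are clipped from below at `eps`, the matrix is
#' reconstructed, and the diagonal is rescaled back to one. Deterministic
#' and standard; congruence with a positive diagonal scaling preserves
#' positive definiteness.
#'
#' @param mat symmetric matrix with unit diagonal (approximately).
#' @param eps eigenvalue floor.
#' @return positive-definite correlation matrix.
#' @export
nearest_pd <- function(mat, eps = 1e-6) {
  if (!all(is.finite(mat))) stop_fc("matrix contains non-finite values")
  e <- eigen(mat, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- diag(out)
  out <- out / sqrt(outer(d, d))
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

# deterministic synthetic event schedules per task; rest runs have none.
# The go/no-go emulation uses five event types (instruction + four block
# types), the anhedonia emulation seven (two cues, target, four feedback
# types); other task labels get a generic single-type schedule.
make_task_events <- function(task, duration_seconds) {
  if (task == "rest") return(NULL)
  if (task == "gonogo") {
    block_types <- c("angry_go", "angry_nogo", "neutral_go", "neutral_nogo")
    n_blocks <- floor(duration_seconds / 36)
    onsets_instr <- (seq_len(n_blocks) - 1) * 36
    ev <- rbind(
      data.frame(onset = onsets_instr, duration = 2,
                 trial_type = "instruction"),
      data.frame(onset = onsets_instr + 4, duration = 30,
                 trial_type = block_types[((seq_len(n_blocks) - 1) %% 4) + 1])
    )
  } else if (task == "anhedonia") {
    n_trials <- floor((duration_seconds - 12) / 14)
    t0 <- (seq_len(n_trials) - 1) * 14
    cue <- ifelse(seq_len(n_trials) %% 2 == 1, "cue_reward", "cue_noreward")
    fb_types <- c("fb_hit_reward", "fb_hit_noreward",
                  "fb_miss_reward", "fb_miss_noreward")
    ev <- rbind(
      data.frame(onset = t0, duration = 2, trial_type = cue),
      data.frame(onset = t0 + 4, duration = 2, trial_type = "target"),
      data.frame(onset = t0 + 8, duration = 2,
                 trial_type = fb_types[((seq_len(n_trials) - 1) %% 4) + 1])
    )
  } else {
    onsets <- seq(0, duration_seconds - 20, by = 20)
    ev <- data.frame(onset = onsets, duration = 2, trial_type = "event")
  }
  ev <- ev[order(ev$onset), ]
  event_table(ev$onset, ev$duration, ev$trial_type)
}

# smooth haemodynamic-like FIR response shape over L lags
fir_kernel <- function(L) {
  l <- seq_len(L) - 1
  h <- stats::dgamma(l, shape = 3, scale = 1.5)
  h / max(h)
}

#' Generate a synthetic time-series dataset with known FC structure
#'
#' For every participant-session-task unit, the unit's latent FC vector
#' (components plus unit noise, as in [generate_fc_vectors()]) is mapped
#' into a valid correlation matrix -- `tanh(scale * z)` elementwise,
#' symmetrized with unit diagonal, then projected to the nearest
#' positive-definite correlation matrix ([nearest_pd()]) -- and T samples
#' of a zero-mean Gaussian process with that target correlation are drawn
#' via its Cholesky factor. Task runs can additionally receive an
#' injected task-locked response: a smooth FIR-shaped kernel per event
#' type with random ROI loadings, scaled by `task_amplitude`, added on
#' the deterministic event schedule that [make_task_events()] produces.
#'
#' @param components from [generate_latent_components()].
#' @param cohort the matching cohort table.
#' @param config a [simulation_config()] (task structure, TR, ROIs,
#'   weights, `ts_corr_scale`).
#' @param task_amplitude amplitude of injected task-evoked activity
#'   relative to the unit-variance background process; 0 disables
#'   injection.
#' @return list of class `timeseries_dataset`: `runs` (named list of
#'   [roi_timeseries()], `subject_session_task`), `targets` (matching
#'   target correlation matrices), `events` (per-task event tables),
#'   `manifest` (data.frame: subject_id, session, task, path, diagnosis,
#'   sex, responder, site), `cohort`, `config`.
#' @export
generate_timeseries_dataset <- function(components, cohort, config,
                                        task_amplitude = 0) {
  stopifnot(inherits(components, "latent_components"))
  if (nrow(cohort) == 0) stop_fc("cohort is empty")
  R <- config$n_rois
  pairs <- upper_pairs(R)
  tasks <- names(config$tasks)
  events <- lapply(tasks, function(tk) {
    make_task_events(tk, config$tasks[[tk]])
  })
  names(events) <- tasks

  meta <- make_unit_metadata(cohort, config, unit_level = "task")
  runs <- vector("list", nrow(meta))
  targets <- vector("list", nrow(meta))
  unit_ids <- paste(meta$subject_id, meta$session, meta$task, sep = "_")
  w_noise <- config$weights[["noise"]]

  with_seed(config$seed + 21L, {
    for (u in seq_len(nrow(meta))) {
      row <- meta[u, ]
      v <- unit_latent(components, row, per_task = TRUE)
      if (w_noise > 0) v <- v + stats::rnorm(length(v)) * w_noise
      if (!all(is.finite(v))) {
        stop_fc("non-finite latent values for unit ", unit_ids[u])
      }
      C <- diag(1, R)
      C[pairs] <- tanh(config$ts_corr_scale * v)
      C[pairs[, 2:1]] <- C[pairs]
      C <- nearest_pd(C)

      tk <- row$task
      n_t <- floor(config$tasks[[tk]] / config$tr_seconds)
      X <- matrix(stats::rnorm(n_t * R), n_t, R) %*% chol(C)
      if (task_amplitude > 0 && !is.null(events[[tk]])) {
        design <- build_fir_design(events[[tk]], n_t, config$tr_seconds,
                                   lag_samples = 10)
        labels <- attr(design, "labels")
        L <- max(labels$lag) + 1L
        h <- fir_kernel(L)
        types <- unique(labels$type)
        load <- matrix(stats::rnorm(length(types) * R), length(types), R)
        B <- (h[labels$lag + 1L] *
                load[match(labels$type, types), , drop = FALSE])
        X <- X + task_amplitude * (design %*% B)
      }
      colnames(X) <- sprintf("roi%03d", seq_len(R))
      runs[[u]] <- roi_timeseries(X, row$subject_id, row$session, tk,
                                  config$tr_seconds)
      targets[[u]] <- C
    }
  })
  names(runs) <- unit_ids
  names(targets) <- unit_ids

  manifest <- data.frame(
    subject_id = meta$subject_id, session = meta$session, task = meta$task,
    path = paste0(unit_ids, ".tsv"), diagnosis = meta$diagnosis,
    sex = meta$sex, responder = meta$responder, site = "synthetic",
    stringsAsFactors = FALSE
  )
  structure(list(runs = runs, targets = targets, events = events,
                 manifest = manifest, cohort = cohort, config = config),
            class = "timeseries_dataset")
}

#' Write a synthetic time-series dataset to disk
#'
#' Produces the same formats the pipeline reads: one tab-separated
#' time-series file per run (header row of ROI ids), a `manifest.csv`,
#' BIDS-style `<task>_events.tsv` files, and the analytic ground truth as
#' JSON.
#'
#' @param dataset from [generate_timeseries_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "timeseries_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$runs)) {
    run <- dataset$runs[[i]]
    utils::write.table(run$data,
                       file.path(dir, dataset$manifest$path[i]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  for (tk in names(dataset$events)) {
    ev <- dataset$events[[tk]]
    if (!is.null(ev)) {
      utils::write.table(ev, file.path(dir, paste0(tk, "_events.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  gt <- ground_truth(dataset$config, cohort = dataset$cohort)
  jsonlite::write_json(
    list(weights = as.list(dataset$config$weights), expected = gt),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
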