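# Config-driven orchestration tying every stage together: data intake
# (manifest or simulation), preparation, FC, decomposition, inference,
# and optional localization and reliability.

#' Build a pipeline run configuration
#'
#' @param manifest path to a manifest CSV (or a data.frame), mapping
#'   participant x session x task to time-series files with group labels.
#'   Omit when `simulation` is given.
#' @param events_dir directory holding `<task>_events.tsv` (or
#'   `<subject>_<session>_<task>_events.tsv`) files for task regression.
#' @param out_dir output directory for the TSV/JSON results; `NULL` keeps
#'   results in memory only.
#' @param sample analysis sample: `"all"`, `"controls"`, `"patients"`.
#' @param mode `"pooled"` concatenates each participant-session's runs
#'   before FC; `"per-task"` keeps one unit per run (the exploratory
#'   design).
#' @param n_perm permutations for the paired tests (default 1000).
#' @param fdr_q FDR level (default 0.05).
#' @param min_voxels minimum parcel size when voxel data are parcellated
#'   upstream (recorded; default 1 keeps everything).
#' @param fir_lag FIR window length in samples (default 10, ~20 s at
#'   TR = 2 s).
#' @param include_within_individual_in_group_masks see
#'   [make_effect_masks()].
#' @param localize also compute per-region effect magnitudes.
#' @param reliability also compute split-half reliability curves
#'   (time-series input only).
#' @param reliability_grid target lengths in minutes for the reliability
#'   curve.
#' @param simulation optional [simulation_config()]; when present the
#'   pipeline generates its input instead of reading a manifest.
#' @param seed master seed; stage sub-seeds are derived from it.
#' @param log_level `"debug"`, `"info"`, or `"warn"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, events_dir = NULL, out_dir = NULL,
                       sample = c("all", "controls", "patients"),
                       mode = c("pooled", "per-task"),
                       n_perm = 1000, fdr_q = 0.05, min_voxels = 1,
                       fir_lag = 10,
                       include_within_individual_in_group_masks = FALSE,
                       localize = FALSE, reliability = FALSE,
                       reliability_grid = seq(5, 35, by = 5),
                       simulation = NULL, seed = 1L,
                       log_level = c("info", "debug", "warn")) {
  sample <- match.arg(sample)
  mode <- match.arg(mode)
  if (is.null(manifest) && is.null(simulation)) {
    stop_fc("configuration needs either a manifest or a simulation block")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  structure(list(manifest = manifest, events_dir = events_dir,
                 out_dir = out_dir, sample = sample, mode = mode,
                 n_perm = n_perm, fdr_q = fdr_q, min_voxels = min_voxels,
                 fir_lag = fir_lag,
                 include_within_individual_in_group_masks =
                   include_within_individual_in_group_masks,
                 localize = localize, reliability = reliability,
                 reliability_grid = reliability_grid,
                 simulation = simulation, seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

pipeline_log <- function(config, level, stage, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[config$log_level]]) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
}

#' Validate a study manifest against the expected design
#'
#' Checks that every participant has one row per session x task, that
#' rows are unique, that the group labels (diagnosis, sex, responder) are
#' consistent across a participant's rows, and (optionally) that every
#' referenced file exists. All problems are reported together in one
#' itemized error.
#'
#' @param manifest data.frame or path to a manifest CSV.
#' @param sessions,tasks the expected design (defaults mirror the study).
#' @param base_dir directory that relative `path` entries resolve
#'   against.
#' @param check_files verify that files exist.
#' @return the validated manifest, invisibly.
#' @export
validate_manifest <- function(manifest,
                              sessions = c("baseline", "week2", "week8"),
                              tasks = c("rest", "gonogo", "anhedonia"),
                              base_dir = ".", check_files = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  need <- c("subject_id", "session", "task", "path", "diagnosis", "sex",
            "responder")
  problems <- character(0)
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols)) {
    stop_fc("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(manifest$subject_id, manifest$session, manifest$task)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate unit row: ", dup))
  }
  for (s in unique(manifest$subject_id)) {
    rows <- manifest[manifest$subject_id == s, ]
    have <- paste(rows$session, rows$task)
    want <- as.vector(outer(sessions, tasks, paste))
    miss <- setdiff(want, have)
    if (length(miss)) {
      problems <- c(problems,
                    paste0(s, " missing run(s): ", paste(miss, collapse = "; ")))
    }
    for (col in c("diagnosis", "sex", "responder")) {
      if (length(unique(rows[[col]])) > 1) {
        problems <- c(problems,
                      paste0(s, " has contradictory ", col, " labels"))
      }
    }
  }
  if (check_files) {
    paths <- file.path(base_dir, manifest$path)
    gone <- manifest$path[!file.exists(paths)]
    if (length(gone)) {
      problems <- c(problems, paste0("missing file: ", gone))
    }
  }
  if (length(problems)) {
    stop_fc("manifest validation failed:\n",
            paste0("  - ", problems, collapse = "\n"))
  }
  invisible(manifest)
}

# prepare one run: FIR task regression (when events exist) then demeaning
prep_run <- function(run, events, fir_lag) {
  if (!is.null(events)) {
    design <- build_fir_design(events, nrow(run$data), run$tr_seconds,
                               lag_samples = fir_lag)
    run <- regress_out_task(run, design)
  }
  demean_timeseries(run)
}

# locate the events table for one run in events_dir (specific file first,
# then the per-task file); NULL when none exists
find_events <- function(events_dir, subject, session, task) {
  if (is.null(events_dir)) return(NULL)
  for (f in c(file.path(events_dir,
                        paste0(subject, "_", session, "_", task,
                               "_events.tsv")),
              file.path(events_dir, paste0(task, "_events.tsv")))) {
    if (file.exists(f)) return(read_events(f))
  }
  NULL
}

#' Run the full decomposition pipeline
#'
#' Executes preparation (FIR regression, demeaning, concatenation in
#' pooled mode), FC estimation, the similarity-matrix decomposition, and
#' the permutation comparison suite, with optional per-region
#' localization and split-half reliability. All randomness derives from
#' the single master seed. When `config$out_dir` is set, results are
#' written as TSV files plus a `run.json` with the config echo, seed, and
#' per-file checksums.
#'
#' @param config a [run_config()].
#' @return list of class `results_bundle`: `magnitudes`,
#'   `participant_values`, `comparisons`, `simmat`, `meta`, and when
#'   enabled `roi_magnitudes` and `reliability`, plus `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  per_task <- config$mode == "per-task"

  fc_list <- NULL
  dataset <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$unit_level <- if (per_task) "task" else "session"
    sim$seed <- config$seed  # single master seed for the whole run
    pipeline_log(config, "info", "simulate",
                 "generating synthetic cohort (seed ", sim$seed, ")")
    cohort <- generate_cohort(sim)
    comps <- generate_latent_components(sim, cohort)
    if (sim$mode == "vector") {
      ds <- generate_fc_vectors(comps, cohort, sim)
      vectors <- ds$vectors
      meta <- ds$meta
      n_rois <- sim$n_rois
    } else {
      dataset <- generate_timeseries_dataset(comps, cohort, sim)
      prepped <- prepare_runs(dataset$runs, dataset$manifest,
                              dataset$events, config)
      vectors <- prepped$vectors
      meta <- prepped$meta
      fc_list <- prepped$fc_list
      n_rois <- sim$n_rois
    }
  } else {
    manifest <- if (is.character(config$manifest)) {
      read_manifest(config$manifest)
    } else {
      config$manifest
    }
    base_dir <- if (is.character(config$manifest)) {
      dirname(config$manifest)
    } else {
      "."
    }
    pipeline_log(config, "info", "validate", "validating manifest (",
                 nrow(manifest), " rows)")
    validate_manifest(manifest, sessions = unique(manifest$session),
                      tasks = unique(manifest$task), base_dir = base_dir)
    runs <- lapply(seq_len(nrow(manifest)), function(i) {
      read_timeseries(file.path(base_dir, manifest$path[i]),
                      subject_id = manifest$subject_id[i],
                      session = manifest$session[i],
                      task = manifest$task[i])
    })
    names(runs) <- paste(manifest$subject_id, manifest$session,
                         manifest$task, sep = "_")
    events <- lapply(seq_len(nrow(manifest)), function(i) {
      find_events(config$events_dir, manifest$subject_id[i],
                  manifest$session[i], manifest$task[i])
    })
    names(events) <- names(runs)
    prepped <- prepare_runs(runs, manifest, events, config)
    vectors <- prepped$vectors
    meta <- prepped$meta
    fc_list <- prepped$fc_list
    n_rois <- ncol(runs[[1]]$data)
    dataset <- list(runs = runs, manifest = manifest)
  }

  keep <- switch(config$sample,
                 all = rep(TRUE, nrow(meta)),
                 controls = meta$diagnosis == "control",
                 patients = meta$diagnosis == "MD")
  if (!any(keep)) stop_fc("no units in sample '", config$sample, "'")
  meta <- meta[keep, , drop = FALSE]
  vectors <- vectors[, keep, drop = FALSE]
  if (!is.null(fc_list)) fc_list <- fc_list[keep]

  pipeline_log(config, "info", "decompose", "similarity matrix over ",
               nrow(meta), " units")
  simmat <- build_similarity_matrix(vectors, meta = meta)
  masks <- make_effect_masks(
    meta, sample = config$sample, mode = config$mode,
    include_within_individual_in_group_masks =
      config$include_within_individual_in_group_masks)
  magnitudes <- effect_magnitudes(simmat, masks)
  participant_values <- participant_effect_table(simmat, masks)

  pipeline_log(config, "info", "inference", "comparison suite, ",
               config$n_perm, " permutations")
  comparisons <- run_comparison_suite(
    participant_values, sample = config$sample, mode = config$mode,
    n_perm = config$n_perm, seed = config$seed + 100L, q = config$fdr_q)

  bundle <- list(magnitudes = magnitudes,
                 participant_values = participant_values,
                 comparisons = comparisons, simmat = simmat, meta = meta,
                 config = config)

  if (isTRUE(config$localize)) {
    pipeline_log(config, "info", "localize", "per-region magnitudes")
    if (is.null(fc_list)) {
      # vector-mode simulation: rebuild FC matrices from the vectors
      fc_list <- lapply(seq_len(ncol(vectors)), function(u) {
        structure(list(z = matrix_from_fc_vector(vectors[, u], n_rois),
                       meta = as.list(meta[u, ])), class = "fc_matrix")
      })
    }
    bundle$roi_magnitudes <- roi_effect_magnitudes(
      fc_list, meta, sample = config$sample, mode = config$mode,
      include_within_individual_in_group_masks =
        config$include_within_individual_in_group_masks)
  }

  if (isTRUE(config$reliability)) {
    if (is.null(dataset$runs)) {
      stop_fc("reliability requires time-series input")
    }
    pipeline_log(config, "info", "reliability", "split-half curves")
    bundle$reliability <- reliability_curve(
      dataset, grid_minutes = config$reliability_grid,
      seed = config$seed + 200L, sample = "controls")
  }

  class(bundle) <- "results_bundle"
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  invisible(bundle)
}

# prep + FC + vectorization for a set of runs; pooled mode concatenates a
# participant-session's runs before FC
prepare_runs <- function(runs, manifest, events, config) {
  per_task <- config$mode == "per-task"
  get_events <- function(i) {
    tk <- manifest$task[i]
    if (!is.null(events[[names(runs)[i]]])) {
      events[[names(runs)[i]]]
    } else if (tk %in% names(events)) {
      events[[tk]]
    } else {
      NULL
    }
  }
  prepped <- lapply(seq_along(runs), function(i) {
    prep_run(runs[[i]], get_events(i), config$fir_lag)
  })
  if (per_task) {
    meta <- manifest[, c("subject_id", "session", "task", "diagnosis",
                         "sex", "responder")]
    fc_list <- lapply(prepped, compute_fc)
  } else {
    groups <- split(seq_along(prepped),
                    paste(manifest$subject_id, manifest$session))
    # keep first-appearance order (participant-major)
    groups <- groups[unique(paste(manifest$subject_id, manifest$session))]
    fc_list <- lapply(groups, function(ix) {
      compute_fc(concatenate_runs(prepped[ix]))
    })
    first <- vapply(groups, `[`, integer(1), 1)
    meta <- manifest[first, c("subject_id", "session", "diagnosis", "sex",
                              "responder")]
    meta$task <- "pooled"
    meta <- meta[, c("subject_id", "session", "task", "diagnosis", "sex",
                     "responder")]
  }
  rownames(meta) <- NULL
  vectors <- vapply(fc_list, function(fc) vectorize_upper(fc)$z,
                    numeric(n_pairs(ncol(fc_list[[1]]$z))))
  colnames(vectors) <- paste(meta$subject_id, meta$session, meta$task,
                             sep = "_")
  list(vectors = vectors, meta = meta, fc_list = fc_list)
}

# write the bundle's tables plus run metadata with checksums
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  files <- c(files, write_tsv(bundle$magnitudes,
                              file.path(out_dir, "effects.tsv")))
  files <- c(files, write_tsv(bundle$participant_values,
                              file.path(out_dir,
                                        "per_participant_effects.tsv")))
  files <- c(files, write_tsv(bundle$comparisons,
                              file.path(out_dir, "comparisons.tsv")))
  if (!is.null(bundle$roi_magnitudes)) {
    files <- c(files, write_tsv(bundle$roi_magnitudes,
                                file.path(out_dir, "roi_effects.tsv")))
  }
  if (!is.null(bundle$reliability)) {
    files <- c(files, write_tsv(bundle$reliability$curves,
                                file.path(out_dir, "reliability.tsv")))
    files <- c(files, write_tsv(bundle$reliability$mean_curve,
                                file.path(out_dir,
                                          "reliability_mean.tsv")))
  }
  cfg <- bundle$config
  cfg_echo <- cfg[!vapply(cfg, is.null, logical(1))]
  cfg_echo$simulation <- if (!is.null(cfg$simulation)) {
    unclass(cfg$simulation)
  }
  jsonlite::write_json(
    list(config = cfg_echo, seed = cfg$seed,
         timestamp = format(Sys.time(), tz = "UTC"),
         files = as.list(tools::md5sum(files))),
    file.path(out_dir, "run.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(files)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Decomposition results (", x$config$sample, "sample,",
      x$config$mode, "mode )\n\n")
  print(x$magnitudes)
  invisible(x)
}
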