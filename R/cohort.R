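#' Simulation configuration for a synthetic longitudinal FC cohort
#'
#' Bundles the design of the emulated study: stratum sizes, session and task
#' structure, region count, and the standard-deviation weights of the latent
#' variance components that generate connectivity. Defaults mirror the study
#' design this package models: 107 participants (42 female / 26 male
#' patients with major depression, of whom 33 treatment responders; 21
#' female / 18 male controls), three sessions (baseline, week 2, week 8),
#' and three runs per session (rest 588 s, affective go/no-go 588 s,
#' monetary-incentive/anhedonia 690 s) at TR = 2 s.
#'
#' @param n_controls_f,n_controls_m,n_patients_f,n_patients_m stratum sizes.
#' @param n_responders number of patients classified as treatment
#'   responders (must not exceed the patient count).
#' @param sessions ordered character vector of session labels.
#' @param tasks named numeric vector of run durations in seconds, names are
#'   task labels. Durations are floored to whole samples at `tr_seconds`.
#' @param tr_seconds sampling interval of the emulated fMRI series.
#' @param n_rois number of regions. Default 60 keeps simulations light;
#'   use 326 to mirror the study's parcellation.
#' @param weights named numeric vector of non-negative standard-deviation
#'   weights for the latent components `common`, `diagnosis`, `sex`,
#'   `response`, `session`, `individual`, `task`, `individual_session`,
#'   and `noise`. Missing names default to 0. At least one weight must be
#'   positive. Defaults encode a realistic regime: strong common and
#'   individual structure, small group effects, weaker session structure,
#'   moderate unit-level noise.
#' @param unit_level `"session"` pools tasks into one unit per
#'   participant-session; `"task"` keeps one unit per
#'   participant-session-task (the exploratory, per-task design).
#' @param mode `"vector"` emits latent FC vectors directly; `"timeseries"`
#'   additionally synthesizes ROI time series whose correlation structure
#'   matches each unit's latent vector.
#' @param ts_corr_scale scale applied inside `tanh` when mapping latent
#'   z-values to target correlations in time-series mode.
#' @param seed master integer seed; every random draw in the generator is
#'   a deterministic function of it.
#'
#' @return an object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_rois = 10, seed = 1)
#' cfg$weights
simulation_config <- function(n_controls_f = 21, n_controls_m = 18,
                              n_patients_f = 42, n_patients_m = 26,
                              n_responders = 33,
                              sessions = c("baseline", "week2", "week8"),
                              tasks = c(rest = 588, gonogo = 588, anhedonia = 690),
                              tr_seconds = 2,
                              n_rois = 60,
                              weights = NULL,
                              unit_level = c("session", "task"),
                              mode = c("vector", "timeseries"),
                              ts_corr_scale = 0.25,
                              seed = 1L) {
  counts <- c(n_controls_f, n_controls_m, n_patients_f, n_patients_m)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_fc("stratum counts must be non-negative integers")
  }
  n_patients <- n_patients_f + n_patients_m
  if (n_responders < 0 || n_responders > n_patients) {
    stop_fc("n_responders must be between 0 and the number of patients (",
            n_patients, ")")
  }
  if (length(sessions) < 1 || anyDuplicated(sessions)) {
    stop_fc("sessions must be a non-empty vector of unique labels")
  }
  if (is.null(names(tasks)) || anyDuplicated(names(tasks)) || any(tasks <= 0)) {
    stop_fc("tasks must be a named vector of positive durations (seconds)")
  }
  if (n_rois < 3) stop_fc("n_rois must be at least 3")
  default_w <- c(common = 1, diagnosis = 0.1, sex = 0.1, response = 0,
                 session = 0.05, individual = 0.95, task = 0,
                 individual_session = 0, noise = 0.35)
  if (is.null(weights)) {
    weights <- default_w
  } else {
    unknown <- setdiff(names(weights), names(default_w))
    if (length(unknown)) {
      stop_fc("unknown weight component(s): ", paste(unknown, collapse = ", "))
    }
    w <- default_w * 0
    w[names(weights)] <- weights
    weights <- w
  }
  if (any(weights < 0)) stop_fc("all component weights must be >= 0")
  if (all(weights == 0)) stop_fc("at least one component weight must be > 0")

  cfg <- list(
    n_controls_f = as.integer(n_controls_f),
    n_controls_m = as.integer(n_controls_m),
    n_patients_f = as.integer(n_patients_f),
    n_patients_m = as.integer(n_patients_m),
    n_responders = as.integer(n_responders),
    sessions = as.character(sessions),
    tasks = tasks,
    tr_seconds = tr_seconds,
    n_rois = as.integer(n_rois),
    weights = weights,
    unit_level = match.arg(unit_level),
    mode = match.arg(mode),
    ts_corr_scale = ts_corr_scale,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:",
      x$n_patients_f + x$n_patients_m, "patients (",
      x$n_responders, "responders ),",
      x$n_controls_f + x$n_controls_m, "controls;",
      length(x$sessions), "sessions x", length(x$tasks), "tasks;",
      x$n_rois, "ROIs; unit level:", x$unit_level, "\n")
  cat("Weights:", paste(names(x$weights), round(x$weights, 3),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Classify treatment response from MADRS scores
#'
#' A patient is a responder when their MADRS symptom score decreased by
#' strictly more than 50% from baseline to week 8. A decrease of exactly
#' 50% (or less, or an increase) is a nonresponse.
#'
#' @param madrs_baseline,madrs_week8 numeric symptom scores.
#' @return character vector, `"responder"` or `"nonresponder"`.
#' @export
#' @examples
#' responder_status(28, 8)    # 71.4% decrease -> responder
#' responder_status(30, 15)   # exactly 50% -> nonresponder
responder_status <- function(madrs_baseline, madrs_week8) {
  if (any(madrs_baseline <= 0)) stop_fc("madrs_baseline must be positive")
  decrease <- (madrs_baseline - madrs_week8) / madrs_baseline
  ifelse(decrease > 0.5, "responder", "nonresponder")
}

# truncated-normal draw via rejection; used for MADRS baselines
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lower
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic cohort with MADRS trajectories
#'
#' Builds the participant table for a [simulation_config()]: stratum sizes
#' are honored exactly, and MADRS trajectories are sampled so that exactly
#' `n_responders` patients satisfy the responder rule (>50% decrease from
#' baseline to week 8; see [responder_status()]). Patient baselines are
#' drawn from a normal distribution (mean 29, sd 3) truncated at the trial
#' entry criterion of 24; responders' week-8 scores are 10-45% of baseline,
#' nonresponders' 55-110%; week-2 scores lie part-way along the trajectory.
#' Controls receive low, stable scores.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` of class `cohort_table` with columns
#'   `subject_id`, `diagnosis` (`MD`/`control`), `sex` (`F`/`M`),
#'   `responder` (`responder`/`nonresponder`/`not_applicable`),
#'   `madrs_baseline`, `madrs_week2`, `madrs_week8`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(seed = 7))
#' table(cohort$diagnosis, cohort$responder)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_pat <- config$n_patients_f + config$n_patients_m
  n_con <- config$n_controls_f + config$n_controls_m
  n <- n_pat + n_con
  if (n == 0) stop_fc("cohort is empty: all stratum counts are zero")

  diagnosis <- c(rep("MD", n_pat), rep("control", n_con))
  sex <- c(rep("F", config$n_patients_f), rep("M", config$n_patients_m),
           rep("F", config$n_controls_f), rep("M", config$n_controls_m))
  subject_id <- sprintf("sub%03d", seq_len(n))

  with_seed(config$seed + 1L, {
    responder <- rep("not_applicable", n)
    if (n_pat > 0) {
      resp_idx <- sample(seq_len(n_pat), config$n_responders)
      responder[seq_len(n_pat)] <- "nonresponder"
      responder[resp_idx] <- "responder"
    }

    madrs_baseline <- madrs_week2 <- madrs_week8 <- numeric(n)
    if (n_pat > 0) {
      b <- rnorm_trunc(n_pat, 29, 3, lower = 24)
      ratio8 <- ifelse(responder[seq_len(n_pat)] == "responder",
                       stats::runif(n_pat, 0.10, 0.45),
                       stats::runif(n_pat, 0.55, 1.10))
      w8 <- b * ratio8
      w2 <- b + (w8 - b) * stats::runif(n_pat, 0.45, 0.75)
      madrs_baseline[seq_len(n_pat)] <- b
      madrs_week2[seq_len(n_pat)] <- w2
      madrs_week8[seq_len(n_pat)] <- w8
    }
    if (n_con > 0) {
      idx <- n_pat + seq_len(n_con)
      b <- pmax(stats::rnorm(n_con, 2, 1.5), 0) + 0.5
      madrs_baseline[idx] <- b
      madrs_week2[idx] <- pmax(b + stats::rnorm(n_con, 0, 1), 0)
      madrs_week8[idx] <- pmax(b + stats::rnorm(n_con, 0, 1), 0)
    }
  })

  cohort <- data.frame(
    subject_id = subject_id, diagnosis = diagnosis, sex = sex,
    responder = responder,
    madrs_baseline = madrs_baseline, madrs_week2 = madrs_week2,
    madrs_week8 = madrs_week8,
    stringsAsFactors = FALSE
  )
  # invariant: the stored label must be derivable from the scores
  pat <- cohort$diagnosis == "MD"
  if (any(pat)) {
    derived <- responder_status(cohort$madrs_baseline[pat],
                                cohort$madrs_week8[pat])
    stopifnot(identical(derived, cohort$responder[pat]))
  }
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Expand a cohort into analysis-unit metadata
#'
#' One row per analysis unit: participant-session when `unit_level` is
#' `"session"` (tasks pooled, `task = "pooled"`), participant-session-task
#' when `"task"`. Rows are ordered participant-major, then session, then
#' task, matching the generated FC vectors.
#'
#' @param cohort a `cohort_table`.
#' @param config the [simulation_config()] that defines sessions/tasks.
#' @param unit_level override of `config$unit_level`.
#' @return data.frame with columns `subject_id`, `session`, `task`,
#'   `diagnosis`, `sex`, `responder`.
#' @export
make_unit_metadata <- function(cohort, config, unit_level = config$unit_level) {
  tasks <- if (unit_level == "task") names(config$tasks) else "pooled"
  grid <- expand.grid(task = tasks, session = config$sessions,
                      subject_id = cohort$subject_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject_id", "session", "task")]
  idx <- match(grid$subject_id, cohort$subject_id)
  grid$diagnosis <- cohort$diagnosis[idx]
  grid$sex <- cohort$sex[idx]
  grid$responder <- cohort$responder[idx]
  rownames(grid) <- NULL
  grid
}
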