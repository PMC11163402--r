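# Latent variance components for the synthetic FC generator.
#
# Each component is a set of patterns over the P = R(R-1)/2 ROI pairs,
# one pattern per factor level (one common pattern, one per diagnosis
# level, per sex, per response level, per session, per task, per
# individual, and per individual-session cell). A unit's latent FC vector
# is the sum of the patterns it shares (plus fresh unit noise), so the
# expected correlation between two units is the ratio of shared to total
# squared weights -- the analytic oracle in expected_effect_similarity().

# fixed level orders, so patterns regenerate bit-identically
component_levels <- function(config, cohort) {
  list(
    common = "common",
    diagnosis = c("MD", "control"),
    sex = c("F", "M"),
    response = c("responder", "nonresponder", "not_applicable"),
    session = config$sessions,
    task = names(config$tasks),
    individual = cohort$subject_id,
    individual_session = as.vector(outer(config$sessions, cohort$subject_id,
                                         function(s, i) paste(i, s, sep = ":")))
  )
}

# per-component RNG substream offsets from the master seed
component_seed_offsets <- c(common = 11L, diagnosis = 12L, sex = 13L,
                            response = 14L, session = 15L, task = 16L,
                            individual = 17L, individual_session = 18L,
                            noise = 19L)

#' Generate latent FC variance-component patterns
#'
#' Draws one i.i.d. standard-normal pattern of length P = R(R-1)/2 per
#' factor level and scales it by the matching component weight. Components
#' with weight zero are exact zero patterns. Each component uses its own
#' RNG substream derived from the master seed, so patterns are
#' bit-reproducible and independent of which other weights are nonzero.
#'
#' @param config a [simulation_config()].
#' @param cohort the matching [generate_cohort()] table.
#' @return an object of class `latent_components`: a named list of
#'   P-by-levels matrices, with attributes `P` and `weights`.
#' @export
generate_latent_components <- function(config, cohort) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(cohort, "cohort_table"))
  P <- n_pairs(config$n_rois)
  levels <- component_levels(config, cohort)
  w <- config$weights
  comps <- lapply(names(levels), function(nm) {
    lv <- levels[[nm]]
    if (w[[nm]] == 0) {
      m <- matrix(0, nrow = P, ncol = length(lv))
    } else {
      m <- with_seed(config$seed + component_seed_offsets[[nm]],
                     matrix(stats::rnorm(P * length(lv)), nrow = P)) * w[[nm]]
    }
    colnames(m) <- lv
    m
  })
  names(comps) <- names(levels)
  structure(comps, P = P, weights = w, class = "latent_components")
}

# latent vector of one unit (no noise): sum of the patterns it shares
unit_latent <- function(components, meta_row, per_task) {
  v <- components$common[, 1] +
    components$diagnosis[, meta_row$diagnosis] +
    components$sex[, meta_row$sex] +
    components$response[, meta_row$responder] +
    components$session[, meta_row$session] +
    components$individual[, meta_row$subject_id] +
    components$individual_session[, paste(meta_row$subject_id,
                                          meta_row$session, sep = ":")]
  if (per_task) v <- v + components$task[, meta_row$task]
  v
}

#' Generate synthetic FC vectors with known variance structure
#'
#' For each analysis unit, sums the latent component patterns the unit
#' shares (common, its diagnosis/sex/response levels, its session, its
#' individual and individual-session patterns, and -- in per-task mode --
#' its task pattern) and adds a fresh noise pattern scaled by the noise
#' weight. Vectors are emitted directly on the Fisher-z scale: the
#' decomposition depends only on correlations between vectors, not on
#' their marginal scale.
#'
#' @param components from [generate_latent_components()].
#' @param cohort the matching cohort table.
#' @param config the [simulation_config()].
#' @return an `fc_dataset`: list with `vectors` (P x N matrix, one column
#'   per unit) and `meta` (the unit metadata rows, aligned with columns).
#' @export
#' @examples
#' cfg <- simulation_config(n_controls_f = 2, n_controls_m = 2,
#'                          n_patients_f = 0, n_patients_m = 0,
#'                          n_responders = 0, n_rois = 8, seed = 3)
#' cohort <- generate_cohort(cfg)
#' comps <- generate_latent_components(cfg, cohort)
#' ds <- generate_fc_vectors(comps, cohort, cfg)
#' dim(ds$vectors)
generate_fc_vectors <- function(components, cohort, config) {
  stopifnot(inherits(components, "latent_components"))
  if (nrow(cohort) == 0) stop_fc("cohort is empty")
  meta <- make_unit_metadata(cohort, config)
  per_task <- config$unit_level == "task"
  P <- attr(components, "P")
  N <- nrow(meta)
  V <- matrix(0, nrow = P, ncol = N)
  for (u in seq_len(N)) {
    V[, u] <- unit_latent(components, meta[u, ], per_task)
  }
  w_noise <- config$weights[["noise"]]
  if (w_noise > 0) {
    V <- V + with_seed(config$seed + component_seed_offsets[["noise"]],
                       matrix(stats::rnorm(P * N), nrow = P)) * w_noise
  }
  colnames(V) <- paste(meta$subject_id, meta$session, meta$task, sep = "_")
  structure(list(vectors = V, meta = meta), class = "fc_dataset")
}

#' Analytic expected similarity for each effect mask
#'
#' The oracle for parameter-recovery tests. Under the generative model,
#' the expected correlation between two distinct units is
#' (sum of squared weights of the components they share) /
#' (sum of squared weights of all components, including noise); every unit
#' carries one level of every component, so the denominator is the same
#' for all units. The mask-level expectation averages the Fisher z of
#' these pairwise correlations over the cells of the effect's mask,
#' weighted by cell counts.
#'
#' @param config a [simulation_config()].
#' @param effect effect name (e.g. `"common"`, `"individual"`, `"sex"`,
#'   `"diagnosis_x_session"`); must exist for the given sample and mode.
#' @param sample which participants the analysis uses: `"all"`,
#'   `"controls"`, or `"patients"`.
#' @param cohort optional cohort table; regenerated from `config` if
#'   missing (pair-class counts depend only on stratum sizes).
#' @return list with `effect`, `expected_r` (mask-average correlation,
#'   pre-Fisher) and `expected_z` (mask-average Fisher z).
#' @export
expected_effect_similarity <- function(config, effect, sample = "all",
                                       cohort = NULL) {
  gt <- ground_truth(config, sample = sample, cohort = cohort)
  row <- gt[gt$effect == effect, ]
  if (nrow(row) != 1) {
    stop_fc("unknown effect '", effect, "' for sample '", sample,
            "' (available: ", paste(gt$effect, collapse = ", "), ")")
  }
  list(effect = effect, expected_r = row$expected_r,
       expected_z = row$expected_z)
}

#' Ground-truth expected similarities for every effect
#'
#' @inheritParams expected_effect_similarity
#' @return data.frame with one row per effect: `effect`, `expected_r`,
#'   `expected_z`.
#' @export
ground_truth <- function(config, sample = "all", cohort = NULL) {
  cohort <- cohort %||% generate_cohort(config)
  meta <- make_unit_metadata(cohort, config)
  meta <- subset_sample(meta, sample)
  per_task <- config$unit_level == "task"
  w2 <- config$weights^2
  total <- sum(w2[c("common", "diagnosis", "sex", "response", "session",
                    "individual", "individual_session", "noise")]) +
    if (per_task) w2[["task"]] else 0

  same <- function(col) outer(meta[[col]], meta[[col]], "==")
  shared <- w2[["common"]] +
    w2[["diagnosis"]] * same("diagnosis") +
    w2[["sex"]] * same("sex") +
    w2[["response"]] * same("responder") +
    w2[["session"]] * same("session") +
    w2[["individual"]] * same("subject_id") +
    w2[["individual_session"]] * (same("subject_id") & same("session"))
  if (per_task) shared <- shared + w2[["task"]] * same("task")
  r <- shared / total
  z <- fisher_z(r)
  diag(r) <- NA_real_
  diag(z) <- NA_real_

  masks <- make_effect_masks(meta, sample = sample,
                             mode = if (per_task) "per-task" else "pooled")
  ut <- upper.tri(r)
  out <- data.frame(
    effect = names(masks),
    expected_r = vapply(masks, function(m) mean(r[m & ut]), numeric(1)),
    expected_z = vapply(masks, function(m) mean(z[m & ut]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
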