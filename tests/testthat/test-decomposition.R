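make_meta <- function(subject, session, task = "pooled",
                      diagnosis = "control", sex = "F",
                      responder = "not_applicable") {
  data.frame(subject_id = subject, session = session, task = task,
             diagnosis = diagnosis, sex = sex, responder = responder,
             stringsAsFactors = FALSE)
}

test_that("similarity matrix equals pairwise Fisher-z correlations", {
  set.seed(9)
  V <- matrix(rnorm(6 * 3), 6, 3)
  colnames(V) <- paste0("u", 1:3)
  meta <- make_meta(paste0("s", 1:3), "baseline")
  sm <- build_similarity_matrix(V, meta)
  for (u in 1:2) for (v in (u + 1):3) {
    expect_equal(sm$z[u, v], atanh(cor(V[, u], V[, v])))
    expect_equal(sm$z[u, v], sm$z[v, u])
  }
  expect_true(all(is.na(diag(sm$z))))

  # identical vectors hit the clipped ceiling
  V2 <- cbind(V[, 1], V[, 1], V[, 1])
  colnames(V2) <- paste0("u", 1:3)
  sm2 <- build_similarity_matrix(V2, meta)
  expect_true(all(sm2$z[upper.tri(sm2$z)] == z_clip()))

  V3 <- cbind(V[, 1:2], rep(1, 6))
  colnames(V3) <- paste0("u", 1:3)
  expect_error(build_similarity_matrix(V3, meta), "zero-variance.*u3")
})

test_that("effect masks select the documented cells", {
  # 2 participants x 2 sessions: the session mask holds 4 cells
  meta <- make_meta(rep(c("s1", "s2"), each = 2),
                    rep(c("baseline", "week2"), 2))
  masks <- suppressWarnings(  # all-female toy: sex effect is omitted
    make_effect_masks(meta, sample = "controls", mode = "pooled"))
  expect_equal(sum(masks$session), 4)
  # common: all off-diagonal cells, N(N-1) of them
  expect_equal(sum(masks$common), 4 * 3)
  # each mask is symmetric and avoids the diagonal
  for (m in masks) {
    expect_equal(m, t(m))
    expect_false(any(diag(m)))
  }

  # one participant, three sessions: individual mask = 6 cells
  meta1 <- make_meta("s1", c("baseline", "week2", "week8"))
  masks1 <- suppressWarnings(
    make_effect_masks(meta1, sample = "controls", mode = "pooled"))
  expect_equal(sum(masks1$individual), 6)

  # single-level factors are dropped with a warning
  expect_warning(
    make_effect_masks(meta1, sample = "controls", mode = "pooled"),
    "omitted.*sex")
})

test_that("session masks never include within-participant cells", {
  cfg <- tiny_config()
  meta <- make_unit_metadata(generate_cohort(cfg), cfg)
  masks <- make_effect_masks(meta, sample = "all", mode = "pooled")
  same_sub <- outer(meta$subject_id, meta$subject_id, "==")
  expect_false(any(masks$session & same_sub))
  # with the within-individual switch on, group masks keep within cells
  # but the session mask still excludes them
  masks2 <- make_effect_masks(meta, sample = "all", mode = "pooled",
                              include_within_individual_in_group_masks = TRUE)
  expect_true(any(masks2$diagnosis & same_sub))
  expect_false(any(masks2$session & same_sub))
})

test_that("per-task within-participant masks partition the within block", {
  cfg <- tiny_config(unit_level = "task")
  meta <- make_unit_metadata(generate_cohort(cfg), cfg)
  masks <- make_effect_masks(meta, sample = "all", mode = "per-task")
  same_sub <- outer(meta$subject_id, meta$subject_id, "==")
  within <- same_sub & !diag(TRUE, nrow(meta))
  trio <- list(masks$individual, masks$individual_x_session,
               masks$individual_x_task)
  # pairwise disjoint
  expect_false(any(trio[[1]] & trio[[2]]))
  expect_false(any(trio[[1]] & trio[[3]]))
  expect_false(any(trio[[2]] & trio[[3]]))
  # union covers all within-participant off-diagonal cells
  expect_equal(trio[[1]] | trio[[2]] | trio[[3]], within)
})

test_that("effect averages match hand arithmetic and a double loop", {
  # hand-built 4x4: 2 participants x 2 sessions
  meta <- make_meta(rep(c("s1", "s2"), each = 2),
                    rep(c("baseline", "week2"), 2))
  z <- matrix(c(NA, 0.9, 0.5, 0.3,
                0.9, NA, 0.2, 0.6,
                0.5, 0.2, NA, 0.8,
                0.3, 0.6, 0.8, NA), 4, 4)
  sm <- structure(list(z = z, meta = meta), class = "similarity_matrix")
  masks <- suppressWarnings(
    make_effect_masks(meta, sample = "controls", mode = "pooled"))
  # session cells: (u1,u3) and (u2,u4) -> (0.5 + 0.6) / 2
  expect_equal(effect_average(sm, masks$session), 0.55)
  # individual cells: (u1,u2) and (u3,u4) -> (0.9 + 0.8) / 2
  expect_equal(effect_average(sm, masks$individual), 0.85)
  # common: all six unordered pairs
  expect_equal(effect_average(sm, masks$common),
               mean(c(0.9, 0.5, 0.3, 0.2, 0.6, 0.8)))
  # loop oracle and permutation invariance
  for (m in masks) {
    expect_equal(effect_average(sm, m), loop_effect_average(z, m))
  }
  perm <- c(3, 1, 4, 2)
  sm_p <- structure(list(z = z[perm, perm], meta = meta[perm, ]),
                    class = "similarity_matrix")
  masks_p <- suppressWarnings(
    make_effect_masks(meta[perm, ], sample = "controls", mode = "pooled"))
  expect_equal(effect_average(sm_p, masks_p$session),
               effect_average(sm, masks$session))

  expect_error(effect_average(sm, matrix(FALSE, 4, 4)), "empty")
})

test_that("participant averages restrict the mask to the participant's rows", {
  meta <- make_meta(rep(c("s1", "s2"), each = 2),
                    rep(c("baseline", "week2"), 2))
  z <- matrix(c(NA, 0.9, 0.5, 0.3,
                0.9, NA, 0.2, 0.6,
                0.5, 0.2, NA, 0.8,
                0.3, 0.6, 0.8, NA), 4, 4)
  sm <- structure(list(z = z, meta = meta), class = "similarity_matrix")
  masks <- suppressWarnings(
    make_effect_masks(meta, sample = "controls", mode = "pooled"))
  # s1 session cells in rows 1-2: (1,3) = 0.5 and (2,4) = 0.6
  expect_equal(participant_effect_average(sm, masks$session, "s1"), 0.55)
  # s1 individual cells in rows 1-2: (1,2) and (2,1), both 0.9
  expect_equal(participant_effect_average(sm, masks$individual, "s1"), 0.9)
  # constant matrix: every participant average equals the constant
  zc <- matrix(0.4, 4, 4)
  diag(zc) <- NA
  smc <- structure(list(z = zc, meta = meta), class = "similarity_matrix")
  for (s in c("s1", "s2")) {
    expect_equal(participant_effect_average(smc, masks$common, s), 0.4)
  }
  # balanced design: participant mean of a cross-participant effect equals
  # the matrix-level average
  tab <- participant_effect_table(sm, masks)
  s_tab <- tab[tab$effect == "session", ]
  expect_equal(mean(s_tab$mean_z), effect_average(sm, masks$session))
  expect_error(participant_effect_average(sm, masks$common, "nobody"),
               "unknown")
})

test_that("the baseline ladder yields the documented normalized magnitudes", {
  raw <- c(common = 0.30, session = 0.28, sex = 0.32, individual = 0.58)
  tab <- normalized_magnitudes(raw)
  expect_equal(tab$baseline_z, c(0, 0.30, 0.30, 0.32))
  expect_equal(tab$corrected, c(0.30, 0, 0.02, 0.26))
  expect_equal(tab$normalized_pct,
               100 * c(0.30, 0, 0.02, 0.26) / 0.58, tolerance = 1e-12)
  # hand check of the published-style percentages
  expect_equal(round(tab$normalized_pct, 1), c(51.7, 0, 3.4, 44.8))
  # effects below baseline are floored at zero
  expect_true(all(tab$corrected >= 0))
  # normalized values partition 100%
  expect_equal(sum(tab$normalized_pct), 100)

  # single effect above a zero baseline takes 100%
  tab1 <- normalized_magnitudes(c(common = 0.4))
  expect_equal(tab1$normalized_pct, 100)

  # interaction baselines use the larger constituent main effect
  raw2 <- c(common = 0.2, session = 0.25, sex = 0.22, diagnosis = 0.3,
            diagnosis_x_session = 0.4, diagnosis_x_sex = 0.1,
            individual = 0.6)
  tab2 <- normalized_magnitudes(raw2)
  get <- function(e, col) tab2[tab2$effect == e, col]
  expect_equal(get("diagnosis_x_session", "baseline_z"), 0.3)
  expect_equal(get("diagnosis_x_sex", "baseline_z"), 0.3)
  expect_equal(get("diagnosis_x_sex", "corrected"), 0)
  expect_equal(get("individual", "baseline_z"), 0.4)

  # all-zero corrected magnitudes: normalization undefined
  tab3 <- normalized_magnitudes(c(common = 0, session = -0.1))
  expect_true(all(is.na(tab3$normalized_pct)))
})

test_that("per-region magnitudes equal the whole-brain path on profiles", {
  cfg <- tiny_config(n_rois = 3, seed = 13)
  ch <- generate_cohort(cfg)
  ds <- generate_fc_vectors(generate_latent_components(cfg, ch), ch, cfg)
  fc_list <- lapply(seq_len(ncol(ds$vectors)), function(u) {
    structure(list(z = matrix_from_fc_vector(ds$vectors[, u], 3),
                   meta = as.list(ds$meta[u, ])), class = "fc_matrix")
  })
  roi_tab <- roi_effect_magnitudes(fc_list, ds$meta, sample = "all",
                                   mode = "pooled")
  # compositional oracle for region 2: run the whole-brain machinery on
  # the length-2 profile vectors directly
  profiles <- vapply(fc_list, function(fc) roi_profile(fc, 2), numeric(2))
  sm <- build_similarity_matrix(profiles, meta = ds$meta)
  masks <- make_effect_masks(ds$meta, sample = "all", mode = "pooled")
  want <- effect_magnitudes(sm, masks)
  got <- roi_tab[roi_tab$roi_id == "2", ]
  expect_equal(got$normalized_pct, want$normalized_pct)
  expect_equal(got$raw_mean_z, want$raw_mean_z)

  # constant profiles are rejected as degenerate
  fc_const <- lapply(fc_list, function(fc) {
    fc$z[] <- 0.5
    diag(fc$z) <- NA
    fc
  })
  expect_error(roi_effect_magnitudes(fc_const, ds$meta), "zero-variance")
})
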