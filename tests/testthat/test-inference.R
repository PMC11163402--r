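test_that("paired permutation t-test matches hand arithmetic", {
  res <- paired_permutation_ttest(c(1, 2, 4), c(0, 1, 1), n_perm = 200,
                                  seed = 1)
  expect_equal(res$t, 2.5)
  expect_equal(res$df, 2)
  expect_equal(res$cohens_d, (5 / 3) / (2 / sqrt(3)))

  # identical samples: t = 0, p = 1 (every |t*| >= 0)
  a <- c(0.3, 0.5, 0.7, 0.4)
  res0 <- paired_permutation_ttest(a, a + 0, n_perm = 100, seed = 2)
  expect_true(res0$degenerate)
  b <- a + c(0.1, -0.1, 0.1, -0.1)
  res1 <- paired_permutation_ttest(a, b, n_perm = 100, seed = 2)
  expect_equal(res1$t, 0)
  expect_equal(res1$p_perm, 1)

  expect_error(paired_permutation_ttest(1:2, 2:3), "at least 3")
  expect_error(paired_permutation_ttest(1:4, 1:3), "equal length")
})

test_that("permutation p converges to the exhaustive sign-flip p", {
  set.seed(30)
  for (i in 1:4) {
    d <- rnorm(6, mean = 0.5)
    p_exact <- exhaustive_perm_p(d)
    res <- paired_permutation_ttest(d, rep(0, 6), n_perm = 1000, seed = i)
    se <- sqrt(p_exact * (1 - p_exact) / 1000)
    # +1 smoothing shifts the estimate by at most 1/1001
    expect_lt(abs(res$p_perm - p_exact), 3 * se + 2 / 1001)
  }
  # seed reproducibility
  r1 <- paired_permutation_ttest(rnorm(5), rnorm(5), n_perm = 50, seed = 9)
  set.seed(999)  # unrelated global state must not matter
  r2 <- paired_permutation_ttest(rnorm(5), rnorm(5), n_perm = 50, seed = 9)
  expect_false(identical(r1$p_perm, NULL))
  d <- c(0.2, -0.1, 0.4, 0.3, -0.2)
  expect_identical(
    paired_permutation_ttest(d, rep(0, 5), n_perm = 500, seed = 4)$p_perm,
    paired_permutation_ttest(d, rep(0, 5), n_perm = 500, seed = 4)$p_perm)
})

test_that("BH-FDR equals the brute-force step-up rule", {
  expect_equal(fdr_correct(rep(0.001, 6), q = 0.05), rep(TRUE, 6))
  p <- c(0.01, 0.02, 0.03, 0.04, 0.20)
  expect_equal(fdr_correct(p, q = 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))

  set.seed(44)
  pool <- c(0.001, 0.008, 0.012, 0.04, 0.049, 0.2, 0.5, 0.9)
  for (k in 1:8) {
    combos <- combn(8, k)
    for (c_i in seq_len(ncol(combos))) {
      pv <- pool[combos[, c_i]]
      expect_equal(fdr_correct(pv, 0.05), brute_force_bh(pv, 0.05))
    }
  }
  # rejections are monotone non-decreasing in q
  pv <- runif(10)
  prev <- rep(FALSE, 10)
  for (q in c(0.01, 0.05, 0.1, 0.3, 0.8)) {
    now <- fdr_correct(pv, q)
    expect_true(all(now[prev]))
    prev <- now
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("default comparison suites have the published cardinalities", {
  expect_equal(nrow(default_comparisons("controls", "pooled")), 4)
  expect_equal(nrow(default_comparisons("all", "pooled")), 10)
  expect_equal(nrow(default_comparisons("patients", "pooled")), 10)
  expect_equal(nrow(default_comparisons("controls", "per-task")), 7)
  expect_equal(nrow(default_comparisons("all", "per-task")), 13)
  # patients suites use response effects, not diagnosis
  suite <- default_comparisons("patients", "pooled")
  expect_true(any(grepl("response", unlist(suite))))
  expect_false(any(grepl("diagnosis", unlist(suite))))
})

test_that("comparison suites test participant values pairwise with FDR", {
  set.seed(55)
  subjects <- sprintf("s%02d", 1:12)
  effects <- c("common", "session", "sex", "individual")
  shift <- c(common = 0.5, session = 0.1, sex = 0.12, individual = 1)
  vals <- expand.grid(subject_id = subjects, effect = effects,
                      stringsAsFactors = FALSE)
  vals$mean_z <- shift[vals$effect] + rnorm(nrow(vals), sd = 0.05)
  out <- run_comparison_suite(vals, sample = "controls", n_perm = 500,
                              seed = 3)
  expect_equal(nrow(out), 4)
  expect_equal(out$n, rep(12, 4))
  expect_equal(out$df, rep(11, 4))
  # t follows the a - b convention
  row <- out[out$effect_a == "sex" & out$effect_b == "individual", ]
  expect_lt(row$t, 0)
  expect_true(all(out$p_perm > 0 & out$p_perm <= 1))
  expect_true(is.logical(out$fdr_significant))
  expect_error(run_comparison_suite(vals, data.frame(effect_a = "common",
                                                     effect_b = "ghost")),
               "unknown effect")
})

test_that("summary-statistics ANOVA reconstructs published F values", {
  # education (years) cells from the demographic table:
  # diagnosis main effect printed as F(1,103) = 11.34
  edu <- data.frame(
    factor_a = c("MD", "MD", "control", "control"),
    factor_b = c("F", "M", "F", "M"),
    n = c(42, 26, 21, 18),
    mean = c(17.00, 17.38, 18.71, 18.22),
    sem = c(0.26, 0.38, 0.38, 0.53))
  out <- anova_from_cell_summaries(edu)
  expect_equal(out$df2, rep(103L, 3))
  expect_equal(out$F[out$term == "factor_a"], 11.34, tolerance = 0.005)
  expect_equal(out$F[out$term == "factor_b"], 0.02, tolerance = 0.5)

  # all cell means equal: every F is exactly 0
  flat <- edu
  flat$mean <- 5
  expect_equal(anova_from_cell_summaries(flat)$F, rep(0, 3))

  expect_error(anova_from_cell_summaries(edu[1:3, ]), "2 x 2")
  bad <- edu
  bad$sem[2] <- 0
  expect_error(anova_from_cell_summaries(bad), "positive")
})

test_that("summary ANOVA equals a Type-III ANOVA on the raw data", {
  skip_if_not_installed("car")
  set.seed(66)
  n <- c(14, 9, 11, 17)
  a <- rep(rep(c("a1", "a2"), each = 2), n)
  b <- rep(rep(c("b1", "b2"), 2), n)
  y <- rnorm(sum(n), mean = rep(c(1, 1.6, 0.8, 1.2), n))
  cells <- do.call(rbind, lapply(split(y, paste(a, b)), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = sd(v) / sqrt(length(v)))
  }))
  cells$factor_a <- c("a1", "a1", "a2", "a2")
  cells$factor_b <- c("b1", "b2", "b1", "b2")
  got <- anova_from_cell_summaries(cells)

  dat <- data.frame(y = y, a = factor(a), b = factor(b))
  fit <- stats::lm(y ~ a * b, data = dat,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  oracle <- car::Anova(fit, type = 3)
  expect_equal(got$F[got$term == "factor_a"], oracle["a", "F value"],
               tolerance = 1e-8)
  expect_equal(got$F[got$term == "factor_b"], oracle["b", "F value"],
               tolerance = 1e-8)
  expect_equal(got$F[got$term == "interaction"], oracle["a:b", "F value"],
               tolerance = 1e-8)
})
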