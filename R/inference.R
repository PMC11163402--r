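# Within-subject permutation inference, FDR correction, and the
# summary-statistics two-way ANOVA.

#' Within-subject sign-flip permutation paired t-test
#'
#' Dependent-samples t-test on the per-participant paired differences
#' `a - b`, with significance from a sign-flip permutation distribution:
#' each permutation independently swaps the two values within each
#' participant, equivalent to flipping the sign of that participant's
#' difference. The two-sided permutation p-value is smoothed with the
#' identity permutation, p = (1 + #\{|t*| >= |t|\}) / (1 + n_perm), so it
#' is never exactly zero. Cohen's d is the paired standardized mean
#' difference, mean(a - b) / sd(a - b).
#'
#' @param a,b paired per-participant values (equal length >= 3). Pairs
#'   with a missing value are dropped listwise.
#' @param n_perm number of permutations (the classic choice is 1000).
#' @param seed integer seed for the permutation draws.
#' @return list of class `perm_test_result`: `n`, `t`, `df` (= n - 1),
#'   `sd_diff`, `p_perm`, `cohens_d`, `degenerate`. When all differences
#'   are identical (zero variance) the result is flagged degenerate and
#'   `t`/`p_perm` are `NA`.
#' @export
#' @examples
#' paired_permutation_ttest(c(1, 2, 4), c(0, 1, 1), n_perm = 200, seed = 1)
paired_permutation_ttest <- function(a, b, n_perm = 1000, seed = 1L) {
  if (length(a) != length(b)) stop_fc("a and b must have equal length")
  keep <- stats::complete.cases(a, b)
  d <- (a - b)[keep]
  n <- length(d)
  if (n < 3) stop_fc("need at least 3 complete pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(structure(list(n = n, t = NA_real_, df = n - 1L, sd_diff = 0,
                          p_perm = NA_real_, cohens_d = NA_real_,
                          degenerate = TRUE),
                     class = "perm_test_result"))
  }
  t_obs <- mean(d) / (sd_d / sqrt(n))
  sum_d2 <- sum(d^2)
  t_star <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    m_star <- as.vector(signs %*% d) / n
    # sum((s*d)^2) == sum(d^2) for sign flips, so the permuted sd is
    # available in closed form
    sd_star <- sqrt(pmax(sum_d2 - n * m_star^2, 0) / (n - 1))
    m_star / (sd_star / sqrt(n))
  })
  # tolerance guards tied |t*| values (e.g. the identity flip) against
  # losing the tie to floating-point noise
  p <- (1 + sum(abs(t_star) >= abs(t_obs) - 1e-8)) / (1 + n_perm)
  structure(list(n = n, t = t_obs, df = n - 1L, sd_diff = sd_d,
                 p_perm = p, cohens_d = mean(d) / sd_d, degenerate = FALSE),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate paired test (zero-variance differences), n =", x$n, "\n")
  } else {
    cat(sprintf("t(%d) = %.3f, sd(diff) = %.4f, perm p = %.4g, d = %.3f\n",
                x$df, x$t, x$sd_diff, x$p_perm, x$cohens_d))
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up control of the false discovery rate at level `q` within one
#' comparison family. Missing p-values propagate as `NA` flags.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical vector of rejections.
#' @export
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.04, 0.20), q = 0.05)
fdr_correct <- function(p_values, q = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop_fc("p-values must lie in [0, 1]")
  }
  out <- rep(NA, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH") <= q
  out
}

#' Default comparison ladder for a sample and mode
#'
#' Replicates the published comparison suites: each effect against its
#' baseline and against the other effects of the same type. Controls-only
#' pooled analyses yield 4 comparisons; the combined and patients-only
#' samples yield 10 (diagnosis effects replaced by response effects for
#' patients). Per-task (exploratory) analyses add the three
#' within-participant comparisons (individual vs individual-session,
#' individual vs individual-task, individual-session vs individual-task).
#'
#' @param sample `"all"`, `"controls"`, or `"patients"`.
#' @param mode `"pooled"` or `"per-task"`.
#' @return data.frame with columns `effect_a`, `effect_b`.
#' @export
default_comparisons <- function(sample = c("all", "controls", "patients"),
                                mode = c("pooled", "per-task")) {
  sample <- match.arg(sample)
  mode <- match.arg(mode)
  pairs <- if (sample == "controls") {
    list(c("common", "session"), c("common", "sex"), c("session", "sex"),
         c("sex", "individual"))
  } else {
    g <- if (sample == "all") "diagnosis" else "response"
    gs <- paste0(g, "_x_session")
    gx <- paste0(g, "_x_sex")
    list(c("common", g), c("common", "session"), c("common", "sex"),
         c(g, "session"), c(g, "sex"), c("session", "sex"),
         c(g, gs), c("sex", gx), c(gs, gx), c(gx, "individual"))
  }
  if (mode == "per-task") {
    pairs <- c(pairs, list(c("individual", "individual_x_session"),
                           c("individual", "individual_x_task"),
                           c("individual_x_session", "individual_x_task")))
  }
  data.frame(effect_a = vapply(pairs, `[`, character(1), 1),
             effect_b = vapply(pairs, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Run a suite of paired permutation comparisons with FDR correction
#'
#' For each comparison, the participants' per-effect average similarities
#' are paired and tested with [paired_permutation_ttest()] (t and d both
#' computed on `effect_a - effect_b`); Benjamini-Hochberg FDR is applied
#' across the whole suite, which constitutes one comparison family.
#'
#' @param participant_values long data.frame from
#'   [participant_effect_table()]: `subject_id`, `effect`, `mean_z`.
#' @param comparisons data.frame with `effect_a`, `effect_b`; defaults to
#'   the ladder for the given sample/mode (see [default_comparisons()]).
#' @param sample,mode used to build the default suite.
#' @param n_perm,seed,q permutation count, seed, FDR level. Each
#'   comparison uses its own seed derived from `seed`.
#' @return data.frame with one row per comparison: `effect_a`, `effect_b`,
#'   `n`, `t`, `df`, `sd_diff`, `p_perm`, `cohens_d`, `fdr_significant`.
#' @export
run_comparison_suite <- function(participant_values, comparisons = NULL,
                                 sample = "all", mode = "pooled",
                                 n_perm = 1000, seed = 1L, q = 0.05) {
  comparisons <- comparisons %||% default_comparisons(sample, mode)
  effects <- unique(participant_values$effect)
  missing <- setdiff(unique(unlist(comparisons[c("effect_a", "effect_b")])),
                     effects)
  if (length(missing)) {
    stop_fc("comparison refers to unknown effect(s): ",
            paste(missing, collapse = ", "))
  }
  wide <- stats::reshape(participant_values, idvar = "subject_id",
                         timevar = "effect", direction = "wide")
  names(wide) <- sub("^mean_z\\.", "", names(wide))
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    ea <- comparisons$effect_a[i]
    eb <- comparisons$effect_b[i]
    res <- paired_permutation_ttest(wide[[ea]], wide[[eb]],
                                    n_perm = n_perm, seed = seed + i)
    data.frame(effect_a = ea, effect_b = eb, n = res$n, t = res$t,
               df = res$df, sd_diff = res$sd_diff, p_perm = res$p_perm,
               cohens_d = res$cohens_d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_significant <- fdr_correct(out$p_perm, q = q)
  out
}

#' Two-way ANOVA from printed cell summaries
#'
#' Reconstructs an unbalanced 2 x 2 between-subjects ANOVA from the cell
#' means, standard errors of the mean, and cell sizes that published
#' tables report. The within-cell sum of squares is recovered from the
#' SEMs (sd = sem * sqrt(n)); the two main effects and the interaction
#' are tested with unweighted-marginal-means (Type III) contrasts on the
#' cell means, each on 1 and (sum of n) - 4 degrees of freedom.
#'
#' @param cells data.frame with one row per cell and columns `factor_a`,
#'   `factor_b` (two levels each), `n` (>= 2), `mean`, `sem` (> 0).
#' @return data.frame with rows for factor A, factor B and the
#'   interaction: `term`, `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' cells <- data.frame(
#'   factor_a = c("MD", "MD", "control", "control"),
#'   factor_b = c("F", "M", "F", "M"),
#'   n = c(42, 26, 21, 18),
#'   mean = c(17.00, 17.38, 18.71, 18.22),
#'   sem = c(0.26, 0.38, 0.38, 0.53))
#' anova_from_cell_summaries(cells)  # diagnosis F ~ 11.34
anova_from_cell_summaries <- function(cells) {
  need <- c("factor_a", "factor_b", "n", "mean", "sem")
  if (!all(need %in% names(cells))) {
    stop_fc("cells must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(cells) != 4 ||
      length(unique(cells$factor_a)) != 2 ||
      length(unique(cells$factor_b)) != 2 ||
      anyDuplicated(cells[c("factor_a", "factor_b")])) {
    stop_fc("cells must form a complete 2 x 2 grid")
  }
  if (any(cells$n < 2)) stop_fc("every cell needs n >= 2")
  if (any(cells$sem <= 0)) stop_fc("SEMs must be positive")

  a_lv <- unique(cells$factor_a)
  b_lv <- unique(cells$factor_b)
  ord <- order(match(cells$factor_a, a_lv), match(cells$factor_b, b_lv))
  cells <- cells[ord, ]  # A1B1, A1B2, A2B1, A2B2

  sd <- cells$sem * sqrt(cells$n)
  ss_within <- sum((cells$n - 1) * sd^2)
  df_error <- sum(cells$n) - 4L
  ms_within <- ss_within / df_error

  contrast_F <- function(cw) {
    (sum(cw * cells$mean))^2 / (ms_within * sum(cw^2 / cells$n))
  }
  Fs <- c(contrast_F(c(0.5, 0.5, -0.5, -0.5)),
          contrast_F(c(0.5, -0.5, 0.5, -0.5)),
          contrast_F(c(0.5, -0.5, -0.5, 0.5)))
  data.frame(
    term = c("factor_a", "factor_b", "interaction"),
    F = Fs, df1 = 1L, df2 = df_error,
    p = stats::pf(Fs, 1, df_error, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}
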