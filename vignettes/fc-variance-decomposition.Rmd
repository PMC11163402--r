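---
title: "Decomposing variance in whole-brain functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing variance in whole-brain functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdecomp)
```

## The model

`fcdecomp` quantifies how much of the variation in whole-brain functional
connectivity (FC) is shared across everyone, tied to group membership,
tied to measurement occasion, or unique to individual people. The
analysis object is the *similarity matrix*: every analysis unit (a
participant-session with tasks concatenated, or a
participant-session-task in per-task mode) contributes one FC vector —
the Fisher-z upper triangle of its ROI-by-ROI Pearson correlation matrix
— and the similarity matrix holds the Fisher-z correlations between all
pairs of these vectors.

The central assumption is that sources of variance leave additive
signatures in similarity space: if some component of connectivity is
shared by, say, all female participants, then the cells of the
similarity matrix that pair two female participants will be elevated on
average. Each effect is therefore defined as the mean over a structured
cell subset (its mask):

* **common** — all off-diagonal cells;
* **session** — same session, different participant;
* **sex**, **diagnosis**, **response** — same group level, different
  participant;
* **group × session**, **group × sex** — same level on both factors,
  different participant;
* **individual** — same participant, different session (in per-task
  mode: also different task);
* **individual × session**, **individual × task** — within-participant
  cells sharing the session or the task (per-task mode only; the three
  within-participant masks partition the within-participant block).

Masks are symmetric, exclude the diagonal (a unit's similarity with
itself is 1 by definition and carries no information), and each
unordered pair of units is counted once.

A raw mask average is not interpretable on its own because every pair of
units shares the common component. Each effect is therefore measured
against a *baseline*: zero for the common effect; the common average for
the session and group main effects; the larger of the two constituent
main effects for each group interaction; the largest of all main and
group-interaction averages for the individual effect; and the individual
average for the individual-session / individual-task interactions.
Corrected magnitudes, `max(raw - baseline, 0)`, are normalized to
percent of their sum. The floor at zero means an effect that does not
exceed its baseline simply contributes nothing; the normalized values
then partition 100% of the *unique* explained similarity.

Two mask-design points were genuinely open and are worth stating:

* Group main-effect and interaction masks are restricted to
  different-participant pairs, so a participant's group average reflects
  their similarity to *other* members of their group. The alternative
  (keeping within-participant cells, as the common mask does) is
  available via `include_within_individual_in_group_masks = TRUE` in
  `make_effect_masks()`. The session mask always excludes
  within-participant cells: time-specific similarity is a claim about
  agreement *across* people at an occasion. A visible consequence is
  that the session average can fall below the common average — the
  common mask contains the high within-participant cells and the
  session mask does not.
* In per-task mode the individual effect uses the "pure" mask (different
  session *and* different task), so the three within-participant effects
  are disjoint and jointly cover the within-participant block. Folding
  same-task or same-session cells into the individual mask would double
  count them against the interaction masks.

## Inference

Per-participant effect averages (the mask mean restricted to the rows of
one participant's units) feed dependent-samples t-tests with sign-flip
permutation: each permutation independently swaps the two compared
values within a participant, equivalent to flipping the sign of that
participant's difference. We use the two-sided, add-one-smoothed
p-value `p = (1 + #{|t*| >= |t_obs|}) / (1 + n_perm)`; smoothing keeps p
away from zero and makes the test mildly conservative, and tied `|t*|`
values are counted with a `1e-8` tolerance so the identity flip never
loses its tie to floating-point noise. The t statistic and Cohen's d are
both computed on `effect_a - effect_b` as listed in the comparison
table, so their signs always agree. Benjamini–Hochberg FDR (via
`stats::p.adjust`) is applied across each suite — 4 comparisons for a
controls-only pooled analysis, 10 for the two-group and patients-only
suites, plus 3 within-participant comparisons in per-task mode — which
constitutes one family.

The package also reconstructs two-way ANOVAs from printed cell summaries
(mean, SEM, n per cell of an unbalanced 2 × 2): within-cell sums of
squares from `sd = sem * sqrt(n)`, and unweighted-marginal-means
(Type III) contrasts on the cell means. For a 2 × 2 this is exactly the
Type-III test a sum-contrast linear model would give, which the test
suite verifies against `car::Anova` on raw data.

## Preparation choices

* **FIR task regression.** One block of `lag_samples` lagged 0/1
  indicator columns per event type (default 10 samples, about 20 s at
  TR = 2 s), event onsets mapped to samples by `floor(onset / TR)`
  (0-based; no sub-TR convention is imposed). Event durations are not
  modeled — the lag window absorbs block extent. Collinearity is handled
  by dropping rank-deficient columns found by pivoted QR at relative
  tolerance `1e-8`; dropped columns are recorded on the result. No
  intercept is added: demeaning is an explicit separate step, and the
  two operations commute when the design columns are themselves
  centered (a property test).
* **Concatenation.** Pooled mode concatenates each participant-session's
  runs in a fixed task order (rest, go/no-go, anhedonia; other labels
  keep manifest order) before estimating FC, giving roughly 30 minutes
  of data per unit under the default durations.
* **Fisher-z clipping.** Correlations are clipped to ±(1 − 1e-7) before
  `atanh`. Duplicate series would otherwise produce infinite z values
  that poison every average they enter; the clip maps them to ≈ 8.1,
  large but finite.
* **Degenerate inputs.** Zero-variance ROIs and zero-variance FC vectors
  are errors naming the offender; an empty mask is an error; a
  participant with no mask cells in their rows yields `NA` with a
  warning and is dropped listwise from affected comparisons; a
  comparison with zero-variance differences is flagged degenerate and
  excluded from FDR.

## The synthetic generator

The generator exists so every stage can be checked against a known
answer. For each factor level (one common level, two diagnoses, two
sexes, three response levels including `not_applicable`, each session,
each task, each individual, each individual-session cell) it draws an
i.i.d. standard-normal pattern over the `P = R(R-1)/2` ROI pairs and
scales it by the component's standard-deviation weight. A unit's latent
FC vector is the sum of the patterns it shares plus a fresh noise
pattern. Giving controls a real `not_applicable` response pattern keeps
every unit's total latent variance identical, so the expected
correlation between any two units is simply

> (sum of squared weights of shared components) /
> (sum of squared weights of all components, noise included),

and the expected mask average is the cell-count-weighted mean of the
Fisher z of these pairwise expectations (`ground_truth()`,
`expected_effect_similarity()`). Latent vectors are emitted directly on
the z scale in vector mode: the decomposition depends only on
correlations between vectors, so a tanh round-trip would add nothing.

Default weights (common 1, individual 0.95, diagnosis 0.1, sex 0.1,
session 0.05, noise 0.35, others 0) encode the regime the method is
designed to resolve — strong common and individual structure, small
group effects — and the default design mirrors the emulated study:
42/26 female/male patients with 33 treatment responders, 21/18
female/male controls, sessions baseline/week-2/week-8, runs of 588 s
(rest), 588 s (go/no-go), and 690 s (anhedonia) at TR = 2 s. The default
`n_rois = 60` keeps test-scale simulations light; 326 mirrors the
emulated parcellation. MADRS trajectories are drawn so that exactly
`n_responders` patients show a strictly >50% decrease from baseline to
week 8 (a decrease of exactly 50% is a nonresponse, matching the strict
inequality in the responder rule); patient baselines are truncated
normal (mean 29, sd 3, minimum 24, the trial entry criterion).

In time-series mode each unit's latent vector is mapped to a target
correlation matrix by `tanh(0.25 * z)` (scale chosen so typical latent
values land in a realistic FC range), symmetrized with unit diagonal,
and projected to the nearest positive-definite correlation matrix by
eigenvalue clipping at `1e-6` followed by a diagonal rescale — a
deterministic, standard projection. Gaussian series with exactly that
population correlation are drawn through the Cholesky factor; task runs
can receive an injected task-locked response (a smooth gamma-shaped FIR
kernel per event type with random ROI loadings) on a deterministic
event schedule, which is what lets the FIR-regression stage be tested:
residual FC must be closer (Frobenius) to the generating background
correlation than raw FC is.

What the generator does *not* emulate: voxel-level images, head motion
and censoring, scanner/site effects, hemodynamic nonlinearity, and
autocorrelated BOLD noise (samples are temporally white). Passing tests
therefore demonstrate that the *pipeline arithmetic* is right and that
the decomposition recovers known variance structure — not that the
method is robust to real-data artifacts, which upstream preprocessing
is assumed to have handled.

## Reliability

Split-half reliability cuts each participant's runs into whole 150 s
epochs (75 samples at TR = 2 s; trailing remainders are discarded so
segments stay homogeneous) and splits them into two pools, as evenly as
possible within each run, with an odd segment going to the currently
smaller pool and a rejection step ensuring both pools contain every task
and both temporal run-halves — the package's reading of "pseudorandomly
mixed" segment composition. The curve correlates FC from the full
reference pool with FC from increasing numbers of test-pool segments
(nested, in a seeded random order). Under the default study durations
whole-epoch division yields 30 segments per participant, 15 per pool,
so the default grid runs 5–35 minutes. Note the curve cannot reach
exactly 1 even with zero generator noise: finite segments estimate FC
with sampling error; the relevant property (verified in the tests) is
that the curve is non-decreasing in data amount and rises toward 1 as
generator noise shrinks.

## Numerical and reproducibility choices

All randomness flows from one integer seed: the cohort, each latent
component, unit noise, the time-series draws, segment assignment, and
every permutation test use their own substream derived from it by fixed
offsets, so turning one component's weight to zero never changes
another's draw, and rerunning a pipeline config writes byte-identical
TSV outputs. Package functions save and restore the caller's RNG state.

Monte-Carlo tolerances in the parameter-recovery tests use a
delete-one-block jackknife over the pair dimension
(`effect_average_mc_se()`): every source of generator randomness is
independent across ROI pairs, so deleting interleaved blocks of pairs
captures both the per-cell correlation noise and the pattern-norm
fluctuation that is shared across all cells. A jackknife over
participants would miss the latter and understate the Monte-Carlo error
several-fold.

Problem sizes used by the test suite, chosen to exercise each property
at the smallest scale where its statistics are stable: parameter
recovery on the full 107-participant design with `P = 10011`
(`n_rois = 142`); permutation calibration with 39 participants, 500
replicates of 500 permutations; reliability on 4 controls, 12 ROIs, 10
seeds; exhaustive oracles (pair loops, 64-flip permutation
distributions, all-subset FDR) on instances of at most 12 units or 8
p-values.

## Limitations

The decomposition is relative: it partitions the similarity explained by
the modeled effects and cannot flag a source of variance that was never
given a mask. Group effects are categorical; continuous moderators
(age, symptom severity) are out of scope. Region-level magnitudes are
descriptive — no inference is performed on them. The summary-statistics
ANOVA is exact only for the unbalanced 2 × 2 design it targets. And the
synthetic generator validates arithmetic, not robustness to artifacts
absent from its model (see above).
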