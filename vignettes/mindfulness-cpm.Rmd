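---
title: "Predicting trait mindfulness from functional connectomes with mindcpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting trait mindfulness from functional connectomes with mindcpm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(mindcpm)
```

## The problem and the model

Trait mindfulness is usually measured with the Five Facet Mindfulness
Questionnaire (FFMQ): 39 five-point items yielding the facets Acting with
Awareness (AA), Non-judging (NJ), Non-reactivity (NR), Describing (D) and
Observing (O), a total score (range 39–195), and a total without the
Observing facet, whose validity is debated. `mindcpm` implements
connectome-based predictive modeling (CPM) of these scores from resting-state
functional connectomes, together with everything such an analysis needs
around it: questionnaire scoring, head-motion quality control, permutation
inference, frozen-model external validation across scanners, mask overlap and
split-half stability analyses, and a synthetic multi-site cohort generator
that makes the whole pipeline testable without any restricted data.

A connectome here is the matrix of Fisher z-transformed Pearson correlations
between the mean BOLD timeseries of every pair of atlas nodes (any node
count; 268-node parcellations are typical). Each unique node pair is an
*edge*; all edge containers use one canonical ordering (upper triangle,
row-major, `edge_index()`), so masks and exports can never silently
misalign.

CPM proceeds in four steps inside every cross-validation fold:

1. **Screening.** Every edge is correlated with the behavioral score across
   training subjects. Edges with positive r and two-tailed p below the
   screening threshold (default 0.01, exact t transform with n − 2 df) form
   the *positive network*; negative-r edges below threshold form the
   *negative network*. The masks are binary and disjoint by construction.
2. **Strength.** Each subject's edge values are summed within each mask;
   the *combined* strength is the positive sum minus the negative sum.
3. **Linear model.** Ordinary least squares of the score on strength,
   `score = beta * strength + c`, fitted on training subjects for all three
   strength variants (combined, positive-only, negative-only).
4. **Prediction.** Held-out subjects are predicted from their own strengths.
   The headline statistic is the Pearson correlation between predicted and
   observed scores; the combined variant is the default report and the
   single-network variants are always recorded alongside.

Group-level inference uses a permutation test: the entire cross-validated
procedure — screening included — is re-run on score vectors permuted across
subjects (default 1000 iterations), and the p-value is the fraction of null
correlations at or above the observed one (`count / n_perm`; the
`(count + 1)/(n + 1)` estimator is available behind a flag but off by
default, matching the plain probability definition). Candidate models are
selected for external validation when their permutation p is strictly below
0.05, uncorrected. The final exported model is fitted on *all* training
subjects (a "single fold") and is then frozen: applying it to another
dataset only masks, sums, and applies the stored line — it never re-screens.

## A worked example on synthetic data

```{r train}
cfg <- cohort_config(
  n_nodes = 30,
  sites = list(train = list(n = 150, score_mean = 134.8, score_sd = 17.8),
               test  = list(n = 100, score_mean = 126.8, score_sd = 17.4)),
  planted_positive = 10, planted_negative = 10, effect_r = 0.3,
  seed = 42
)
cohort <- generate_cohort(cfg)
train <- cohort$phenotype$site == "train"

cv <- cpm_cv(cohort$phenotype[train, ], cohort$edges[train, ], "total")
cv
perm <- cpm_permute(cohort$phenotype[train, ], cohort$edges[train, ],
                    "total", n_perm = 100, seed = 1)
perm
model <- cpm_fit(cohort$phenotype[train, ], cohort$edges[train, ], "total")
model
```

```{r validate}
ev <- cpm_apply(model, cohort$phenotype[!train, ], cohort$edges[!train, ],
                covariates = "mean_fd")
ev
autoplot(ev)
```

Anatomy summaries work from the model's masks and a node-to-network label
table (a label scheme is an *input*, not hard-coded; the packaged
`washu10_labels_synthetic100.csv` is an illustrative random assignment for
demos only):

```{r anatomy, eval = FALSE}
deg <- node_degree(model)
labels <- read_network_labels(system.file(
  "extdata", "washu10_labels_synthetic100.csv", package = "mindcpm"))
plot_network_counts(network_pair_counts(model$negative, labels$network[1:30]))
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.01 | Two-tailed edge-screening p threshold; strict (`p < threshold`), ties excluded. |
| `cv`, `k` | `"loocv"`, 10 | Leave-one-out by default; k-fold uses a seeded uniform shuffle into near-equal folds, recorded in the result. |
| `n_perm` | 1000 | Permutation iterations; the attainable p resolution is `1/n_perm`. |
| `alpha` | 0.05 | Strict model-selection threshold on the permutation p. |
| `fd_threshold` | 0.15 mm | Mean framewise displacement above which a run/subject is excluded; strictly greater, so a value exactly at 0.15 is retained. |
| `run_level` | `FALSE` | Multi-run exclusion mode: drop runs first, then subjects by the mean of mean FD across runs. |

Two motion-exclusion readings exist for the subject-level decision in
run-level mode, because "the mean across runs" does not say which runs. The
default uses the mean over *retained* runs (a subject whose one bad run was
dropped is judged by the data that remain); `subject_mean = "all"` exposes
the alternative, and the exclusion log records every decision with its FD
value so either choice is auditable.

Covariate control (head motion, asthma or clinical status, scan-resolution
indicators, per-site score means) happens at *evaluation*, as partial
correlations between predicted and observed scores — never inside the
screening step.

## The synthetic cohort generator

`generate_cohort()` emulates the features of a multi-site mindfulness study
that the analysis actually relies on:

- **Sites.** Three sites by default, with Gaussian total-score distributions
  matching the published site summaries (means 134.8, 126.8, 107.2; SDs
  17.8, 17.4, 11.3) and per-site edge offsets emulating scanner shifts.
- **Facets.** Five equicorrelated facet latents (default inter-facet
  correlation 0.4, below the < 0.5 reported for real subscales), scaled so
  the facet sums reproduce the configured site totals exactly.
- **Signal.** Planted positive and negative edge sets follow
  `a * z(score) + noise` with `a = effect_r / sqrt(1 - effect_r^2)`, giving
  an expected edge–score correlation of `effect_r` (default 0.3). The
  default is deliberately stronger than the weak per-edge effects implied by
  published prediction correlations near 0.2: it keeps recovery properties
  testable at n = 200. A weak-effect exploration simply passes a smaller
  `effect_r`.
- **Motion.** `fd_score_r` and `confound_strength` couple FD to the score
  and to the planted edges, creating a genuine motion confound whose removal
  by partial correlation is itself tested.
- **Runs.** With `n_runs > 1`, run matrices add independent Gaussian run
  noise calibrated so a null edge's split-half reliability between two-run
  averages equals `edge_reliability` (default 0.4); planted edges are more
  reliable because they share the trait-driven component — exactly the
  aggregation property the stability analysis probes.
- **Timeseries mode.** `generate_timeseries_cohort()` realizes the same
  planted structure as raw node signals by sampling from per-subject node
  covariances (planted pairs are node-disjoint so the covariance is positive
  definite by construction), exercising the `build_connectome()` path end to
  end at reduced power.

What the generator does **not** emulate: temporal autocorrelation of BOLD,
scanner-specific artifact structure, atlas geometry, non-Gaussian score
distributions (scores are continuous by default; an item-level pattern can
be scored through `score_ffmq()` separately), and realistic edge dependence
beyond the planted signal. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under the assumed model — not that
real connectomes predict real questionnaires.

## Numerical choices

- Edge p-values use the exact t transform, never a normal approximation, so
  the selection boundary is reproducible at small n (the minimal selectable
  |r| at n = 188 is ≈ 0.187 at p < 0.01).
- A correlation with |r| ≥ 1 − 1e−12 in `build_connectome()` is an error,
  not a clipped value: perfect correlations have no finite Fisher z and
  almost always indicate a degenerate fixture.
- Zero-variance edges are silently ineligible for selection (counted and
  warned about) rather than fatal, since degenerate fixtures can produce
  constant edges.
- The LOOCV engine computes each fold's screening correlations by downdating
  full-sample sums (one-subject-removed sufficient statistics) and fits all
  fold models in closed form; an independent per-fold `cor()` computation
  verifies equality in the tests. Folds whose training strength is
  (numerically) constant — e.g. both masks empty — predict the training mean
  and are logged.
- A constant prediction vector has an undefined Pearson correlation; the
  package reports 0 in that case, which keeps permutation counting defined
  and is the honest summary of a prediction that carries no information.
- Run averaging operates on Fisher-z matrices (the stored representation),
  not back-transformed correlations.
- The overlap percent denominator is the *sum* of the two mask sizes, the
  only convention consistent with both published example values (20 shared
  of 328 + 664 → 2.02%; 58 of 758 + 628 → 4.18%). The overlap null shuffles
  both masks; shuffling one is distributionally equivalent.
- The stability null is one-sided (`P(null r >= r_split)`) by default,
  matching the "is the aggregate more stable than single edges" question;
  a two-sided option exists.

## Problem sizes in the test suite

The suite exercises calibration properties at reduced but statistically
adequate sizes, chosen once as part of the package's design: permutation
calibration uses 200 null cohorts of n = 60 subjects, 300 edges and 200
permutations; planted-edge recovery uses 20 seeds at n = 200 per site with a
100-node atlas and effect r = 0.3; stability uses four-run cohorts of n =
120 with 30 nodes. At these sizes the binomial uncertainty of the checked
rates is several times smaller than the acceptance bands.

## Known limitations

- Scores enter screening as given; confound regression *inside* the
  screening step (as some CPM variants do) is deliberately out of scope.
- Upstream fMRI preprocessing, parcellation and FD computation are out of
  scope: the package consumes node timeseries or connectivity matrices plus
  per-run mean FD values.
- Elastic-net, basis-set and tangent-space alternatives to strength
  aggregation are extension points, not implemented.
- The packaged node-to-network labelling is illustrative; real analyses
  must supply their atlas's label table.
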