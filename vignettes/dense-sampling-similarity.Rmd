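---
title: "Within- and between-person similarity of densely sampled activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within- and between-person similarity of densely sampled activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Precision (dense-sampling) fMRI studies scan a small number of people many
times in order to obtain person-level brain measurements that are reliable
enough to interpret individually. `densim` implements the statistical
pipeline for one such design: two (or more) participants each complete a
large battery of cognitive-control tasks twice on separate days, yielding a
contrast effect-size overlay per task contrast per administration on a
common cortical surface mesh (fsaverage7-style, 163,842 vertices per
hemisphere). The scientific question is whether task-evoked activation
patterns are *person-specific and reliable*: more similar across sessions
within a person than between people, even after anatomical similarity is
taken into account.

The pipeline has five stages:

1. **Matrix assembly.** Each task's two administrations are randomly split
   into `Set1` and `Set2` (a fair coin per subject x task, so neither set
   systematically contains later, more practiced sessions). Contrast
   overlays are concatenated into a vertex-by-contrast matrix per subject
   and set: left hemisphere rows first, then right, columns in catalog
   order (112 contrasts from 22 tasks by default). Anatomy (cortical
   thickness in mm, surface area in mm^2, curvature in 1/mm, standardized
   sulcal depth) is split by scan session parity — odd sessions to `Set1`,
   even to `Set2`, truncated to equal counts — giving vertex-by-session
   matrices. Vertices with a missing value in *any* matrix (in practice
   the medial wall) are removed everywhere.
2. **Per-vertex similarity.** At each kept vertex, the Pearson correlation
   of the `Set1` and `Set2` rows across the 112 contrasts (within-person,
   one value per subject, averaged as raw r), and of set-matched rows
   across subjects (between-person, averaged over unordered pairs x sets).
   The anatomical analogue correlates the paired session columns.
3. **Anatomical adjustment.** The within and between functional similarity
   vectors are stacked and regressed (OLS, intercept) on the four
   anatomical similarity vectors of matching vertex and kind. Residuals
   are divided by their sample standard deviation, and the within-minus-
   between mean difference of these standardized residuals is tested by
   shuffling the within/between labels (500,000 iterations in the
   reference analysis; configurable), with the plain proportion of
   as-or-more-extreme permuted differences as the p-value and a pooled-SD
   Cohen's d as the effect size.
4. **Whole-map similarity.** The same construction column-wise: one
   within- and one between-person score per contrast, compared with a
   paired t-test (df = K − 1 over K contrasts). A larger single-session
   cohort can serve as a between-person reference distribution, compared
   with a Welch t-test (unequal sizes and variances).
5. **Task profile.** Map-level scores are grouped by generating task;
   Welch's heteroscedastic one-way ANOVA tests whether similarity varies
   by task, and a per-task median table (median within, median between,
   and their difference) ranks tasks for individual-differences research.
   The Pearson correlation of the two median vectors summarizes how much
   reliable tasks also look alike across people.

## The synthetic-data generator

The raw imaging data behind the published analysis are not distributed, so
the package ships a variance-components simulator that makes every stage
testable against closed-form expectations. Per vertex `v`, contrast `c` of
task `t`, subject `i`, set `s`:

```
x(v,c,i,s) = g(v,c) + p(v,c,i) + e(v,c,i,s)
g ~ N(0, s2_shared(t));  p ~ N(0, s2_person(t));  e ~ N(0, s2_noise(t))
```

with `g` shared by everyone, `p` independent across subjects, and `e`
independent across sets. Anatomy follows the analogous model per measure
with one noise draw per scan session. Under this model the expected
within-person correlation across contrasts of one task is
`(s2_shared + s2_person) / (s2_shared + s2_person + s2_noise)` and the
between-person expectation replaces the numerator with `s2_shared`
(`expected_similarity()`), which is what the parameter-recovery tests
assert.

Deliberate simplifications:

* **No spatial autocorrelation.** Components are independent across
  vertices. Correlation statistics are invariant to spatial smoothness in
  expectation, and independence keeps the analytic expectations exact; but
  passing tests therefore say nothing about spatially clustered artifacts
  or smoothing-induced dependence between neighboring vertices in real
  data.
* **Task-specific, not contrast-specific, variances.** This is the
  minimal structure that produces task-level similarity differences. The
  default per-task profile is derived from the published per-task median
  table: shared variance set to the between-person median (floored at 0),
  person variance to the within-minus-between gap, session noise topping
  the total to 1. One task in that table has a within median slightly
  below its between median, which the model cannot represent; its person
  variance is floored at 0.
* **Uniformly random medial wall.** Missing vertices are drawn once per
  dataset and applied to every matrix, mirroring the fact that missingness
  is a property of the vertex, not of a particular matrix. Real medial
  walls are contiguous; since all statistics are computed per vertex or
  over the kept set, contiguity does not affect them.
* **Anatomy coupling.** `anatomy_coupling > 0` adds the thickness
  person-deviation into every contrast's person component with a unit
  alternating-sign loading across contrasts (a contrast-constant loading
  would vanish under the row-centering implicit in Pearson correlation).
  This raises effective person variance for functional data at vertices
  where a person's anatomy deviates most.

The default per-task contrast counts (5 per task, 6 for the two
multi-component batteries, totalling 112 over 22 tasks) are a package
convention: the published per-task breakdown of the 112 contrasts is in
supplementary material that is not machine-readable here, and only the
totals are constrained.

Seeding: one root seed drives deterministically derived sub-streams per
component (mask, shared maps, per-subject, per-subject-and-set, anatomy),
so a dataset is bit-reproducible from its config.

## Numerical and design choices

* **Raw-r averaging.** Within/between similarity vectors average plain
  correlations, matching the reference analysis; Fisher-z averaging is
  available (`fisher_z = TRUE`) but off by default.
* **Zero-variance rows/columns give `NA`**, never 0, and propagate into
  the complete-case handling of the regression stage with logged counts;
  nothing is imputed.
* **Set assignment granularity** is the task repetition (the test/retest
  administration), not the individual run of multi-run tasks: the
  split-half design pairs administrations, and per-run splitting would mix
  days within a set. A fixed repetition-to-set mapping
  (`identity_set_assignment()`) supports exact round-trips.
* **Session truncation, not padding**, when odd/even anatomy session
  counts differ: row-wise correlation needs equal-length paired vectors.
* **Permutation sidedness.** Two-sided (`|diff|` comparison) by default —
  the conservative reading of "as extreme or more extreme" — with a
  one-sided option. The p-value is the plain proportion; a `(b+1)/(m+1)`
  never-zero variant is available. Ties with the observed difference are
  counted as extreme (a `1e-12` relative tolerance absorbs float noise).
* **"Standardized" residuals** are raw OLS residuals divided by the
  sample SD of all residuals (the simplest reading); internally
  studentized residuals are available via `standardize = "studentized"`.
* **Welch unconditionally.** Both the ANOVA and the cohort comparison use
  heteroscedasticity-robust forms by default (the observed variance
  heterogeneity across tasks motivates this); classical equal-variance
  modes exist behind flags.
* **Median convention**: midpoint of the two central order statistics for
  even group sizes (the `stats::median` default). Emitted task tables are
  rounded to 2 decimals for display; internal values are full precision.
* **Cohort aggregation** of between-person scores defaults to one mean
  score per subject pair (`per_pair`), with `per_contrast` as the
  alternative; the published degrees of freedom for that comparison are
  not derivable from the text, so both structures are provided.
* **Overlay formats.** MGH/MGZ stores float32 (the format's definition);
  GIFTI (ASCII encoding) and dense TSV store full double precision.
  Vertex indices in all text outputs are 0-based.

## Known limitations

* **The label-shuffle permutation test is conservative.** Within- and
  between-person scores at the same vertex are computed from the same
  matrices and are therefore positively correlated whenever a shared group
  component exists (empirically r ≈ 0.3 at shared variance 0.2). The full
  shuffle treats all rows as exchangeable, which overstates the null
  variance of the mean difference, so the type-I error rate is *below*
  the nominal level (≈ 0.01 at α = 0.05 in null simulations with a
  realistic shared component) rather than equal to it. This is intrinsic
  to the published design — a paired/sign-flip permutation would be exact
  but is a different test. Rejections are therefore trustworthy; power is
  modestly understated.
* **Vertex-level anatomy similarity is noisy and near zero-mean** under
  session-independent anatomy noise: with only four paired sessions and
  all person/shared components constant within a row, row-centering leaves
  mostly noise. The anatomical regression is retained as specified, but in
  simulation its predictors carry little systematic signal; its efficacy
  (removing an anatomy-mediated gap) is exercised at the module level with
  directly constructed score vectors.
* The generator does not simulate hemodynamics, GLM fitting, spatial
  smoothness, or realistic cortical geometry; conclusions about those
  stages are out of scope.

## Problem sizes used in the shipped checks

The test suite and the acceptance script scale the study design down so
the whole battery runs in minutes: parameter-recovery runs use 5,000
vertices per hemisphere with the full 112-contrast catalog and 10,000
permutation iterations; null-calibration runs use 200 replicate datasets
of 500 vertices with 2,000 iterations each; kernel oracles use tiny
fixtures where exhaustive enumeration or closed forms are available. At
these sizes the Monte-Carlo error of a mean similarity is well under the
±0.03 tolerance used against the analytic expectations.

## A worked example

```{r, eval = FALSE}
library(densim)

specs <- default_task_specs(sigma2_shared = 0.25, sigma2_person = 0.25,
                            sigma2_noise = 0.5)
cfg <- sim_config(n_vertices_per_hemisphere = 1000, task_specs = specs,
                  medial_mask_fraction = 0.1, seed = 42)
pc <- pipeline_config(sim = cfg, n_permutation_iterations = 10000,
                      permutation_seed = 1, out_dir = "densim_report")
res <- run_full_pipeline(pc)
res$adjust$permutation   # within > between after anatomical adjustment
res$profile$table        # per-task median table
```
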