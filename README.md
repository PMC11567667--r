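# seqprime

Design generation and analysis for statistical-learning experiments built on
**overlapping object triplets**: two sequences ABC₁ and ABC₂ that share their
A→B stem, so that C₁ and C₂ are never seen together yet share their entire
predictive context. The package is aimed at cognitive-neuroscience groups who
want to (a) generate fully constrained trial orders for this paradigm, (b)
simulate complete synthetic cohorts with known ground truth, and (c) run the
behavioral, multivoxel pattern-similarity and resting-state analysis chain
that links implicit behavioral integration of C₁/C₂ to neural change scores.

## What it computes

**Design generator.** Pseudo-randomized orders for four task phases under the
paradigm's hard constraints — learning (every A followed by its own B,
P(C₁|B) = P(C₂|B) = 0.5, baseline objects in inter-triplet gaps, no
back-to-back repeats of an A/B stem), recognition priming (each C₂ directly
preceded by its overlapping C₁, each tested C₁ preceded by a same-session
baseline, B always after its A), pre/post exposure scans (C₁ and C₂ split
across scans; identical orders reused pre and post), and explicit
integration tests (rating pairs or 2AFC). Empirical role-transition matrices
validate any generated or recorded order against the structural cells.

**Behavioral statistics.** The recognition-priming score — per sequence, the
RT difference between the control C₁ (after an unrelated old object) and the
primed C₂ (after its overlapping C₁), with the triple-inclusion rule that
baseline, C₁ and C₂ were all endorsed 'old'; summarized as the per-subject
median of within-sequence differences (difference-of-medians available).
Trial-level mixed-effects models (lme4/lmerTest, Satterthwaite F) for
learning curves (repetition × session × predictability) and priming, the
Zhang–Mueller nonparametric sensitivity *A* (closed form re-derived from the
min/max proper-ROC-area construction, with a numeric-geometry oracle in the
tests), and explicit-integration scores against chance.

**Pattern pipeline.** Single-trial-class GLM per exposure scan (3-s boxcars
per object convolved with the double-gamma HRF, junk regressor for pound-sign
trials, temporal derivatives), per-object *t*-patterns, cross-scan C₁×C₂
Pearson similarity matrices, and the point-biserial fit to the binary
**neural integration model** (1 = same-sequence pair). Change score
Δz = z(post) − z(pre): positive = integration, negative = differentiation.
Controls: partial correlation given per-cell |ΔBOLD| and voxelwise z-scoring.

**Rest pipeline.** Nuisance GLM (6 motion parameters + derivatives, spike
stick functions, WM/CSF signals + derivatives), zero-phase Butterworth
band-pass 0.01–0.1 Hz of the residuals, ROI mean courses, Fisher-z Pearson
coupling, and pre→post change scores against the single pre-learning
baseline scan.

**Group inference.** Across-subject correlations, comparison of dependent
nonoverlapping correlations (Raghunathan–Rosenthal–Rubin / Pearson–Filon),
partial correlations, the two-predictor regression of priming on
Δ-integration and Δ-coupling with semi-partial R² per predictor, and
Bonferroni bookkeeping over the ROI (4) and ROI-pair (5) families.

**Synthetic cohort.** Subject latents (priming in ms, Δ-integration and
Δ-coupling in Fisher-z units) drawn from a configurable correlation
structure (defaults 0.6 / 0.6 / 0.4) drive trial-level RTs, recognition
responses, voxel patterns/time series and rest scans — so the whole chain is
testable by parameter recovery. See `vignette("seqprime-methods")`.

## Worked example

```r
library(seqprime)
params <- cohort_params(n_subjects = 24)
result <- run_pipeline(params, seed = 42, rois = "mPFC")

tests <- result$report$tests
tests[tests$measure %in% c("priming", "dint_mPFC", "dcoup_postHPC-LOC"), ]
#>             measure session    mean      t        p p_adjusted
#> 1           priming  remote 48.3335  2.626 0.015102    0.01510
#> 2         dint_mPFC  remote -0.5577 -3.100 0.005049    0.02020
#> 3 dcoup_postHPC-LOC  remote  0.3251  1.919 0.067452    0.33726
#> 4           priming  recent -1.0217 -0.637 0.530433    0.53043
#> 5         dint_mPFC  recent -0.6170 -3.864 0.000788    0.00315
#> 6 dcoup_postHPC-LOC  recent  0.0966  1.320 0.199788    0.99894

result$report$correlations
#>                                       label      r df        p  n
#> 1           priming_remote~dint_mPFC_remote 0.6044 22 1.76e-03 24
#> 2           priming_recent~dint_mPFC_recent 0.0888 22 6.80e-01 24
#> 3   priming_remote~dcoup_postHPC_LOC_remote 0.7214 22 6.94e-05 24
#> ...

result$report$regression
#> <regression_summary: n = 24, R2 = 0.632>
#>   predictor         estimate     t    df        p semipartial_R2
#> 1 dint_mPFC             37.6  2.52    21 0.0200            0.111
#> 2 dcoup_postHPC_LOC     61.7  3.90    21 0.000831          0.266
```

Reading the output: this synthetic 24-subject cohort shows recognition
priming only for remotely learned sequences (mean RT benefit ≈ 48 ms,
p = 0.015; recent session null), a *negative* group change in the mPFC
integration-model fit (overlapping C objects differentiate after learning
plus a delay) that nevertheless correlates *positively* with priming across
subjects (r(22) = 0.60), a positive change in posterior-hippocampus–LOC rest
coupling related to the same behavior, and unique variance for both neural
predictors in the regression on priming (both semi-partial R² > 0) — the
qualitative structure the default generating parameters encode.

Design validation for any generated order set:

```r
result$design_checks          # structural transition cells, all pass
sign_pattern(result)          # the qualitative findings as named booleans
```

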